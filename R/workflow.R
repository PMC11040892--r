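list_micrographs <- function(folder) {
  if (!dir.exists(folder)) stop("input folder not found: ", folder, call. = FALSE)
  files <- list.files(folder, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                      full.names = TRUE)
  sort(files)  # lexicographic, so processing order is reproducible
}

#' Initial automatic analysis of an image folder
#'
#' Analyzes every micrograph in `folder` (lexicographic filename order) with
#' automatically derived parameters, writes the full six-folder artifact tree
#' under `results_root`, one Palam parameter file per image, a
#' `PalamLock.txt` seeded from the first successfully analyzed image, and the
#' counts text file. Images that fail to decode or analyze are logged and
#' skipped; the remaining images are still processed.
#'
#' @param folder Directory of TIFF/PNG micrographs.
#' @param results_root Directory for the output tree (created if absent).
#' @param exclude_border Passed to [analyze_image()].
#' @return List of class `mn_run`: `results` (per-image `mn_image_result`),
#'   `tree`, `failed` (named character vector of error messages).
#' @export
initial_analysis <- function(folder, results_root, exclude_border = FALSE) {
  files <- list_micrographs(folder)
  if (length(files) == 0L)
    stop("no decodable images (*.tif, *.tiff, *.png) in ", folder, call. = FALSE)
  tree <- output_tree(results_root)
  results <- list()
  failed <- character()
  for (f in files) {
    stem <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch(analyze_image(f, p = NULL, exclude_border = exclude_border),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[stem] <- conditionMessage(res)
      message("skipping ", basename(f), ": ", conditionMessage(res))
      next
    }
    m <- read_rgb_micrograph(f)
    render_outputs(m, res$masks$cell_labels, res$mn, tree, name = stem)
    write_palam(res$params, file.path(tree$paths[["Palam"]], paste0(stem, ".txt")))
    results[[stem]] <- res
  }
  if (length(results) == 0L)
    stop("all images failed to analyze in ", folder, call. = FALSE)
  # PalamLock seeds batch reanalysis with the first image's automatic params
  write_palam(results[[1L]]$params,
              file.path(tree$paths[["Palam"]], "PalamLock.txt"))
  write_counts_text(results, tree)
  structure(list(results = results, tree = tree, failed = failed),
            class = "mn_run")
}

#' @export
print.mn_run <- function(x, ...) {
  cat(sprintf("Analysis run: %d image(s), %d skipped; results under %s\n",
              length(x$results), length(x$failed), x$tree$root))
  invisible(x)
}

#' Individual reanalysis of one image
#'
#' Re-runs a single image with manual parameter overrides merged onto the
#' parameters stored during the initial analysis, then overwrites only that
#' image's artifacts, Palam file and counts-table row.
#'
#' @param image Path to the micrograph (must have been part of an initial
#'   analysis into `results_root`).
#' @param results_root Root of an existing output tree.
#' @param overrides Named list of parameter overrides (any of
#'   `binarization_th`, `kernel_s`, `kernel_l`, `noise_reduction`,
#'   `micronucleus_th`, `window_level`, `sigmoid_gain`).
#' @param exclude_border Passed to [analyze_image()].
#' @return The new `mn_image_result`.
#' @export
individual_reanalysis <- function(image, results_root, overrides = list(),
                                  exclude_border = FALSE) {
  stem <- tools::file_path_sans_ext(basename(image))
  palam_path <- file.path(results_root, "Palam", paste0(stem, ".txt"))
  if (!file.exists(palam_path))
    stop("no stored parameters for '", stem, "' under ", results_root,
         "; run initial_analysis() first", call. = FALSE)
  p <- merge_params(read_palam(palam_path), overrides)
  tree <- output_tree(results_root)
  res <- analyze_image(image, p = p, exclude_border = exclude_border)
  m <- read_rgb_micrograph(image)
  render_outputs(m, res$masks$cell_labels, res$mn, tree, name = stem)
  write_palam(p, palam_path)
  update_counts_row(tree, res)
  res
}

#' Batch reanalysis of a folder with one parameter set
#'
#' Re-analyzes every image of a previously analyzed folder with the single
#' parameter set read from `PalamLock.txt`, overwriting all artifacts and
#' every per-image Palam file with that set.
#'
#' @param folder Directory of micrographs.
#' @param results_root Root of an existing output tree.
#' @param palamlock Path to the parameter lock file; defaults to the one
#'   inside the tree's `Palam` folder.
#' @param exclude_border Passed to [analyze_image()].
#' @return List of class `mn_run`.
#' @export
batch_reanalysis <- function(folder, results_root,
                             palamlock = file.path(results_root, "Palam", "PalamLock.txt"),
                             exclude_border = FALSE) {
  p <- read_palam(palamlock)
  files <- list_micrographs(folder)
  if (length(files) == 0L)
    stop("no decodable images in ", folder, call. = FALSE)
  tree <- output_tree(results_root)
  results <- list()
  failed <- character()
  for (f in files) {
    stem <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch(analyze_image(f, p = p, exclude_border = exclude_border),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[stem] <- conditionMessage(res)
      message("skipping ", basename(f), ": ", conditionMessage(res))
      next
    }
    m <- read_rgb_micrograph(f)
    render_outputs(m, res$masks$cell_labels, res$mn, tree, name = stem)
    write_palam(p, file.path(tree$paths[["Palam"]], paste0(stem, ".txt")))
    results[[stem]] <- res
  }
  if (length(results) == 0L)
    stop("all images failed to analyze in ", folder, call. = FALSE)
  write_counts_text(results, tree)
  structure(list(results = results, tree = tree, failed = failed),
            class = "mn_run")
}

# rewrite one image's row of the counts file in place, keeping the order and
# recomputing the terminal total row
update_counts_row <- function(tree, res, filename = "counts.txt") {
  path <- file.path(tree$paths[["Text"]], filename)
  if (!file.exists(path)) return(invisible(NULL))
  lines <- readLines(path, warn = FALSE)
  body <- lines[seq_len(length(lines) - 1L)]  # last line is the total row
  parts <- strsplit(body, "\t", fixed = TRUE)
  names_col <- vapply(parts, `[[`, "", 1L)
  hit <- which(names_col == res$name)
  newline <- sprintf("%s\t%d\t%d", res$name, res$total_cells, res$mn_cells)
  if (length(hit) == 1L) body[hit] <- newline else body <- c(body, newline)
  parts <- strsplit(body, "\t", fixed = TRUE)
  tot <- sprintf("total\t%d\t%d",
                 sum(as.integer(vapply(parts, `[[`, "", 2L))),
                 sum(as.integer(vapply(parts, `[[`, "", 3L))))
  writeLines(c(body, tot), path)
  invisible(path)
}
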