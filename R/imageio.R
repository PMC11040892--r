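#' Read an RGB micrograph
#'
#' Reads a TIFF or PNG micrograph into an 8-bit-per-channel RGB pixel grid.
#' 16-bit TIFF inputs are rescaled to 8-bit by integer division by 257 (the
#' full-range linear map). An alpha channel, if present, is dropped;
#' single-channel images are rejected because channel separation is the first
#' step of the analysis.
#'
#' @param path Path to a TIFF (8- or 16-bit) or PNG file.
#' @return An object of class `rgb_micrograph`: list with `pixels` (H x W x 3
#'   integer array, values 0..255), `path`, `height`, `width`.
#' @export
read_rgb_micrograph <- function(path) {
  if (!file.exists(path))
    stop("cannot read micrograph, file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      img <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(img, "bits.per.sample")
      if (is.null(bits)) bits <- 8L
      v <- round(unclass(img) * (2^bits - 1))
      if (bits > 8L) v <- v %/% 257 else v
    } else if (ext == "png") {
      round(unclass(png::readPNG(path)) * 255)
    } else {
      stop("unsupported image format: .", ext)
    }
  }, error = function(e) {
    stop("cannot decode '", path, "' as an image: ", conditionMessage(e),
         call. = FALSE)
  })
  if (length(dim(arr)) == 2L)
    stop("expected an RGB image, got 1 channel: ", path, call. = FALSE)
  nch <- dim(arr)[3L]
  if (nch == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3L] != 3L)
    stop("expected an RGB image, got ", nch, " channel(s): ", path, call. = FALSE)
  arr <- structure(arr, dim = dim(arr))        # drop decoder metadata attributes
  attributes(arr) <- list(dim = dim(arr))
  storage.mode(arr) <- "integer"
  structure(list(pixels = arr, path = path,
                 height = dim(arr)[1L], width = dim(arr)[2L]),
            class = "rgb_micrograph")
}

#' Construct a micrograph from a pixel array
#'
#' Wraps an in-memory H x W x 3 array (values 0..255) as an `rgb_micrograph`,
#' e.g. for synthetic scenes that were never written to disk.
#'
#' @param pixels H x W x 3 numeric array with values in 0..255.
#' @param path Identifier used in reports and file names.
#' @return An `rgb_micrograph`.
#' @export
rgb_micrograph <- function(pixels, path = "<memory>") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L,
            dim(pixels)[1L] >= 1L, dim(pixels)[2L] >= 1L)
  if (any(pixels < 0 | pixels > 255)) stop("pixel values must lie in 0..255")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, path = path,
                 height = dim(pixels)[1L], width = dim(pixels)[2L]),
            class = "rgb_micrograph")
}

#' @export
print.rgb_micrograph <- function(x, ...) {
  cat(sprintf("RGB micrograph %dx%d px (%s)\n", x$height, x$width, x$path))
  invisible(x)
}

#' Split a micrograph into red and green channels
#'
#' Returns the red and green planes as grayscale matrices; the blue plane
#' carries no stain information under acridine orange and is discarded.
#'
#' @param m An `rgb_micrograph`.
#' @return List with integer matrices `red` and `green`.
#' @export
split_channels <- function(m) {
  stopifnot(inherits(m, "rgb_micrograph"))
  list(red = m$pixels[, , 1L], green = m$pixels[, , 2L])
}

# ---- Output tree ------------------------------------------------------------

OUTPUT_SUBFOLDERS <- c("Image", "Grayscale", "Count", "Shokaku", "Text", "Palam")

#' Initialize the six-folder results tree
#'
#' Creates (if needed) the fixed set of output folders under a results root:
#' `Image` (copies of the originals), `Grayscale` (green channel), `Count`
#' (cytoplasm label map in distinct colors), `Shokaku` (original annotated
#' with a white circle around each accepted micronucleus), `Text` (the counts
#' table) and `Palam` (per-image parameter files plus `PalamLock.txt`).
#'
#' @param root Results root directory (created if absent).
#' @return Object of class `output_tree`: list with `root` and named `paths`.
#' @export
output_tree <- function(root) {
  dirs <- file.path(root, OUTPUT_SUBFOLDERS)
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ok <- dir.exists(dirs)
  if (!all(ok))
    stop("cannot create output folder(s): ", paste(dirs[!ok], collapse = ", "),
         call. = FALSE)
  structure(list(root = root, paths = stats::setNames(dirs, OUTPUT_SUBFOLDERS)),
            class = "output_tree")
}

# deterministic golden-angle palette keyed by label id
label_palette <- function(n) {
  if (n == 0L) return(character())
  hues <- ((seq_len(n) - 1L) * 137.50776405) %% 360
  grDevices::hsv(h = hues / 360, s = 0.65, v = 1)
}

write_png_gray <- function(m, path) {
  png::writePNG(m / 255, path)
  invisible(path)
}

write_png_rgb <- function(arr, path) {
  png::writePNG(arr / 255, path)
  invisible(path)
}

#' Render the per-image output artifacts
#'
#' Writes, for one analyzed micrograph: a copy of the original into `Image`;
#' the green channel as grayscale into `Grayscale`; the cell label map with a
#' distinct deterministic color per cell into `Count`; and the original with
#' a white circle (2 px stroke, radius = the micronucleus equivalent radius
#' + 4 px) around each accepted micronucleus into `Shokaku`. Rendering only
#' reads the analysis result; it never modifies counts.
#'
#' @param m The source `rgb_micrograph`.
#' @param cells Integer cell label map (H x W).
#' @param accepted_mn Region table of accepted micronuclei (from
#'   [filter_micronuclei()]), needing columns `centroid_r`, `centroid_c`,
#'   `area`.
#' @param tree An [output_tree()].
#' @param name Output stem; defaults to the stem of `m$path`.
#' @return Named character vector of the four file paths, invisibly.
#' @export
render_outputs <- function(m, cells, accepted_mn, tree, name = NULL) {
  stopifnot(inherits(m, "rgb_micrograph"), inherits(tree, "output_tree"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(m$path))
  paths <- c(
    Image     = file.path(tree$paths[["Image"]], basename_or_png(m$path, name)),
    Grayscale = file.path(tree$paths[["Grayscale"]], paste0(name, ".png")),
    Count     = file.path(tree$paths[["Count"]], paste0(name, ".png")),
    Shokaku   = file.path(tree$paths[["Shokaku"]], paste0(name, ".png"))
  )
  # Image: byte copy when the source exists on disk, else a PNG render
  if (file.exists(m$path)) {
    file.copy(m$path, paths[["Image"]], overwrite = TRUE)
  } else {
    png::writePNG(m$pixels / 255, file.path(tree$paths[["Image"]],
                                            paste0(name, ".png")))
  }
  write_png_gray(m$pixels[, , 2L], paths[["Grayscale"]])
  # Count: golden-angle palette, black background
  n <- max(cells, 0L)
  pal <- grDevices::col2rgb(label_palette(n))
  count_img <- array(0, dim = c(nrow(cells), ncol(cells), 3L))
  if (n > 0L) {
    idx <- which(cells > 0L)
    lv <- cells[idx]
    for (ch in 1:3) {
      plane <- count_img[, , ch]
      plane[idx] <- pal[ch, lv]
      count_img[, , ch] <- plane
    }
  }
  write_png_rgb(count_img, paths[["Count"]])
  # Shokaku: white ring of stroke 2 px around each accepted micronucleus
  marked <- m$pixels
  if (nrow(accepted_mn) > 0L) {
    ring <- mn_marker_mask(dim(marked)[1L], dim(marked)[2L], accepted_mn)
    for (ch in 1:3) {
      plane <- marked[, , ch]
      plane[ring] <- 255L
      marked[, , ch] <- plane
    }
  }
  write_png_rgb(marked, paths[["Shokaku"]])
  invisible(paths)
}

basename_or_png <- function(path, name) {
  if (file.exists(path)) basename(path) else paste0(name, ".png")
}

# logical mask of the annotation rings: for each micronucleus, pixels whose
# Euclidean distance d from the centroid satisfies r0 <= d < r0 + 2 with
# r0 = equivalent radius + 4
mn_marker_mask <- function(h, w, mn_table) {
  ring <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(mn_table))) {
    r0 <- sqrt(mn_table$area[i] / pi) + 4
    cr <- mn_table$centroid_r[i]; cc <- mn_table$centroid_c[i]
    rr <- max(1L, floor(cr - r0 - 2)):min(h, ceiling(cr + r0 + 2))
    cw <- max(1L, floor(cc - r0 - 2)):min(w, ceiling(cc + r0 + 2))
    d <- sqrt(outer((rr - cr)^2, (cw - cc)^2, "+"))
    ring[rr, cw] <- ring[rr, cw] | (d >= r0 & d < r0 + 2)
  }
  ring
}

#' Write the counts text file
#'
#' Tab-separated table with one line per analyzed image (`name`,
#' `total_cells`, `mn_cells`) and a terminal `total` row holding the column
#' sums, written into the `Text` folder.
#'
#' @param results List of image results (see [analyze_image()]).
#' @param tree An [output_tree()].
#' @param filename Name of the file inside `Text`.
#' @return The file path, invisibly.
#' @export
write_counts_text <- function(results, tree, filename = "counts.txt") {
  if (length(results) == 0L)
    stop("no results to write", call. = FALSE)
  stopifnot(inherits(tree, "output_tree"))
  lines <- vapply(results, function(r)
    sprintf("%s\t%d\t%d", r$name, r$total_cells, r$mn_cells), "")
  tot <- sprintf("total\t%d\t%d",
                 sum(vapply(results, `[[`, 0L, "total_cells")),
                 sum(vapply(results, `[[`, 0L, "mn_cells")))
  path <- file.path(tree$paths[["Text"]], filename)
  writeLines(c(lines, tot), path)
  invisible(path)
}
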