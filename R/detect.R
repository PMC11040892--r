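#' Separate nuclei from micronucleus candidates by erosion
#'
#' Size discrimination at the heart of the method: the cleaned green mask is
#' eroded with the large square element. Connected components (8-connectivity)
#' that retain at least one pixel after erosion are large enough to be nuclei;
#' components erased entirely are micronucleus candidates. Surviving
#' components are returned at their full original extent (the component is the
#' unit of reconstruction), so nucleus footprints are exact, not re-dilated
#' approximations. The two outputs partition the input mask.
#'
#' @param green_mask Cleaned logical mask of green (nuclear) material.
#' @param kernel_l Width of the large square structuring element.
#' @return List with logical masks `nuclei` and `mn_candidates`.
#' @export
classify_blobs_by_erosion <- function(green_mask, kernel_l) {
  stopifnot(is.matrix(green_mask))
  if (!any(green_mask))
    return(list(nuclei = green_mask & FALSE, mn_candidates = green_mask & FALSE))
  lab <- label_regions(green_mask)
  remnant <- erode_mask(green_mask, kernel_l)
  surviving <- unique(lab[remnant & lab > 0L])
  nuclei <- matrix(lab %in% surviving, nrow(lab), ncol(lab))
  list(nuclei = nuclei, mn_candidates = green_mask & !nuclei)
}

#' Cytoplasm mask from the red and green channels
#'
#' Superimposes the two stain channels (per-pixel maximum), applies the
#' sigmoid gradation around the window level to emphasize the dim cytoplasm
#' against background, thresholds the enhanced composite with Otsu's method,
#' cleans the mask with the small element and fills every enclosed hole. The
#' binarized green mask is folded in before hole filling so that each nucleus
#' pixel is guaranteed to lie inside the cytoplasm mask.
#'
#' @param red,green Integer channel matrices (same shape).
#' @param p A `detection_params` object.
#' @return Logical cytoplasm mask.
#' @export
cytoplasm_mask <- function(red, green, p) {
  stopifnot(is.matrix(red), is.matrix(green), all(dim(red) == dim(green)))
  validate_params(p)
  composite <- pmax(red, green)
  enh <- sigmoid_enhance(composite, center = p$window_level, gain = p$sigmoid_gain)
  if (all(enh == enh[1L])) return(matrix(FALSE, nrow(red), ncol(red)))
  th <- EBImage::otsu(EBImage::Image(enh / 255), range = c(0, 1))
  mask <- enh / 255 > th
  mask <- clean_mask(mask, p$kernel_s)
  mask <- mask | clean_mask(binarize(green, p$binarization_th), p$kernel_s)
  filled <- EBImage::fillHull(as_mask(mask))
  matrix(as.numeric(filled) > 0.5, nrow(red), ncol(red))
}

#' Separate touching cells by marker-controlled watershed
#'
#' Splits the fused cytoplasm mask into one region per nucleus: nucleus
#' components act as markers and grow geodesically inside the mask (the
#' propagation metric is dominated by spatial distance), so the dividing
#' lines fall near the midpoints between adjacent nuclei. Pixels on the
#' dividing lines belong to no cell, and cytoplasm components that contain no
#' marker stay unlabeled (debris and ghosts are not cells).
#'
#' @param cyto Logical cytoplasm mask.
#' @param nuclei Logical nucleus mask. Nucleus pixels outside the cytoplasm
#'   are dropped with a warning.
#' @return Integer label map; label i corresponds to nucleus component i.
#' @export
separate_cells <- function(cyto, nuclei) {
  stopifnot(is.matrix(cyto), is.matrix(nuclei), all(dim(cyto) == dim(nuclei)))
  inside <- nuclei & cyto
  if (any(nuclei & !cyto))
    warning(sum(nuclei & !cyto), " nucleus pixel(s) outside the cytoplasm mask were dropped")
  markers <- label_regions(inside)
  if (max(markers) == 0L) return(matrix(0L, nrow(cyto), ncol(cyto)))
  dm <- EBImage::distmap(as_mask(cyto))
  lab <- EBImage::propagate(EBImage::Image(dm / max(dm)),
                            seeds = markers, mask = cyto, lambda = 1e4)
  lab <- matrix(as.integer(lab), nrow(cyto), ncol(cyto))
  zero_boundary(lab)
}

# set to background every pixel with a 4-neighbor carrying a different
# nonzero label: these are the watershed dividing lines
zero_boundary <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  line <- matrix(FALSE, h, w)
  a <- lab[-h, ]; b <- lab[-1, ]
  sel <- a > 0L & b > 0L & a != b
  line[-h, ][sel] <- TRUE; line[-1, ][sel] <- TRUE
  a <- lab[, -w]; b <- lab[, -1]
  sel <- a > 0L & b > 0L & a != b
  line[, -w][sel] <- TRUE; line[, -1][sel] <- TRUE
  lab[line] <- 0L
  lab
}

#' Filter micronucleus candidates by area and circularity
#'
#' Keeps candidate regions whose area is at least the noise-reduction cut and
#' whose circularity reaches the micronucleus threshold. Raising either
#' parameter can only shrink the accepted set.
#'
#' @param candidates Region table (from [measure_regions()]) of micronucleus
#'   candidate blobs.
#' @param p A `detection_params` object.
#' @return The subset of rows accepted as micronuclei.
#' @export
filter_micronuclei <- function(candidates, p) {
  validate_params(p)
  candidates[candidates$area >= p$noise_reduction &
               candidates$circularity >= p$micronucleus_th, , drop = FALSE]
}

#' Classify cells as normal or micronucleated
#'
#' One record per cell label. Each accepted micronucleus is assigned to the
#' cell whose label contains its centroid (rounded to the nearest pixel);
#' centroids falling on watershed lines or background are discarded. A cell
#' with one nucleus and no assigned micronucleus is a normal cell; a cell
#' with one or more assigned micronuclei is a single micronucleated cell
#' regardless of how many micronuclei it carries.
#'
#' @param cells Integer cell label map from [separate_cells()].
#' @param mn Region table of accepted micronuclei.
#' @param exclude_border Drop cells whose label touches the image border.
#' @return data.frame with `cell_id`, `n_mn`, `is_mn_cell`.
#' @export
classify_cells <- function(cells, mn, exclude_border = FALSE) {
  stopifnot(is.matrix(cells))
  ids <- sort(unique(cells[cells > 0L]))
  if (exclude_border && length(ids) > 0L) {
    h <- nrow(cells); w <- ncol(cells)
    touching <- unique(c(cells[1, ], cells[h, ], cells[, 1], cells[, w]))
    ids <- setdiff(ids, touching)
  }
  n_mn <- stats::setNames(integer(length(ids)), ids)
  if (!is.null(mn) && nrow(mn) > 0L && length(ids) > 0L) {
    rr <- pmin(pmax(round(mn$centroid_r), 1L), nrow(cells))
    cc <- pmin(pmax(round(mn$centroid_c), 1L), ncol(cells))
    owner <- cells[cbind(rr, cc)]
    owner <- owner[owner %in% ids]
    if (length(owner) > 0L) {
      tab <- table(owner)
      n_mn[names(tab)] <- as.integer(tab)
    }
  }
  data.frame(cell_id = as.integer(ids), n_mn = as.integer(n_mn),
             is_mn_cell = n_mn > 0L, row.names = NULL)
}

#' Analyze one micrograph
#'
#' Full pipeline: split channels; binarize and clean the green channel;
#' separate nuclei from micronucleus candidates by erosion with the large
#' element; measure and filter the candidates by area and circularity; build
#' the cytoplasm mask from the sigmoid-enhanced red/green composite; split
#' touching cells by marker-controlled watershed; and classify each cell as
#' normal or micronucleated. Deterministic: the same image and parameters
#' always give identical masks and counts.
#'
#' @param m An `rgb_micrograph` (or a path, which is read first).
#' @param p A `detection_params` object, or `NULL` to derive parameters
#'   automatically from the green channel ([auto_params()]).
#' @param exclude_border Drop cells touching the image border (by default all
#'   cells in the field are counted).
#' @param name Result name; defaults to the file stem of the image path.
#' @return Object of class `mn_image_result`: list with `name`,
#'   `total_cells`, `mn_cells`, `cells` (per-cell records), `mn` (accepted
#'   micronucleus region table), `params`, and `masks` (green binary, nuclei,
#'   micronucleus candidates, cytoplasm, cell label map).
#' @export
analyze_image <- function(m, p = NULL, exclude_border = FALSE, name = NULL) {
  if (is.character(m)) m <- read_rgb_micrograph(m)
  stopifnot(inherits(m, "rgb_micrograph"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(m$path))
  ch <- split_channels(m)
  if (is.null(p)) p <- auto_params(ch$green)
  validate_params(p)

  green_bin <- clean_mask(binarize(ch$green, p$binarization_th), p$kernel_s)
  blobs <- classify_blobs_by_erosion(green_bin, p$kernel_l)
  cand <- measure_regions(blobs$mn_candidates)
  mn <- filter_micronuclei(cand, p)
  cyto <- cytoplasm_mask(ch$red, ch$green, p)
  cells <- separate_cells(cyto, blobs$nuclei)
  records <- classify_cells(cells, mn, exclude_border = exclude_border)

  structure(list(
    name = name,
    total_cells = nrow(records),
    mn_cells = sum(records$is_mn_cell),
    cells = records,
    mn = mn,
    params = p,
    masks = list(green_binary = green_bin, nuclei = blobs$nuclei,
                 mn_candidates = blobs$mn_candidates, cytoplasm = cyto,
                 cell_labels = cells)
  ), class = "mn_image_result")
}

#' @export
print.mn_image_result <- function(x, ...) {
  cat(sprintf("%s: %d cells, %d micronucleated (MN%% %.2f)\n", x$name,
              x$total_cells, x$mn_cells,
              if (x$total_cells > 0) 100 * x$mn_cells / x$total_cells else 0))
  invisible(x)
}
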