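#' Detection parameters
#'
#' Constructs and validates the six-parameter model that governs the analysis
#' of one micrograph: the green-channel binarization threshold, the small and
#' large square structuring elements, the minimum region area kept after
#' segmentation (noise reduction), the circularity threshold a candidate spot
#' must reach to be accepted as a micronucleus, and the sigmoid window level
#' used to enhance the cytoplasm. A seventh value, the sigmoid gain, is a
#' configuration setting rather than a tunable threshold and is deliberately
#' kept out of the on-disk parameter files (see [write_palam()]).
#'
#' @param binarization_th Integer in 0..255. Green intensities at or above
#'   this value are treated as nuclear material (nuclei and micronuclei).
#' @param kernel_s Odd integer >= 3. Width in pixels of the small square
#'   structuring element used to fill pinholes and remove speckle.
#' @param kernel_l Odd integer > `kernel_s`. Width of the large square
#'   structuring element; green blobs that survive erosion by this element
#'   are nuclei, blobs erased by it are micronucleus candidates.
#' @param noise_reduction Non-negative integer. Minimum area in px^2 a
#'   micronucleus candidate must have; smaller regions are discarded as noise.
#' @param micronucleus_th Circularity threshold in \[0, 1\]. Candidates with
#'   circularity `4*pi*A/P^2` below this value are rejected; 1 accepts only
#'   perfectly round spots.
#' @param window_level Integer in 0..255. Center of the sigmoid gradation
#'   applied to the red/green composite before cytoplasm thresholding;
#'   intensities above it are emphasized, below it suppressed.
#' @param sigmoid_gain Positive slope of the sigmoid at its center.
#'
#' @return An object of class `detection_params` (a validated list).
#' @seealso [default_params()], [auto_binarization_th()], [write_palam()]
#' @export
#' @examples
#' detection_params(binarization_th = 85, kernel_l = 13)
detection_params <- function(binarization_th = 85, kernel_s = 3, kernel_l = 13,
                             noise_reduction = 11, micronucleus_th = 0.5,
                             window_level = 118, sigmoid_gain = 0.05) {
  p <- list(
    binarization_th = as.integer(binarization_th),
    kernel_s        = as.integer(kernel_s),
    kernel_l        = as.integer(kernel_l),
    noise_reduction = as.integer(noise_reduction),
    micronucleus_th = as.numeric(micronucleus_th),
    window_level    = as.integer(window_level),
    sigmoid_gain    = as.numeric(sigmoid_gain)
  )
  class(p) <- "detection_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "detection_params"))
  if (is.na(p$binarization_th) || p$binarization_th < 0 || p$binarization_th > 255)
    stop("binarization_th must lie in 0..255", call. = FALSE)
  for (k in c("kernel_s", "kernel_l")) {
    v <- p[[k]]
    if (is.na(v) || v < 3 || v %% 2 == 0)
      stop(k, " must be an odd integer >= 3", call. = FALSE)
  }
  if (p$kernel_s >= p$kernel_l)
    stop("kernel_s must be smaller than kernel_l", call. = FALSE)
  if (is.na(p$noise_reduction) || p$noise_reduction < 0)
    stop("noise_reduction must be >= 0", call. = FALSE)
  if (is.na(p$micronucleus_th) || p$micronucleus_th < 0 || p$micronucleus_th > 1)
    stop("micronucleus_th must lie in [0, 1]", call. = FALSE)
  if (is.na(p$window_level) || p$window_level < 0 || p$window_level > 255)
    stop("window_level must lie in 0..255", call. = FALSE)
  if (is.na(p$sigmoid_gain) || p$sigmoid_gain <= 0)
    stop("sigmoid_gain must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Detection parameters\n")
  cat(sprintf("  binarization TH : %d\n", x$binarization_th))
  cat(sprintf("  kernel S / L    : %d / %d px\n", x$kernel_s, x$kernel_l))
  cat(sprintf("  noise reduction : %d px^2\n", x$noise_reduction))
  cat(sprintf("  micronucleus TH : %g\n", x$micronucleus_th))
  cat(sprintf("  window level    : %d (gain %g)\n", x$window_level, x$sigmoid_gain))
  invisible(x)
}

#' Green-channel intensity histogram
#'
#' Tallies the 256 possible 8-bit intensities of a green channel image and
#' records the modal nonzero intensity, the statistic that drives automatic
#' threshold selection. Ties are broken toward the lower intensity; bin 0 is
#' excluded from the peak because it is dominated by true background.
#'
#' @param green Integer matrix of green intensities in 0..255.
#' @return A list of class `green_histogram` with `counts` (named 256-vector,
#'   bins "0".."255") and `peak_intensity` (0 when no nonzero pixel exists).
#' @export
green_histogram <- function(green) {
  v <- as.integer(green)
  if (any(is.na(v)) || any(v < 0L | v > 255L))
    stop("green channel values must be integers in 0..255", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  names(counts) <- as.character(0:255)
  nz <- counts[-1L]
  peak <- if (sum(nz) == 0L) 0L else which.max(nz)  # which.max -> lowest tie
  structure(list(counts = counts, peak_intensity = as.integer(peak)),
            class = "green_histogram")
}

#' Automatic binarization threshold from the green histogram
#'
#' Maps the modal nonzero green intensity onto one of five representative
#' binarization thresholds (65, 75, 85, 120, 165). The mapping is monotone:
#' brighter histogram peaks select higher thresholds. The default bin edges
#' place peaks below 50 at threshold 65, 50-69 at 75, 70-99 at 85, 100-149 at
#' 120 and 150 or more at 165; both edges and levels can be overridden.
#'
#' @param h A [green_histogram()], or an integer matrix from which one is
#'   computed.
#' @param breaks Increasing integer vector of bin edges (length one less than
#'   `levels`).
#' @param levels Non-decreasing thresholds returned for each bin.
#' @return A single integer threshold, one of `levels`. An image with no
#'   nonzero pixel returns the lowest level with a warning.
#' @export
#' @examples
#' auto_binarization_th(green_histogram(matrix(85L, 8, 8)))
auto_binarization_th <- function(h, breaks = c(50L, 70L, 100L, 150L),
                                 levels = c(65L, 75L, 85L, 120L, 165L)) {
  if (is.matrix(h)) h <- green_histogram(h)
  stopifnot(inherits(h, "green_histogram"))
  if (length(levels) != length(breaks) + 1L)
    stop("levels must be one longer than breaks", call. = FALSE)
  if (is.unsorted(breaks, strictly = TRUE) || is.unsorted(levels))
    stop("breaks must be strictly increasing and levels non-decreasing", call. = FALSE)
  if (h$peak_intensity == 0L && h$counts[["0"]] == sum(h$counts)) {
    warning("image has no nonzero green pixel; using the lowest threshold")
    return(as.integer(levels[1L]))
  }
  as.integer(levels[findInterval(h$peak_intensity, breaks) + 1L])
}

#' Estimate the typical nucleus diameter of an image
#'
#' Coarse pre-pass used to size the large structuring element: the green
#' channel is thresholded by Otsu's method, connected components with area
#' above `min_area` px^2 are measured, and the median equivalent diameter
#' `2*sqrt(A/pi)` is returned.
#'
#' @param green Integer matrix of green intensities in 0..255.
#' @param min_area Components at or below this area are ignored (debris and
#'   micronuclei should not drive the kernel size).
#' @return Median equivalent diameter in pixels, or `NA` when no component
#'   qualifies (e.g. a blank image).
#' @export
estimate_nucleus_diameter <- function(green, min_area = 50) {
  g <- green / 255
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  mask <- g > th
  if (!any(mask)) return(NA_real_)
  lab <- label_regions(mask)
  areas <- tabulate(lab[lab > 0L])
  areas <- areas[areas > min_area]
  if (length(areas) == 0L) return(NA_real_)
  stats::median(2 * sqrt(areas / pi))
}

#' Default parameters scaled to the nucleus size
#'
#' Produces the automatic parameter set used by the initial analysis. The
#' micronucleus circularity threshold and window level take the fixed values
#' 0.5 and 118. The large kernel follows the nucleus size: the nearest odd
#' integer at or above `max(7, round(0.6 * diameter))`. The noise area cut is
#' 11 px^2 for large kernels up to 15 px and 21 px^2 beyond that, so that the
#' noise floor scales with the size class being kept.
#'
#' @param nucleus_diameter_estimate Estimated nucleus diameter in pixels
#'   (from [estimate_nucleus_diameter()]); must be >= 6.
#' @param binarization_th Threshold to embed in the returned set, typically
#'   from [auto_binarization_th()].
#' @param sigmoid_gain Passed through to [detection_params()].
#' @return A `detection_params` object.
#' @export
#' @examples
#' default_params(20)  # kernel_l 13, noise_reduction 11
default_params <- function(nucleus_diameter_estimate, binarization_th = 85L,
                           sigmoid_gain = 0.05) {
  d <- nucleus_diameter_estimate
  if (!is.finite(d) || d < 6)
    stop("nucleus diameter estimate must be >= 6 px; image scale too small",
         call. = FALSE)
  k <- max(7L, as.integer(round(0.6 * d)))
  if (k %% 2L == 0L) k <- k + 1L
  detection_params(
    binarization_th = binarization_th,
    kernel_s        = 3L,
    kernel_l        = k,
    noise_reduction = if (k <= 15L) 11L else 21L,
    micronucleus_th = 0.5,
    window_level    = 118L,
    sigmoid_gain    = sigmoid_gain
  )
}

#' Automatic parameters for one micrograph
#'
#' Convenience wrapper combining [auto_binarization_th()] and
#' [default_params()] on the green channel of an image.
#'
#' @param green Integer matrix of green intensities.
#' @inheritParams auto_binarization_th
#' @return A `detection_params` object. When the nucleus pre-pass finds no
#'   usable component (blank or near-blank image) the size-dependent fields
#'   fall back to kernel_l 13 / noise 11 with a warning.
#' @export
auto_params <- function(green, breaks = c(50L, 70L, 100L, 150L),
                        levels = c(65L, 75L, 85L, 120L, 165L)) {
  th <- auto_binarization_th(green_histogram(green), breaks, levels)
  d <- estimate_nucleus_diameter(green)
  if (!is.finite(d) || d < 6) {
    warning("no usable nucleus component for kernel sizing; using defaults")
    return(detection_params(binarization_th = th))
  }
  default_params(d, binarization_th = th)
}

# ---- Palam parameter file dialect -------------------------------------------

#' Read and write Palam parameter files
#'
#' Plain-text dialect used both for the per-image files in the `Palam` output
#' folder and for `PalamLock.txt`, which drives batch reanalysis. A file holds
#' exactly six lines in fixed order: binarization TH, kernel S, kernel L,
#' noise reduction, micronucleus TH, window level. The first four and the last
#' are integers, the micronucleus TH is a decimal. The sigmoid gain is not
#' serialized (it is configuration, and the format is fixed at six lines);
#' [read_palam()] restores it from its default.
#'
#' @param p A `detection_params` object.
#' @param path File to write or read.
#' @return `write_palam` returns `path` invisibly; `read_palam` returns a
#'   `detection_params` object.
#' @export
write_palam <- function(p, path) {
  validate_params(p)
  lines <- c(
    sprintf("%d", p$binarization_th),
    sprintf("%d", p$kernel_s),
    sprintf("%d", p$kernel_l),
    sprintf("%d", p$noise_reduction),
    format(p$micronucleus_th, trim = TRUE),
    sprintf("%d", p$window_level)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_palam
#' @export
read_palam <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) | seq_along(lines) <= 6]
  if (length(lines) != 6L)
    stop(sprintf("parameter file format error at line %d: expected 6 lines, found %d (%s)",
                 min(length(lines) + 1L, 7L), length(lines), path), call. = FALSE)
  parse_one <- function(i, integer = TRUE) {
    v <- suppressWarnings(as.numeric(lines[i]))
    if (is.na(v)) stop(sprintf("parameter file format error at line %d: '%s' (%s)",
                               i, lines[i], path), call. = FALSE)
    if (integer && v != round(v))
      stop(sprintf("parameter file format error at line %d: expected an integer, got '%s'",
                   i, lines[i]), call. = FALSE)
    v
  }
  detection_params(
    binarization_th = parse_one(1),
    kernel_s        = parse_one(2),
    kernel_l        = parse_one(3),
    noise_reduction = parse_one(4),
    micronucleus_th = parse_one(5, integer = FALSE),
    window_level    = parse_one(6)
  )
}

# merge a named list of overrides onto an existing parameter set
merge_params <- function(p, overrides) {
  validate_params(p)
  if (length(overrides) == 0L) return(p)
  allowed <- c("binarization_th", "kernel_s", "kernel_l", "noise_reduction",
               "micronucleus_th", "window_level", "sigmoid_gain")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad) > 0L)
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "), call. = FALSE)
  args <- utils::modifyList(unclass(p), overrides)
  do.call(detection_params, args)
}
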