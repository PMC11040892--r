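#' Binarize a channel image
#'
#' Foreground is every pixel with intensity at or above the threshold (the
#' threshold itself is included).
#'
#' @param img Integer matrix of intensities in 0..255.
#' @param th Threshold in 0..255.
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(img, th) {
  stopifnot(is.matrix(img), length(th) == 1L, th >= 0, th <= 255)
  img >= th
}

# kernel_s x kernel_s flat square structuring element
box_kernel <- function(size) {
  stopifnot(size >= 3, size %% 2 == 1)
  EBImage::makeBrush(as.integer(size), shape = "box")
}

as_mask <- function(m) {
  if (is.logical(m)) storage.mode(m) <- "numeric"
  m
}

#' Morphological cleaning of a binary mask
#'
#' Opening followed by closing with a flat `kernel_s` x `kernel_s` square
#' element: the opening removes speckle smaller than the element, the closing
#' fills pinholes and thin cracks of the same scale. At image borders the
#' window is clipped to the image (pixels outside contribute nothing), so
#' objects touching the border are not eaten from outside.
#'
#' @param m Logical matrix.
#' @param kernel_s Odd element width >= 3.
#' @return Logical matrix.
#' @export
clean_mask <- function(m, kernel_s = 3L) {
  stopifnot(is.matrix(m))
  k <- box_kernel(kernel_s)
  x <- as_mask(m)
  x <- EBImage::closing(EBImage::opening(x, k), k)
  matrix(as.numeric(x) > 0.5, nrow(m), ncol(m))
}

#' Erode or dilate a binary mask with a square element
#'
#' Thin wrappers around flat morphology with a `size` x `size` square
#' structuring element and clipped (border-replicating) window handling.
#'
#' @param m Logical matrix.
#' @param size Odd element width >= 3.
#' @return Logical matrix.
#' @export
erode_mask <- function(m, size) {
  x <- EBImage::erode(as_mask(m), box_kernel(size))
  matrix(as.numeric(x) > 0.5, nrow(m), ncol(m))
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(m, size) {
  x <- EBImage::dilate(as_mask(m), box_kernel(size))
  matrix(as.numeric(x) > 0.5, nrow(m), ncol(m))
}

#' Label connected regions (8-connectivity)
#'
#' Connected-component labeling where diagonal neighbors belong to the same
#' region. Built on 4-connected labeling followed by a union of labels that
#' touch diagonally; final labels are renumbered 1..n in order of each
#' region's first pixel in column-major scan order, so the result is
#' deterministic.
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 is background.
#' @export
label_regions <- function(mask) {
  stopifnot(is.matrix(mask))
  lab4 <- EBImage::bwlabel(as_mask(mask))
  lab4 <- matrix(as.integer(lab4), nrow(mask), ncol(mask))
  n <- max(lab4)
  if (n <= 1L) return(lab4)
  h <- nrow(lab4); w <- ncol(lab4)
  # diagonal adjacencies between distinct 4-connected labels
  a1 <- lab4[-h, -w]; b1 <- lab4[-1, -1]   # down-right
  a2 <- lab4[-h, -1]; b2 <- lab4[-1, -w]   # down-left
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    lab4[lab4 > 0L] <- memb[lab4[lab4 > 0L]]
  }
  storage.mode(lab4) <- "integer"
  # renumber deterministically by first occurrence in column-major order
  fg <- which(lab4 > 0L)
  first <- fg[!duplicated(lab4[fg])]
  remap <- integer(max(lab4))
  remap[lab4[first]] <- seq_along(first)
  lab4[fg] <- remap[lab4[fg]]
  lab4
}

#' Sigmoid gradation enhancement
#'
#' Applies `s(v) = round(255 / (1 + exp(-g * (v - c))))` to every intensity:
#' values above the window level `c` are pushed toward white and values below
#' it toward black, with slope controlled by the gain `g`. Strictly monotone
#' in `v`, so ordering of intensities is preserved.
#'
#' @param img Numeric matrix of intensities in 0..255.
#' @param center Window level `c` in 0..255.
#' @param gain Positive gain `g`.
#' @return Integer matrix in 0..255.
#' @export
sigmoid_enhance <- function(img, center = 118, gain = 0.05) {
  stopifnot(is.matrix(img), center >= 0, center <= 255, gain > 0)
  out <- round(255 / (1 + exp(-gain * (img - center))))
  storage.mode(out) <- "integer"
  out
}
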