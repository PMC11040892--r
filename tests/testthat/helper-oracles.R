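# Independent brute-force oracles used to cross-check the morphology and
# region-measurement code paths. These deliberately share no code with the
# package implementation.

# sliding-window minimum / maximum with the window clipped at image borders
naive_filter <- function(m, k, fun) {
  h <- nrow(m); w <- ncol(m); r <- (k - 1L) / 2L
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1L, i - r):min(h, i + r)
    cj <- max(1L, j - r):min(w, j + r)
    out[i, j] <- fun(m[ri, cj])
  }
  out
}
naive_erode <- function(m, k) naive_filter(m, k, all)
naive_dilate <- function(m, k) naive_filter(m, k, any)
naive_open <- function(m, k) naive_dilate(naive_erode(m, k), k)
naive_close <- function(m, k) naive_erode(naive_dilate(m, k), k)

# 8-connected component count by breadth-first flood fill
flood_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      pi <- (p - 1L) %% h + 1L; pj <- (p - 1L) %/% h + 1L
      for (di in -1:1) for (dj in -1:1) {
        qi <- pi + di; qj <- pj + dj
        if (qi >= 1L && qi <= h && qj >= 1L && qj <= w &&
            mask[qi, qj] && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue <- c(queue, (qj - 1L) * h + qi)
        }
      }
    }
  }
  n
}

# chain-length perimeter per region via EBImage's contour tracer (C code,
# independent of the package's own boundary walk); valid for masks whose
# components are 4-connected
ocontour_perimeters <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  oc <- EBImage::ocontour(lab)
  vapply(oc, function(xy) {
    if (nrow(xy) < 2L) return(0)
    d <- diff(rbind(xy, xy[1L, , drop = FALSE]))
    sum(sqrt(rowSums(d^2)))
  }, 0)
}

# random mask built from axis-aligned rectangles and disks, so every
# component stays 4-connected (a requirement of the ocontour oracle)
random_shape_mask <- function(h = 32L, w = 32L, n_rect = 2L, n_disk = 2L) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_rect)) {
    r0 <- sample(h - 4L, 1L); c0 <- sample(w - 4L, 1L)
    m[r0:min(h, r0 + sample(2:8, 1L)), c0:min(w, c0 + sample(2:8, 1L))] <- TRUE
  }
  for (i in seq_len(n_disk)) {
    cr <- runif(1, 4, h - 4); cc <- runif(1, 4, w - 4); rad <- runif(1, 1.5, 5)
    d2 <- outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, "+")
    m <- m | (d2 <= rad^2)
  }
  m
}

# fully random speckle mask (for the min/max filter oracles, which have no
# connectivity requirement)
random_speckle_mask <- function(h = 32L, w = 32L, p = 0.45) {
  matrix(runif(h * w) < p, h, w)
}

# small, quick synthetic scene used throughout the unit tests
small_spec <- function(seed, n_cells = 5L, ...) {
  synth_spec(height = 320L, width = 320L, n_cells = n_cells, seed = seed, ...)
}

# write a folder of small synthetic micrographs; returns the folder path
make_image_folder <- function(dir, seeds, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seeds) {
    out <- generate_micrograph(small_spec(seed = s, ...))
    tiff::writeTIFF(out$image$pixels / 255,
                    file.path(dir, sprintf("img_%03d.tif", s)),
                    bits.per.sample = 8L)
  }
  dir
}
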