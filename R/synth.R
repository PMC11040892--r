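#' Synthetic micrograph specification
#'
#' Describes an acridine-orange-like scene: red-dominant cytoplasm ellipses,
#' one bright green nucleus disk per cell, optional small green micronucleus
#' disks, optional elongated green debris, flat background and additive
#' Gaussian sensor noise. Geometry defaults emulate a 20x field: nucleus
#' radii 11-12.5 px, micronucleus radii 3-4.5 px, cytoplasm semi-axes 28-40 px.
#' The intensity defaults (cytoplasm red 140 +/- 15 with green bleed
#' 40 +/- 10, nuclear green 200 +/- 15 with red bleed 30 +/- 8, background 5,
#' noise sd 5) put the green histogram peak in the lowest threshold bin and
#' leave the sigmoid window at 118 separating cytoplasm from background.
#'
#' @param height,width Image size in pixels.
#' @param n_cells Number of cells to place.
#' @param mn_cell_rate Probability that a cell carries micronuclei.
#' @param mn_per_cell Integer range `c(min, max)` of micronuclei per
#'   micronucleated cell.
#' @param nucleus_radius,mn_radius Radius ranges in px. The micronucleus
#'   maximum must stay below the nucleus minimum.
#' @param cyto_axes Range of cytoplasm semi-axes in px.
#' @param clustering_prob Chance that a new cell is placed touching an
#'   existing one (exercises watershed separation).
#' @param margin Minimum clearance in px between non-touching cells
#'   (measured between circumscribed circles, so it is a guaranteed gap).
#' @param n_debris Number of elongated debris fragments placed inside cells.
#' @param debris_elong Range of debris length/width ratios. Widths are
#'   4.8-5.2 px (thick enough to survive the small-kernel cleaning in one
#'   piece), so the default elongations give chain circularities that pass
#'   the 0.5 default circularity cut but fall safely below the practical
#'   0.65 band.
#' @param intensity Named list overriding any of the intensity model entries
#'   `nucleus_green`, `nucleus_red`, `cyto_red`, `cyto_green` (each
#'   `c(mean, sd)`), `background`, `noise_sd`.
#' @param seed Integer seed; the same spec always renders the same image.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(height = 768L, width = 768L, n_cells = 30L,
                       mn_cell_rate = 0.2, mn_per_cell = c(1L, 2L),
                       nucleus_radius = c(11, 12.5), mn_radius = c(3, 4.5),
                       cyto_axes = c(28, 40), clustering_prob = 0,
                       margin = 5, n_debris = 0L, debris_elong = c(4.2, 4.6),
                       intensity = list(), seed = 1L) {
  base_int <- list(nucleus_green = c(200, 15), nucleus_red = c(30, 8),
                   cyto_red = c(140, 15), cyto_green = c(40, 10),
                   background = 5, noise_sd = 5)
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_cells = as.integer(n_cells), mn_cell_rate = mn_cell_rate,
               mn_per_cell = as.integer(mn_per_cell),
               nucleus_radius = nucleus_radius, mn_radius = mn_radius,
               cyto_axes = cyto_axes, clustering_prob = clustering_prob,
               margin = margin, n_debris = as.integer(n_debris),
               debris_elong = debris_elong,
               intensity = utils::modifyList(base_int, intensity),
               seed = as.integer(seed))
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(s) {
  stopifnot(inherits(s, "synth_spec"))
  if (s$height < 1L || s$width < 1L) stop("image size must be positive")
  if (s$n_cells < 0L || s$n_debris < 0L) stop("counts must be >= 0")
  if (s$mn_cell_rate < 0 || s$mn_cell_rate > 1)
    stop("mn_cell_rate must lie in [0, 1]")
  if (max(s$mn_radius) >= min(s$nucleus_radius))
    stop("micronucleus radii must stay below nucleus radii")
  if (s$clustering_prob < 0 || s$clustering_prob > 1)
    stop("clustering_prob must lie in [0, 1]")
  means <- c(s$intensity$nucleus_green[1], s$intensity$nucleus_red[1],
             s$intensity$cyto_red[1], s$intensity$cyto_green[1],
             s$intensity$background)
  if (any(means < 0 | means > 255)) stop("intensity means must lie in 0..255")
  invisible(s)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# radius of an ellipse (semi-axes a >= b, orientation phi) along direction
# theta from its center
ellipse_radius <- function(a, b, phi, theta) {
  t <- theta - phi
  a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic micrograph with ground truth
#'
#' Places cells by rejection sampling (non-touching cells keep at least
#' `margin` px between circumscribed circles; clustered cells are placed with
#' a 2 px overlap along the center line so their cytoplasm fuses), draws the
#' nucleus at the ellipse center, scatters micronuclei in the annulus between
#' nucleus and ellipse edge with at least 3 px edge-to-edge clearance, then
#' renders intensities and noise. Deterministic in `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return List with `image` (an `rgb_micrograph`) and `truth` (cell, mn and
#'   debris geometry plus `total_cells` / `mn_cells` counts).
#' @export
generate_micrograph <- function(spec) {
  validate_synth_spec(spec)
  with_seed(spec$seed, generate_micrograph_impl(spec))
}

generate_micrograph_impl <- function(spec) {
  H <- spec$height; W <- spec$width
  cells <- list(); mn_all <- list(); debris_all <- list()
  max_tries <- 400L

  for (i in seq_len(spec$n_cells)) {
    # geometry of cell i (sampled before placement so retries only move it)
    has_mn <- stats::runif(1) < spec$mn_cell_rate
    k_mn <- if (has_mn) {
      if (spec$mn_per_cell[1] == spec$mn_per_cell[2]) spec$mn_per_cell[1]
      else sample(spec$mn_per_cell[1]:spec$mn_per_cell[2], 1L)
    } else 0L
    mn_r <- if (k_mn > 0L) stats::runif(k_mn, spec$mn_radius[1], spec$mn_radius[2]) else numeric()
    r_n <- runif1(spec$nucleus_radius)
    b_need <- r_n + (if (k_mn > 0L) 2 * max(mn_r) else 0) + 5
    b_lo <- max(spec$cyto_axes[1], b_need)
    b_hi <- max(b_lo, spec$cyto_axes[2] - 4)
    b <- stats::runif(1, b_lo, b_hi)
    a <- stats::runif(1, b, spec$cyto_axes[2])
    phi <- stats::runif(1, 0, pi)

    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cluster <- length(cells) > 0L && stats::runif(1) < spec$clustering_prob
      if (cluster) {
        j <- if (length(cells) == 1L) 1L else sample(length(cells), 1L)
        ref <- cells[[j]]
        theta <- stats::runif(1, 0, 2 * pi)
        d <- ellipse_radius(ref$a, ref$b, ref$phi, theta) +
          ellipse_radius(a, b, phi, theta + pi) - 2  # 2 px overlap -> fused
        cr <- ref$center_r + d * sin(theta)
        cc <- ref$center_c + d * cos(theta)
        skip <- j
      } else {
        cr <- stats::runif(1, a + 3, H - a - 3)
        cc <- stats::runif(1, a + 3, W - a - 3)
        skip <- 0L
      }
      if (cr < a + 3 || cr > H - a - 3 || cc < a + 3 || cc > W - a - 3) next
      ok <- TRUE
      for (j2 in seq_along(cells)) {
        if (j2 == skip) next
        other <- cells[[j2]]
        if (sqrt((cr - other$center_r)^2 + (cc - other$center_c)^2) <
            a + other$a + spec$margin) { ok <- FALSE; break }
      }
      if (!ok) next
      cells[[i]] <- list(cell_id = i, center_r = cr, center_c = cc,
                         a = a, b = b, phi = phi, nucleus_r = r_n, n_mn = k_mn)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", spec$n_cells, " cells without forbidden overlap; ",
           "lower the density (fewer/smaller cells or a larger image)",
           call. = FALSE)

    # micronuclei: annulus between nucleus and ellipse edge, >= 3 px gaps
    cell <- cells[[i]]
    placed_mn <- list()
    for (q in seq_len(k_mn)) {
      r <- mn_r[q]
      inner <- r_n + r + 3
      outer <- b - r - 1  # within the inscribed circle: disk stays in the ellipse
      good <- FALSE
      for (try in seq_len(200L)) {
        if (outer <= inner) break
        theta <- stats::runif(1, 0, 2 * pi)
        rho <- stats::runif(1, inner, outer)
        mr <- cell$center_r + rho * sin(theta)
        mc <- cell$center_c + rho * cos(theta)
        clash <- FALSE
        for (pm in placed_mn)
          if (sqrt((mr - pm$center_r)^2 + (mc - pm$center_c)^2) < r + pm$radius + 3) {
            clash <- TRUE; break
          }
        if (!clash) {
          placed_mn[[length(placed_mn) + 1L]] <-
            list(cell_id = i, center_r = mr, center_c = mc, radius = r)
          good <- TRUE
          break
        }
      }
      if (!good)
        stop("could not place a micronucleus inside cell ", i,
             "; lower the density", call. = FALSE)
    }
    mn_all <- c(mn_all, placed_mn)
  }

  # debris: thin rotated rectangles inside randomly chosen cells
  if (spec$n_debris > 0L && spec$n_cells == 0L)
    stop("debris placement requires at least one cell", call. = FALSE)
  for (q in seq_len(spec$n_debris)) {
    good <- FALSE
    for (try in seq_len(400L)) {
      i <- if (length(cells) == 1L) 1L else sample(length(cells), 1L)
      cell <- cells[[i]]
      wid <- stats::runif(1, 4.8, 5.2)
      len <- wid * runif1(spec$debris_elong)
      theta <- stats::runif(1, 0, 2 * pi)
      rho <- stats::runif(1, cell$nucleus_r + wid + 4, cell$b - 3)
      if (!is.finite(rho) || rho <= 0) next
      dr <- cell$center_r + rho * sin(theta)
      dc <- cell$center_c + rho * cos(theta)
      orient <- theta + pi / 2 + stats::runif(1, -0.3, 0.3)  # roughly tangential
      cand <- list(cell_id = i, center_r = dr, center_c = dc,
                   length = len, width = wid, orient = orient)
      if (debris_fits(cand, cell, mn_all)) {
        debris_all[[length(debris_all) + 1L]] <- cand
        good <- TRUE
        break
      }
    }
    if (!good)
      stop("could not place debris fragment ", q, "; lower the density",
           call. = FALSE)
  }

  truth <- build_truth(cells, mn_all, debris_all, spec)
  pixels <- render_scene(cells, mn_all, debris_all, spec)
  img <- rgb_micrograph(pixels, path = sprintf("synthetic_seed%03d", spec$seed))
  list(image = img, truth = truth)
}

# all debris pixels must stay inside the host ellipse and >= 3 px away from
# the nucleus and every micronucleus edge
debris_fits <- function(d, cell, mn_all) {
  pix <- debris_pixels(d)
  if (nrow(pix) == 0L) return(FALSE)
  rel_r <- pix[, 1] - cell$center_r
  rel_c <- pix[, 2] - cell$center_c
  u <- (rel_r * sin(cell$phi) + rel_c * cos(cell$phi))
  v <- (rel_r * cos(cell$phi) - rel_c * sin(cell$phi))
  if (any((u / cell$a)^2 + (v / cell$b)^2 > 0.96)) return(FALSE)
  if (any(sqrt(rel_r^2 + rel_c^2) < cell$nucleus_r + 3)) return(FALSE)
  for (m in mn_all) {
    if (m$cell_id != cell$cell_id) next
    if (any(sqrt((pix[, 1] - m$center_r)^2 + (pix[, 2] - m$center_c)^2) <
            m$radius + 3)) return(FALSE)
  }
  TRUE
}

# pixel centers covered by a rotated rectangle
debris_pixels <- function(d) {
  half <- ceiling(d$length / 2 + 2)
  rr <- (floor(d$center_r) - half):(ceiling(d$center_r) + half)
  cc <- (floor(d$center_c) - half):(ceiling(d$center_c) + half)
  g <- expand.grid(r = rr, c = cc)
  relr <- g$r - d$center_r; relc <- g$c - d$center_c
  u <- relr * sin(d$orient) + relc * cos(d$orient)
  v <- relr * cos(d$orient) - relc * sin(d$orient)
  sel <- abs(u) <= d$length / 2 & abs(v) <= d$width / 2
  as.matrix(g[sel, , drop = FALSE])
}

build_truth <- function(cells, mn_all, debris_all, spec) {
  cell_df <- if (length(cells) == 0L) {
    data.frame(cell_id = integer(), center_r = numeric(), center_c = numeric(),
               axis_a = numeric(), axis_b = numeric(), angle = numeric(),
               nucleus_r = numeric(), n_mn = integer())
  } else {
    do.call(rbind, lapply(cells, function(x)
      data.frame(cell_id = x$cell_id, center_r = x$center_r, center_c = x$center_c,
                 axis_a = x$a, axis_b = x$b, angle = x$phi,
                 nucleus_r = x$nucleus_r, n_mn = x$n_mn)))
  }
  mn_df <- if (length(mn_all) == 0L) {
    data.frame(cell_id = integer(), center_r = numeric(), center_c = numeric(),
               radius = numeric())
  } else do.call(rbind, lapply(mn_all, as.data.frame))
  debris_df <- if (length(debris_all) == 0L) {
    data.frame(cell_id = integer(), center_r = numeric(), center_c = numeric(),
               length = numeric(), width = numeric(), orient = numeric())
  } else do.call(rbind, lapply(debris_all, as.data.frame))
  list(cells = cell_df, mn = mn_df, debris = debris_df,
       total_cells = nrow(cell_df), mn_cells = sum(cell_df$n_mn > 0L),
       seed = spec$seed)
}

render_scene <- function(cells, mn_all, debris_all, spec) {
  H <- spec$height; W <- spec$width
  ints <- spec$intensity
  cyto <- matrix(FALSE, H, W)
  nuc <- matrix(FALSE, H, W)
  for (cell in cells) {
    half <- ceiling(cell$a) + 1L
    rr <- max(1L, floor(cell$center_r) - half):min(H, ceiling(cell$center_r) + half)
    cc <- max(1L, floor(cell$center_c) - half):min(W, ceiling(cell$center_c) + half)
    relr <- outer(rr - cell$center_r, rep(1, length(cc)))
    relc <- outer(rep(1, length(rr)), cc - cell$center_c)
    u <- relr * sin(cell$phi) + relc * cos(cell$phi)
    v <- relr * cos(cell$phi) - relc * sin(cell$phi)
    cyto[rr, cc] <- cyto[rr, cc] | ((u / cell$a)^2 + (v / cell$b)^2 <= 1)
    nuc[rr, cc] <- nuc[rr, cc] | (relr^2 + relc^2 <= cell$nucleus_r^2)
  }
  add_disk <- function(mask, cr, cc0, rad) {
    rr <- max(1L, floor(cr - rad)):min(H, ceiling(cr + rad))
    cc <- max(1L, floor(cc0 - rad)):min(W, ceiling(cc0 + rad))
    d2 <- outer((rr - cr)^2, (cc - cc0)^2, "+")
    mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
    mask
  }
  for (m in mn_all) nuc <- add_disk(nuc, m$center_r, m$center_c, m$radius)
  for (d in debris_all) {
    pix <- debris_pixels(d)
    pix <- pix[pix[, 1] >= 1 & pix[, 1] <= H & pix[, 2] >= 1 & pix[, 2] <= W, , drop = FALSE]
    nuc[pix] <- TRUE
  }
  red <- matrix(ints$background, H, W)
  green <- matrix(ints$background, H, W)
  blue <- matrix(ints$background, H, W)
  idx_c <- which(cyto & !nuc)
  red[idx_c] <- stats::rnorm(length(idx_c), ints$cyto_red[1], ints$cyto_red[2])
  green[idx_c] <- stats::rnorm(length(idx_c), ints$cyto_green[1], ints$cyto_green[2])
  idx_n <- which(nuc)
  green[idx_n] <- stats::rnorm(length(idx_n), ints$nucleus_green[1], ints$nucleus_green[2])
  red[idx_n] <- stats::rnorm(length(idx_n), ints$nucleus_red[1], ints$nucleus_red[2])
  n <- H * W
  pixels <- array(0, dim = c(H, W, 3L))
  pixels[, , 1] <- red + stats::rnorm(n, 0, ints$noise_sd)
  pixels[, , 2] <- green + stats::rnorm(n, 0, ints$noise_sd)
  pixels[, , 3] <- blue + stats::rnorm(n, 0, ints$noise_sd)
  pixels[] <- round(pmin(pmax(pixels, 0), 255))
  pixels
}

#' Generate a seeded dose series of synthetic micrographs
#'
#' One folder per dose group, each holding `images_per_dose` TIFF micrographs
#' plus a `truth.tsv` (per-image ground-truth counts) and one JSON scene file
#' per image. Each image gets its own RNG stream derived as
#' `seed + image index`, so a folder can be regenerated partially and still
#' match. The realized micronucleated fraction of a dose is a Binomial draw
#' with that dose's requested rate.
#'
#' @param base_spec A [synth_spec()] supplying everything but the rate/seed.
#' @param doses Character or numeric dose labels.
#' @param mn_rate_per_dose Micronucleated-cell rate for each dose (same
#'   length as `doses`).
#' @param images_per_dose Number of images per dose group.
#' @param out_dir Output root directory.
#' @param seed Integer base seed.
#' @return Manifest data.frame (dose, image path, truth counts), invisibly.
#' @export
generate_dose_series <- function(base_spec, doses, mn_rate_per_dose,
                                 images_per_dose, out_dir, seed = 1L) {
  stopifnot(length(doses) == length(mn_rate_per_dose), images_per_dose >= 1L)
  validate_synth_spec(base_spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  idx <- 0L
  for (i in seq_along(doses)) {
    dose_dir <- file.path(out_dir, paste0("dose_", doses[i]))
    dir.create(dose_dir, showWarnings = FALSE)
    rows <- list()
    for (j in seq_len(images_per_dose)) {
      idx <- idx + 1L
      spec <- base_spec
      spec$mn_cell_rate <- mn_rate_per_dose[i]
      spec$seed <- as.integer(seed + idx)
      out <- generate_micrograph(spec)
      img_name <- sprintf("img_%03d", j)
      img_path <- file.path(dose_dir, paste0(img_name, ".tif"))
      tiff::writeTIFF(out$image$pixels / 255, img_path, bits.per.sample = 8L)
      jsonlite::write_json(out$truth, file.path(dose_dir, paste0(img_name, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      rows[[j]] <- data.frame(dose = doses[i], image = img_name,
                              total_cells = out$truth$total_cells,
                              mn_cells = out$truth$mn_cells)
    }
    truth_df <- do.call(rbind, rows)
    utils::write.table(truth_df[, c("image", "total_cells", "mn_cells")],
                       file.path(dose_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[i]] <- truth_df
  }
  invisible(do.call(rbind, manifest))
}
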