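disk_mask <- function(h, w, cr, cc, r) {
  outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, "+") <= r^2
}

test_that("erosion partitions blobs into nuclei and micronucleus candidates", {
  m <- matrix(FALSE, 64, 64)
  m <- m | disk_mask(64, 64, 22, 22, 20)   # nucleus-sized
  m <- m | disk_mask(64, 64, 50, 52, 3)    # micronucleus-sized
  out <- classify_blobs_by_erosion(m, 13)
  # the big disk survives a 13x13 erosion (brute-force check) and is
  # restored to its full original extent
  expect_true(any(naive_erode(disk_mask(64, 64, 22, 22, 20), 13)))
  expect_identical(out$nuclei, disk_mask(64, 64, 22, 22, 20))
  # the small disk is erased by the same erosion (brute-force check)
  expect_false(any(naive_erode(disk_mask(64, 64, 50, 52, 3), 13)))
  expect_identical(out$mn_candidates, disk_mask(64, 64, 50, 52, 3))
  # partition: disjoint, union equals input
  expect_false(any(out$nuclei & out$mn_candidates))
  expect_identical(out$nuclei | out$mn_candidates, m)
  # empty input gives two empty outputs
  e <- classify_blobs_by_erosion(matrix(FALSE, 8, 8), 13)
  expect_false(any(e$nuclei) || any(e$mn_candidates))
})

test_that("erosion partition holds on random masks", {
  set.seed(41)
  for (i in 1:8) {
    m <- random_shape_mask(40, 40, n_rect = 3, n_disk = 3)
    out <- classify_blobs_by_erosion(m, 9)
    expect_false(any(out$nuclei & out$mn_candidates))
    expect_identical(out$nuclei | out$mn_candidates, m)
    # every nucleus component individually survives brute-force erosion
    lab <- label_regions(out$nuclei)
    for (l in seq_len(max(lab, 0L)))
      expect_true(any(naive_erode(lab == l, 9)))
    lab <- label_regions(out$mn_candidates)
    for (l in seq_len(max(lab, 0L)))
      expect_false(any(naive_erode(lab == l, 9)))
  }
})

test_that("cytoplasm mask fills rings and separates disjoint blobs", {
  p <- detection_params()
  # bright red ring around a dark interior: interior filled
  red <- matrix(0L, 60, 60)
  ring <- disk_mask(60, 60, 30, 30, 20) & !disk_mask(60, 60, 30, 30, 12)
  red[ring] <- 180L
  cyto <- cytoplasm_mask(red, matrix(0L, 60, 60), p)
  expect_true(all(cyto[disk_mask(60, 60, 30, 30, 19)]))
  # two disjoint bright blobs: two components (flood-fill oracle)
  red2 <- matrix(0L, 60, 60)
  red2[disk_mask(60, 60, 15, 15, 8)] <- 200L
  red2[disk_mask(60, 60, 45, 45, 8)] <- 200L
  cyto2 <- cytoplasm_mask(red2, matrix(0L, 60, 60), p)
  expect_identical(flood_count(cyto2), 2L)
  # blank channels give an empty mask
  expect_false(any(cytoplasm_mask(matrix(0L, 20, 20), matrix(0L, 20, 20), p)))
})

test_that("watershed separation cuts a symmetric dumbbell at the bisector", {
  h <- 90; w <- 140
  cyto <- disk_mask(h, w, 45, 45, 28) | disk_mask(h, w, 45, 95, 28)
  nuclei <- disk_mask(h, w, 45, 45, 8) | disk_mask(h, w, 45, 95, 8)
  cells <- separate_cells(cyto, nuclei)
  expect_identical(sort(unique(cells[cells > 0L])), c(1L, 2L))
  # the dividing line lies within 2 px of the perpendicular bisector (col 70)
  for (row in 30:60) {
    lab <- cells[row, ]
    if (!any(lab == 1L) || !any(lab == 2L)) next
    expect_lte(abs(max(which(lab == 1L)) - 70), 2)
    expect_lte(abs(min(which(lab == 2L)) - 70), 2)
  }
  # watershed-line pixels belong to no cell
  expect_true(any(cells == 0L & cyto))

  # one nucleus in one blob: a single label covering the blob
  one <- separate_cells(disk_mask(60, 60, 30, 30, 20), disk_mask(60, 60, 30, 30, 7))
  expect_identical(unique(one[disk_mask(60, 60, 30, 30, 20)]), 1L)
  # marker-free blob stays unlabeled
  none <- separate_cells(disk_mask(60, 60, 30, 30, 20), matrix(FALSE, 60, 60))
  expect_identical(max(none), 0L)
})

test_that("micronucleus filtering is a monotone area/circularity cut", {
  m <- matrix(FALSE, 40, 60)
  m[5:7, 5:19] <- TRUE                      # 3x15 bar, circularity 0.55
  m <- m | disk_mask(40, 60, 25, 40, 4)     # round spot
  m[35, 50] <- TRUE                         # single noise pixel
  tab <- measure_regions(m)
  base <- detection_params(noise_reduction = 11, micronucleus_th = 0.5)
  kept <- filter_micronuclei(tab, base)
  expect_identical(nrow(kept), 2L)          # noise pixel removed (area 1 < 11)
  kept6 <- filter_micronuclei(tab, detection_params(micronucleus_th = 0.6))
  expect_identical(nrow(kept6), 1L)         # bar rejected at 0.6
  expect_gt(min(kept6$circularity), 0.9)
  # area 8 blob removed at noise cut 11
  small <- measure_regions(disk_mask(20, 20, 10, 10, 1.5))
  expect_identical(small$area, 9L)
  expect_identical(nrow(filter_micronuclei(small, base)), 0L)
  # nesting: accepted set at 0.7 is a subset of the accepted set at 0.5
  set.seed(53)
  for (i in 1:5) {
    tab <- measure_regions(random_shape_mask(32, 32))
    hi <- filter_micronuclei(tab, detection_params(micronucleus_th = 0.7))
    lo <- filter_micronuclei(tab, detection_params(micronucleus_th = 0.5))
    expect_true(all(hi$label %in% lo$label))
  }
})

test_that("cell classification assigns micronuclei by centroid containment", {
  cells <- matrix(0L, 40, 40)
  cells[5:18, 5:18] <- 1L
  cells[25:38, 25:38] <- 2L
  mn <- data.frame(label = 1:3,
                   area = c(12, 12, 12),
                   centroid_r = c(10, 14, 2),
                   centroid_c = c(10, 12, 39))
  rec <- classify_cells(cells, mn)
  expect_identical(nrow(rec), 2L)
  # two micronuclei in the same cytoplasm: still one micronucleated cell
  expect_identical(rec$n_mn[rec$cell_id == 1L], 2L)
  expect_identical(sum(rec$is_mn_cell), 1L)
  # centroid outside every cell label is counted nowhere
  expect_identical(rec$n_mn[rec$cell_id == 2L], 0L)
  # no micronuclei: all normal cells
  rec0 <- classify_cells(cells, mn[0, ])
  expect_false(any(rec0$is_mn_cell))
})

test_that("full analysis recovers synthetic ground truth and is deterministic", {
  out <- generate_micrograph(small_spec(seed = 3, n_cells = 6))
  res1 <- analyze_image(out$image)
  expect_identical(res1$total_cells, out$truth$total_cells)
  expect_identical(res1$mn_cells, out$truth$mn_cells)
  expect_identical(res1$total_cells, nrow(res1$cells))
  expect_lte(res1$mn_cells, res1$total_cells)
  # re-running gives bit-identical masks and counts
  res2 <- analyze_image(out$image)
  expect_identical(res1$masks, res2$masks)
  expect_identical(res1$mn, res2$mn)
  # blank image: zero counts (with the degenerate-parameter warning)
  blank <- rgb_micrograph(array(0L, c(64, 64, 3)))
  suppressWarnings(res0 <- analyze_image(blank))
  expect_identical(res0$total_cells, 0L)
  expect_identical(res0$mn_cells, 0L)
})

test_that("counts are invariant under rotations and reflection", {
  out <- generate_micrograph(small_spec(seed = 8, n_cells = 5))
  px <- out$image$pixels
  ref <- analyze_image(out$image)
  rot90 <- function(a) {
    b <- array(0L, c(dim(a)[2], dim(a)[1], 3))
    for (ch in 1:3) b[, , ch] <- t(a[dim(a)[1]:1, , ch])
    b
  }
  variants <- list(rot90(px), rot90(rot90(px)), rot90(rot90(rot90(px))),
                   px[, dim(px)[2]:1, , drop = FALSE])
  for (v in variants) {
    r <- analyze_image(rgb_micrograph(v))
    expect_identical(r$total_cells, ref$total_cells)
    expect_identical(r$mn_cells, ref$mn_cells)
  }
})

test_that("raising thresholds never increases the micronucleated count", {
  out <- generate_micrograph(small_spec(seed = 12, n_cells = 6, n_debris = 2))
  p0 <- analyze_image(out$image)$params
  prev <- Inf
  for (th in c(0.5, 0.65, 0.9)) {
    r <- analyze_image(out$image, mncount:::merge_params(p0, list(micronucleus_th = th)))
    expect_lte(r$mn_cells, prev)
    expect_identical(r$total_cells, out$truth$total_cells)  # unaffected
    prev <- r$mn_cells
  }
  lo <- analyze_image(out$image, mncount:::merge_params(p0, list(noise_reduction = 11)))
  hi <- analyze_image(out$image, mncount:::merge_params(p0, list(noise_reduction = 40)))
  expect_lte(hi$mn_cells, lo$mn_cells)
  expect_identical(hi$total_cells, out$truth$total_cells)
})
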