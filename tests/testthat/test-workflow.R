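test_that("initial analysis builds the full artifact tree deterministically", {
  tmp <- withr::local_tempdir()
  folder <- make_image_folder(file.path(tmp, "imgs"), seeds = 1:3, n_cells = 4)
  run <- initial_analysis(folder, file.path(tmp, "res"))
  expect_length(run$results, 3L)
  expect_length(run$failed, 0L)

  # one artifact per image in each folder, one Palam per image + PalamLock
  for (sub in c("Grayscale", "Count", "Shokaku", "Image"))
    expect_length(list.files(file.path(tmp, "res", sub)), 3L)
  palams <- list.files(file.path(tmp, "res", "Palam"))
  expect_setequal(palams, c("img_001.txt", "img_002.txt", "img_003.txt",
                            "PalamLock.txt"))
  # PalamLock is seeded from the first image's parameters
  expect_identical(readLines(file.path(tmp, "res", "Palam", "PalamLock.txt")),
                   readLines(file.path(tmp, "res", "Palam", "img_001.txt")))
  # counts: 3 rows + total, sums consistent, counts match the truth
  counts <- readLines(file.path(tmp, "res", "Text", "counts.txt"))
  expect_length(counts, 4L)
  for (s in 1:3) {
    truth <- generate_micrograph(small_spec(seed = s, n_cells = 4))$truth
    expect_identical(counts[s], sprintf("img_%03d\t%d\t%d", s,
                                        truth$total_cells, truth$mn_cells))
  }

  # re-running into a fresh root reproduces the text artifacts byte for byte
  run2 <- initial_analysis(folder, file.path(tmp, "res2"))
  expect_identical(readLines(file.path(tmp, "res2", "Text", "counts.txt")), counts)
  expect_identical(readLines(file.path(tmp, "res2", "Palam", "PalamLock.txt")),
                   readLines(file.path(tmp, "res", "Palam", "PalamLock.txt")))
})

test_that("corrupt images are skipped and reported, not fatal", {
  tmp <- withr::local_tempdir()
  folder <- make_image_folder(file.path(tmp, "imgs"), seeds = 1:2, n_cells = 4)
  writeLines("not an image", file.path(folder, "img_000.tif"))
  suppressMessages(run <- initial_analysis(folder, file.path(tmp, "res")))
  expect_length(run$results, 2L)
  expect_named(run$failed, "img_000")
  counts <- readLines(file.path(tmp, "res", "Text", "counts.txt"))
  expect_length(counts, 3L)  # 2 rows + total
  expect_error(initial_analysis(file.path(tmp, "empty"), file.path(tmp, "r")),
               "not found")
})

test_that("individual reanalysis overrides stored parameters for one image", {
  tmp <- withr::local_tempdir()
  folder <- make_image_folder(file.path(tmp, "imgs"), seeds = 5, n_cells = 5,
                              n_debris = 2)
  img <- file.path(folder, "img_005.tif")
  root <- file.path(tmp, "res")
  expect_error(individual_reanalysis(img, root), "initial_analysis")
  run <- initial_analysis(folder, root)
  stored <- run$results[["img_005"]]

  # no overrides: identical to the stored result
  same <- individual_reanalysis(img, root)
  expect_identical(same$total_cells, stored$total_cells)
  expect_identical(same$mn_cells, stored$mn_cells)
  expect_identical(same$params, stored$params)

  # raising the circularity threshold can only lower the MN-cell count
  strict <- individual_reanalysis(img, root, list(micronucleus_th = 0.9))
  expect_lte(strict$mn_cells, stored$mn_cells)
  expect_identical(strict$total_cells, stored$total_cells)
  # the override is persisted in that image's Palam file only
  p <- read_palam(file.path(root, "Palam", "img_005.txt"))
  expect_identical(p$micronucleus_th, 0.9)
  lock <- read_palam(file.path(root, "Palam", "PalamLock.txt"))
  expect_identical(lock$micronucleus_th, 0.5)
  # the counts row was rewritten consistently
  counts <- readLines(file.path(root, "Text", "counts.txt"))
  expect_identical(counts[1], sprintf("img_005\t%d\t%d", strict$total_cells,
                                      strict$mn_cells))
})

test_that("debris is rejected by raising the circularity threshold", {
  # one round micronucleus plus elongated debris: at 0.65 only the true
  # micronucleus survives the filter
  spec <- small_spec(seed = 9, n_cells = 5, mn_cell_rate = 0.2,
                     mn_per_cell = c(1L, 1L), n_debris = 3)
  out <- generate_micrograph(spec)
  expect_identical(out$truth$mn_cells, 1L)
  res <- analyze_image(out$image)
  strict <- analyze_image(out$image,
                          mncount:::merge_params(res$params,
                                                 list(micronucleus_th = 0.65)))
  expect_identical(strict$mn_cells, 1L)
  expect_identical(strict$total_cells, out$truth$total_cells)
})

test_that("batch reanalysis applies one parameter set everywhere, idempotently", {
  tmp <- withr::local_tempdir()
  folder <- make_image_folder(file.path(tmp, "imgs"), seeds = 1:3, n_cells = 4)
  root <- file.path(tmp, "res")
  run <- initial_analysis(folder, root)
  counts0 <- readLines(file.path(root, "Text", "counts.txt"))

  # batch with the untouched PalamLock (same auto params) is idempotent
  run_b <- batch_reanalysis(folder, root)
  expect_identical(readLines(file.path(root, "Text", "counts.txt")), counts0)
  for (nm in names(run$results))
    expect_identical(run_b$results[[nm]]$total_cells,
                     run$results[[nm]]$total_cells)
  # every per-image Palam file now equals the lock, byte for byte
  lock <- readLines(file.path(root, "Palam", "PalamLock.txt"))
  for (f in sprintf("img_%03d.txt", 1:3))
    expect_identical(readLines(file.path(root, "Palam", f)), lock)

  # a stricter lock can only lower the total MN count
  strict_lock <- file.path(tmp, "lock.txt")
  p <- read_palam(file.path(root, "Palam", "PalamLock.txt"))
  write_palam(mncount:::merge_params(p, list(micronucleus_th = 0.9)), strict_lock)
  run_s <- batch_reanalysis(folder, root, palamlock = strict_lock)
  expect_lte(sum(vapply(run_s$results, `[[`, 0L, "mn_cells")),
             sum(vapply(run$results, `[[`, 0L, "mn_cells")))
  expect_error(batch_reanalysis(folder, root,
                                palamlock = file.path(tmp, "none.txt")),
               "not found")
})
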