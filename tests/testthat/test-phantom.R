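test_that("truncated-normal draws respect bounds and degenerate limits", {
  set.seed(1)
  x <- rnorm_truncated(2000, 0.1, 0.3, 0.02, 0.95)
  expect_length(x, 2000)
  expect_true(all(x > 0.02 & x < 0.95))
  expect_identical(rnorm_truncated(5, 0.3, 0, 0, 1), rep(0.3, 5))
  expect_identical(rnorm_truncated(0, 0.3, 0.1), numeric(0))
  expect_error(rnorm_truncated(1, 2, 0, 0, 1), "degenerate")
})

test_that("cohorts are deterministic with the requested composition", {
  p <- tiny_params()
  expect_identical(sample_cohort(0, 0, p, seed = 3), list())
  a <- sample_cohort(3, 2, p, seed = 9)
  b <- sample_cohort(3, 2, p, seed = 9)
  expect_identical(a, b)
  expect_equal(sum(vapply(a, `[[`, "", "stage") == "IA"), 3)
  expect_equal(sum(vapply(a, `[[`, "", "stage") == "IB"), 2)
  for (cs in a) expect_named(cs$slices, TUR_SEQUENCES)
})

test_that("zero-variance TUR distributions collapse to the mean", {
  p <- tiny_params()
  for (s in TUR_SEQUENCES) {
    p[[s]]$tur_ia_sd <- 0
    p[[s]]$tur_ib_sd <- 0
  }
  coh <- sample_cohort(2, 2, p, seed = 4)
  for (cs in coh)
    for (sq in TUR_SEQUENCES) {
      expected <- if (cs$stage == "IA") p[[sq]]$tur_ia_mean else p[[sq]]$tur_ib_mean
      expect_equal(cs$slices[[sq]]$intended_tur, expected)
    }
})

test_that("sagittal IA intended TURs match the stage-conditional mean", {
  coh <- sample_cohort(22, 13, tiny_params(48), seed = 21)
  ia <- Filter(function(cs) cs$stage == "IA", coh)
  turs <- vapply(ia, function(cs) cs$slices$sagittal_t2w$intended_tur, 0)
  # population mean 0.103, SD 0.077; allow 3 standard errors at n = 22
  expect_lt(abs(mean(turs) - 0.103), 3 * 0.077 / sqrt(22))
})

test_that("rendered slices hit the intended TUR and stay geometrically sane", {
  p <- phantom_params("axial_t2w", image_size = 64)
  sl <- render_slice("IB", "axial_t2w", 0.5, p, seed = 5)
  expect_true(abs(sl$realized_tur - 0.5) <= 0.01)
  organ_frac <- mean(sl$mask != 0)
  expect_gte(organ_frac, 0.05)
  expect_lte(organ_frac, 0.5)
  # tumor is one 4-connected component inside the organ
  tum <- sl$mask == 2
  comp <- matrix(FALSE, nrow(tum), ncol(tum))
  seedpx <- which(tum, arr.ind = TRUE)[1, ]
  frontier <- matrix(seedpx, ncol = 2)
  comp[frontier] <- TRUE
  while (nrow(frontier) > 0) {
    nb <- rbind(frontier + rep(c(1, 0), each = nrow(frontier)),
                frontier + rep(c(-1, 0), each = nrow(frontier)),
                frontier + rep(c(0, 1), each = nrow(frontier)),
                frontier + rep(c(0, -1), each = nrow(frontier)))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(tum) &
               nb[, 2] >= 1 & nb[, 2] <= ncol(tum), , drop = FALSE]
    nb <- nb[tum[nb] & !comp[nb], , drop = FALSE]
    comp[nb] <- TRUE
    frontier <- unique(nb)
  }
  expect_identical(comp, tum)
})

test_that("the noiseless limit has exactly three intensity levels", {
  p <- phantom_params("sagittal_t2w", image_size = 32, noise_sd = 0)
  sl <- render_slice("IA", "sagittal_t2w", 0.2, p, seed = 8)
  expect_length(unique(as.vector(sl$image)), 3)
})

test_that("seeded rendering is bit-identical", {
  p <- phantom_params("axial_dwi", image_size = 32)
  a <- render_slice("IA", "axial_dwi", 0.3, p, seed = 11)
  b <- render_slice("IA", "axial_dwi", 0.3, p, seed = 11)
  expect_identical(a, b)
})

test_that("the distractor preset paints a bright blob outside the organ", {
  p <- phantom_params("axial_t2w", image_size = 64, noise_sd = 0,
                      distractor_prob = 1)
  sl <- render_slice("IA", "axial_t2w", 0.2, p, seed = 13)
  tumor_level <- max(sl$image)
  expect_true(any(sl$image == tumor_level & sl$mask == 0))
})

test_that("cohorts round-trip through PNG plus manifest losslessly", {
  dir <- withr::local_tempdir()
  coh <- sample_cohort(1, 1, tiny_params(), seed = 6)
  man <- write_cohort(coh, dir)
  expect_equal(nrow(man), 6)  # 2 cases x 3 sequences
  expect_identical(
    names(man),
    c("patient_id", "stage", "sequence", "image_path", "mask_path",
      "intended_tur"))
  m <- read_mask(file.path(dir, man$mask_path[1]))
  expect_identical(m, coh[[1]]$slices[[man$sequence[1]]]$mask)
  img <- read_image(file.path(dir, man$image_path[1]))
  expect_lt(max(abs(img - coh[[1]]$slices[[man$sequence[1]]]$image)), 0.51)

  # identical seed => byte-identical files
  dir2 <- withr::local_tempdir()
  write_cohort(sample_cohort(1, 1, tiny_params(), seed = 6), dir2)
  f1 <- list.files(dir, recursive = TRUE)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))))

  # empty cohort: manifest with header only
  dir3 <- withr::local_tempdir()
  man0 <- write_cohort(list(), dir3)
  expect_equal(nrow(man0), 0)
  expect_equal(nrow(read.csv(file.path(dir3, "manifest.csv"))), 0)
})

test_that("invalid phantom parameters name the offending field", {
  expect_error(phantom_params("axial_t2w", image_size = 16), "image_size")
  expect_error(phantom_params("axial_t2w", tur_ia_mean = 1.5), "tur_ia_mean")
  expect_error(phantom_params("axial_t2w", distractor_prob = 2),
               "distractor_prob")
  expect_error(phantom_params("axial_t2w", noise_sd = -1), "noise_sd")
  expect_error(sample_cohort(2, 2, list(), seed = 1), "params")
})
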