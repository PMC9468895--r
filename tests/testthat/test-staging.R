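test_that("TUR is the tumor share of the organ pixel count", {
  expect_equal(compute_tur(flat_mask(10, 10, nu = 70, nt = 30)), 0.30)
  expect_equal(compute_tur(flat_mask(4, 4, nu = 9, nt = 0)), 0)
  expect_equal(compute_tur(flat_mask(4, 4, nu = 0, nt = 5)), 1)
  expect_error(compute_tur(matrix(0L, 4, 4)), "empty segmentation")
})

test_that("ROC endpoints: perfect separation gives 1, pure ties give 0.5", {
  r <- roc_curve(c(0.1, 0.2, 0.6, 0.7), c("IA", "IA", "IB", "IB"))
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_criterion, 1)
  expect_equal(r$spec_at_criterion, 1)
  expect_equal(r$criterion, 0.6)  # smallest threshold with maximal J

  tied <- roc_curve(rep(0.3, 6), c("IA", "IA", "IA", "IB", "IB", "IB"))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_curve(c(0.1, 0.2), c("IA", "IA")), "both stages")
})

test_that("trapezoid AUC equals brute-force Mann-Whitney with ties 1/2", {
  set.seed(5)
  for (rep in 1:20) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    # coarse grid forces plenty of ties
    tur <- round(runif(n0 + n1), 1)
    stage <- c(rep("IA", n0), rep("IB", n1))
    r <- roc_curve(tur, stage)
    expect_equal(r$auc, mw_auc(tur[stage == "IB"], tur[stage == "IA"]),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(8)
  tur <- runif(30)
  stage <- sample(c("IA", "IB"), 30, TRUE, prob = c(0.6, 0.4))
  if (length(unique(stage)) == 2) {
    a1 <- roc_curve(tur, stage)$auc
    expect_equal(roc_curve(tur^3, stage)$auc, a1, tolerance = 1e-12)
    expect_equal(roc_curve(log(tur + 1), stage)$auc, a1, tolerance = 1e-12)
  }
})

test_that("AUC and Youden criterion agree with an independent ROC library", {
  set.seed(17)
  tur <- c(rnorm_truncated(40, 0.15, 0.08), rnorm_truncated(30, 0.33, 0.12))
  stage <- c(rep("IA", 40), rep("IB", 30))
  r <- roc_curve(tur, stage)
  pr <- pROC::roc(response = stage, predictor = tur, levels = c("IA", "IB"),
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  best <- pROC::coords(pr, "best", best.method = "youden", transpose = FALSE)
  expect_equal(r$sens_at_criterion + r$spec_at_criterion,
               best$sensitivity + best$specificity, tolerance = 1e-10)
})

test_that("the Gaussian AUC oracle matches its closed form", {
  expect_equal(gaussian_auc(0.2, 0.1, 0.2, 0.1), 0.5)
  expect_equal(gaussian_auc(0.01, 0.001, 0.99, 0.001), 1, tolerance = 1e-9)
  expect_equal(gaussian_auc(0.103, 0.077, 0.334, 0.125),
               pnorm(0.231 / sqrt(0.077^2 + 0.125^2)))
  expect_equal(round(gaussian_auc(0.103, 0.077, 0.334, 0.125), 3), 0.942)
  expect_error(gaussian_auc(0.1, 0, 0.3, 0.1), "positive")
})

test_that("classification uses the inclusive >= threshold rule", {
  expect_equal(classify_stage(0.30, 0.198), "IB")
  expect_equal(classify_stage(0.198, 0.198), "IB")
  expect_equal(classify_stage(0.05, 0.198), "IA")
  expect_equal(classify_stage(c(0.1, 0.5), 0.2), c("IA", "IB"))
  expect_error(classify_stage(0.5, 1.5), "criterion")
})

test_that("k-of-n fusion counts IB votes", {
  votes <- c(axial_t2w = "IB", axial_dwi = "IA", sagittal_t2w = "IA")
  expect_equal(fuse_votes(votes, fusion_rule("k_of_n", 1)), "IB")
  expect_equal(fuse_votes(votes, fusion_rule("k_of_n", 2)), "IA")
  all_ib <- c(axial_t2w = "IB", axial_dwi = "IB", sagittal_t2w = "IB")
  for (k in 1:3)
    expect_equal(fuse_votes(all_ib, fusion_rule("k_of_n", k)), "IB")
  two_ib <- c(axial_t2w = "IB", axial_dwi = "IB", sagittal_t2w = "IA")
  expect_equal(fuse_votes(two_ib, fusion_rule("k_of_n", 3)), "IA")
  expect_error(fuse_votes(votes[1:2], fusion_rule("k_of_n", 2)),
               "sagittal_t2w")
  single <- fusion_rule("single", sequences = "sagittal_t2w")
  expect_equal(fuse_votes(c(sagittal_t2w = "IB"), single), "IB")
  expect_error(fusion_rule("k_of_n", 4), "k must lie")
})

test_that("staging performance reproduces the clinical operating point", {
  # 22 IA / 13 IB cohort, 12 of 13 IB and 20 of 22 IA called correctly
  truth <- c(rep("IA", 22), rep("IB", 13))
  pred <- c(rep("IA", 20), rep("IB", 2), rep("IB", 12), "IA")
  perf <- evaluate_staging(pred, truth)
  expect_equal(perf$accuracy, 32 / 35)
  expect_equal(round(perf$accuracy, 3), 0.914)
  expect_equal(round(perf$sensitivity, 3), 0.923)
  expect_equal(round(perf$specificity, 3), 0.909)

  all_good <- evaluate_staging(truth, truth)
  expect_equal(all_good$accuracy, 1)
  expect_equal(all_good$sensitivity, 1)
  expect_equal(all_good$specificity, 1)

  degenerate <- evaluate_staging(rep("IA", 35), truth)
  expect_equal(degenerate$specificity, 1)
  expect_equal(degenerate$sensitivity, 0)

  one_class <- evaluate_staging(rep("IA", 3), rep("IA", 3))
  expect_true(is.na(one_class$sensitivity))
  expect_equal(one_class$specificity, 1)
})

test_that("accuracy decomposes exactly into sens/spec weighted by class size", {
  set.seed(23)
  for (rep in 1:20) {
    n_ia <- sample(3:30, 1); n_ib <- sample(3:30, 1)
    truth <- c(rep("IA", n_ia), rep("IB", n_ib))
    pred <- sample(c("IA", "IB"), n_ia + n_ib, TRUE)
    p <- evaluate_staging(pred, truth)
    expect_equal(p$accuracy,
                 (p$sensitivity * n_ib + p$specificity * n_ia) / (n_ia + n_ib),
                 tolerance = 1e-12)
  }
})

test_that("cohort staging applies per-sequence criteria then fuses", {
  tt <- data.frame(
    patient_id = rep(c("P1", "P2"), each = 3),
    sequence = rep(TUR_SEQUENCES, 2),
    tur = c(0.25, 0.40, 0.30, 0.10, 0.05, 0.15),
    true_stage = rep(c("IB", "IA"), each = 3))
  crit <- c(axial_t2w = 0.207, axial_dwi = 0.331, sagittal_t2w = 0.198)
  rep2 <- stage_cohort(tt, crit, fusion_rule("k_of_n", 2))
  expect_equal(rep2$fused, c("IB", "IA"))
  expect_equal(rep2$vote_axial_t2w, c("IB", "IA"))
  expect_error(stage_cohort(tt[-2, ], crit, fusion_rule("k_of_n", 2)),
               "axial_dwi")
})
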