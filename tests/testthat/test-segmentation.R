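# tiny noiseless slice set for capacity / sanity checks
noiseless_set <- function(n, size = 32, seed = 100) {
  p <- phantom_params("sagittal_t2w", image_size = size, noise_sd = 0)
  lapply(seq_len(n), function(i) {
    sl <- render_slice("IA", "sagittal_t2w", 0.2 + 0.05 * i, p,
                       seed = seed + i)
    list(image = sl$image, mask = sl$mask)
  })
}

test_that("configuration bounds are enforced with the field name", {
  expect_error(unet_config(depth = 1), "depth")
  expect_error(unet_config(in_size = 100, depth = 4), "divisible")
  expect_error(unet_config(learning_rate = -1), "learning_rate")
  expect_error(unet_config(max_epochs = 0), "max_epochs")
  expect_error(unet_config(class_weights = c(1, 2)), "class_weights")
})

test_that("network shapes follow the contracting/expansive contract", {
  cfg <- unet_config(depth = 2, base_channels = 2, in_size = 16, seed = 1)
  m <- build_unet(cfg)
  lg <- turstage:::cpp_unet_logits(matrix(0.5, 16, 16), m$weights,
                                   2, 2)
  expect_equal(dim(lg), c(16, 16, 3))  # output = input spatial size x classes

  # channel doubling: bottleneck holds base * 2^depth channels
  cfg4 <- unet_config(depth = 4, base_channels = 16, in_size = 128)
  shapes <- turstage:::.unet_shapes(4, 16)
  expect_equal(shapes$bot_conv2_W[1], 16 * 2^4)  # 256 at the 8x8 bottleneck
  # parameter count is a deterministic function of (depth, base_channels)
  expect_equal(unet_n_params(cfg4), unet_n_params(unet_config(
    depth = 4, base_channels = 16, in_size = 256, seed = 99)))
  expect_equal(unet_n_params(cfg),
    sum(vapply(turstage:::.unet_shapes(2, 2), prod, 0)))
})

test_that("prediction is a deterministic argmax with low-class tie-breaks", {
  cfg <- unet_config(depth = 2, base_channels = 2, in_size = 16, seed = 2)
  m <- build_unet(cfg)
  img <- matrix(runif(256) * 255, 16, 16)
  p1 <- predict_mask(m, img)
  expect_true(all(p1 %in% 0:2))
  expect_identical(p1, predict_mask(m, img))
  expect_error(predict_mask(m, matrix(0, 8, 8)), "in_size")

  # all-zero weights -> all logits equal -> everything background (class 0)
  m0 <- m
  m0$weights <- lapply(m0$weights, function(w) w * 0)
  expect_true(all(predict_mask(m0, img) == 0L))
})

test_that("training reduces the loss and respects max_epochs without patience", {
  set8 <- noiseless_set(8)
  cfg <- unet_config(depth = 2, base_channels = 4, in_size = 32,
                     max_epochs = 6, patience = Inf, seed = 7)
  fit <- train_unet(build_unet(cfg), set8, set8[1:2], cfg)
  expect_equal(fit$history$stopped_epoch, 6)  # patience disabled
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_lte(fit$history$best_val_loss,
             fit$history$val_loss[fit$history$stopped_epoch])
})

test_that("identical seeds give identical training runs", {
  set4 <- noiseless_set(4)
  cfg <- unet_config(depth = 2, base_channels = 2, in_size = 32,
                     max_epochs = 3, patience = Inf, seed = 11)
  f1 <- train_unet(build_unet(cfg), set4, set4[1:2], cfg)
  f2 <- train_unet(build_unet(cfg), set4, set4[1:2], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$weights, f2$model$weights)
})

test_that("training rejects malformed inputs with the pair index", {
  cfg <- unet_config(depth = 2, base_channels = 2, in_size = 32, seed = 1)
  m <- build_unet(cfg)
  set2 <- noiseless_set(2)
  expect_error(train_unet(m, list(), set2, cfg), "empty train")
  bad <- set2
  bad[[2]]$mask <- bad[[2]]$mask[1:16, ]
  expect_error(train_unet(m, bad, set2, cfg), "pair 2")
})

test_that("the net can overfit four noiseless slices and is flip-stable", {
  set4 <- noiseless_set(4, seed = 200)
  cfg <- unet_config(depth = 2, base_channels = 8, in_size = 32,
                     max_epochs = 250, patience = Inf, batch_size = 2,
                     seed = 13, augment_flip = TRUE, learning_rate = 1e-3)
  fit <- train_unet(build_unet(cfg), set4, set4, cfg)
  ds <- vapply(set4, function(p) {
    pm <- predict_mask(fit$model, p$image)
    (dsc(p$mask, pm, "uterus") + dsc(p$mask, pm, "tumor")) / 2
  }, 0)
  expect_gte(mean(ds), 0.98)  # capacity sanity: memorize 4 slices

  # horizontal-flip equivariance after flip-augmented training
  img <- set4[[1]]$image
  direct <- predict_mask(fit$model, img)
  flipped <- predict_mask(fit$model, img[, ncol(img):1])
  unflipped <- flipped[, ncol(flipped):1]
  agree <- (dsc(direct, unflipped, "uterus") +
              dsc(direct, unflipped, "tumor")) / 2
  expect_gte(agree, 0.9)
})

test_that("checkpoints round-trip weights and configuration", {
  dir <- withr::local_tempdir()
  cfg <- unet_config(depth = 2, base_channels = 2, in_size = 16, seed = 5,
                     patience = Inf)
  m <- build_unet(cfg)
  m$sequence <- "axial_dwi"
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  expect_equal(m2$config, m$config)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$sequence, "axial_dwi")
  img <- matrix(runif(256) * 255, 16, 16)
  expect_identical(predict_mask(m, img), predict_mask(m2, img))
})

test_that("resize keeps masks categorical and intensities interpolated", {
  msk <- flat_mask(8, 8, nu = 20, nt = 10)
  rs <- resize_mask(msk, 16)
  expect_equal(dim(rs), c(16, 16))
  expect_true(all(rs %in% 0:2))
  img <- matrix(seq(0, 255, length.out = 64), 8, 8)
  ri <- resize_image(img, 16)
  expect_equal(dim(ri), c(16, 16))
  expect_true(all(ri >= min(img) - 1e-9 & ri <= max(img) + 1e-9))
})
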