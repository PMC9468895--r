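#' Configuration of the U-net segmenter
#'
#' Defaults are desk-scale: 128 x 128 inputs, 4 resolution levels, 16 base
#' channels, Adam at learning rate 3e-4, cross-entropy loss, at most 300
#' epochs with early stopping after `patience` epochs without validation
#' improvement. Clinical-scale inputs (256/512) are accepted through
#' `in_size`.
#'
#' @param depth number of resolution levels (pooling steps); >= 2
#' @param base_channels feature channels at the top level; doubled per level
#' @param in_size input side length in pixels; must be divisible by 2^depth
#' @param learning_rate Adam step size
#' @param max_epochs maximum training epochs
#' @param patience early-stop epochs without validation-loss improvement;
#'   `Inf` disables early stopping
#' @param batch_size images per gradient step
#' @param seed integer driving weight init, shuffling and augmentation
#' @param per_sequence train one model per MRI sequence kind (default) or a
#'   single joint model
#' @param augment_flip random horizontal flip augmentation during training
#' @param class_weights optional length-3 loss weights
#'   (background, uterus, tumor); `NULL` = unweighted
#' @return validated `unet_config` list
#' @export
unet_config <- function(depth = 4L, base_channels = 16L, in_size = 128L,
                        learning_rate = 3e-4, max_epochs = 300L,
                        patience = 20L, batch_size = 4L, seed = 1L,
                        per_sequence = TRUE, augment_flip = FALSE,
                        class_weights = NULL) {
  chk <- function(ok, field, what)
    if (!isTRUE(ok)) stop("invalid unet config '", field, "': ", what,
                          call. = FALSE)
  chk(depth >= 2, "depth", "must be >= 2")
  chk(base_channels >= 1, "base_channels", "must be >= 1")
  chk(in_size %% (2^depth) == 0, "in_size",
      sprintf("%d is not divisible by 2^depth = %d", in_size, 2^depth))
  chk(learning_rate > 0, "learning_rate", "must be > 0")
  chk(max_epochs >= 1, "max_epochs", "must be >= 1")
  chk(is.infinite(patience) || patience >= 0, "patience", "must be >= 0")
  chk(batch_size >= 1, "batch_size", "must be >= 1")
  if (!is.null(class_weights))
    chk(length(class_weights) == 3 && all(class_weights > 0),
        "class_weights", "needs 3 positive values")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_size = as.integer(in_size), classes = 3L,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), patience = patience,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 per_sequence = isTRUE(per_sequence),
                 augment_flip = isTRUE(augment_flip),
                 class_weights = class_weights),
            class = "unet_config")
}

# weight tensor shapes, in the fixed list order shared with the C++ kernels
.unet_shapes <- function(depth, base) {
  sh <- list()
  add <- function(name, d) { sh[[name]] <<- d }
  for (l in seq_len(depth) - 1) {
    cin <- if (l == 0) 1 else base * 2^(l - 1)
    cout <- base * 2^l
    add(sprintf("enc%d_conv1_W", l), c(cout, cin * 9))
    add(sprintf("enc%d_conv1_b", l), cout)
    add(sprintf("enc%d_conv2_W", l), c(cout, cout * 9))
    add(sprintf("enc%d_conv2_b", l), cout)
  }
  cb <- base * 2^depth
  add("bot_conv1_W", c(cb, base * 2^(depth - 1) * 9)); add("bot_conv1_b", cb)
  add("bot_conv2_W", c(cb, cb * 9)); add("bot_conv2_b", cb)
  for (l in rev(seq_len(depth) - 1)) {
    ch <- base * 2^l
    add(sprintf("dec%d_up_W", l), c(ch, base * 2^(l + 1) * 4))
    add(sprintf("dec%d_up_b", l), ch)
    add(sprintf("dec%d_conv1_W", l), c(ch, 2 * ch * 9))
    add(sprintf("dec%d_conv1_b", l), ch)
    add(sprintf("dec%d_conv2_W", l), c(ch, ch * 9))
    add(sprintf("dec%d_conv2_b", l), ch)
  }
  add("final_W", c(3, base)); add("final_b", 3)
  sh
}

#' Build a U-net model with freshly initialized weights
#'
#' He-normal initialization (sd = sqrt(2 / fan_in)) for convolution weights,
#' zero biases; fully determined by `config$seed`. The parameter count is a
#' deterministic function of `(depth, base_channels)`; see [unet_n_params()].
#'
#' @param config a [unet_config()]
#' @return `unet_model` list with `config` and `weights`
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  set.seed(config$seed)
  shapes <- .unet_shapes(config$depth, config$base_channels)
  weights <- lapply(shapes, function(d) {
    if (length(d) == 2) matrix(rnorm(prod(d), 0, sqrt(2 / d[2])), d[1], d[2])
    else numeric(d)
  })
  structure(list(config = config, weights = weights, sequence = NULL),
            class = "unet_model")
}

#' Total number of trainable parameters
#' @param config a [unet_config()]
#' @return integer parameter count
#' @export
unet_n_params <- function(config) {
  sum(vapply(.unet_shapes(config$depth, config$base_channels), prod, 0))
}

.check_pairs <- function(set, in_size, what) {
  if (length(set) == 0) stop("empty ", what, " set")
  for (i in seq_along(set)) {
    p <- set[[i]]
    if (is.null(p$image) || is.null(p$mask))
      stop(what, " pair ", i, " lacks image or mask")
    if (!all(dim(p$image) == dim(p$mask)))
      stop(what, " pair ", i, ": image and mask shapes differ")
    if (!all(dim(p$image) == c(in_size, in_size)))
      stop(what, " pair ", i, ": shape ", paste(dim(p$image), collapse = "x"),
           " does not match configured in_size ", in_size)
  }
}

.val_loss <- function(weights, set, config) {
  cw <- config$class_weights
  mean(vapply(set, function(p) {
    lg <- cpp_unet_logits(p$image / 255, weights, config$depth,
                          config$base_channels)
    m <- pmax(lg[, , 1], lg[, , 2], lg[, , 3])
    lse <- m + log(exp(lg[, , 1] - m) + exp(lg[, , 2] - m) + exp(lg[, , 3] - m))
    picked <- lg[cbind(as.vector(row(p$mask)), as.vector(col(p$mask)),
                       as.vector(p$mask) + 1)]
    ce <- lse - matrix(picked, nrow(p$mask))
    if (is.null(cw)) mean(ce) else {
      w <- matrix(cw[p$mask + 1], nrow(p$mask))
      sum(w * ce) / sum(w)
    }
  }, 0))
}

#' Train the U-net by Adam on pixel-wise cross-entropy
#'
#' Minimizes 3-class softmax cross-entropy with Adam at the configured
#' learning rate; stops at `max_epochs` or once validation loss has failed
#' to improve for `patience` consecutive epochs, and returns the weights of
#' the best validation epoch. Fully deterministic given `config$seed`.
#'
#' @param model a model from [build_unet()]
#' @param train_set,val_set lists of `list(image, mask)` pairs; images on the
#'   0-255 scale, masks coded 0/1/2
#' @param config optional [unet_config()] override (defaults to the model's)
#' @return list with `model` (best weights) and `history` (data frame of
#'   per-epoch train/validation loss, plus `stopped_epoch`, `best_epoch`)
#' @export
train_unet <- function(model, train_set, val_set, config = model$config) {
  stopifnot(inherits(model, "unet_model"))
  .check_pairs(train_set, config$in_size, "train")
  .check_pairs(val_set, config$in_size, "validation")
  w <- model$weights
  cw <- if (is.null(config$class_weights)) numeric(0) else config$class_weights
  m <- lapply(w, function(x) x * 0)
  v <- lapply(w, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  n <- length(train_set)
  best <- list(loss = Inf, weights = w, epoch = 0L)
  hist_train <- hist_val <- numeric(0)
  bad <- 0L
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      gacc <- NULL
      for (k in seq_along(idx)) {
        p <- train_set[[idx[k]]]
        img <- p$image / 255; msk <- p$mask
        if (config$augment_flip && runif(1) < 0.5) {
          img <- img[, ncol(img):1]
          msk <- msk[, ncol(msk):1]
        }
        res <- cpp_unet_grad(img, msk, w, config$depth, config$base_channels,
                             cw)
        losses[idx[k]] <- res$loss
        gacc <- if (is.null(gacc)) res$grads else
          mapply(`+`, gacc, res$grads, SIMPLIFY = FALSE)
      }
      t <- t + 1
      lr_t <- config$learning_rate * sqrt(1 - b2^t) / (1 - b1^t)
      for (j in seq_along(w)) {
        g <- gacc[[j]] / length(idx)
        m[[j]] <- b1 * m[[j]] + (1 - b1) * g
        v[[j]] <- b2 * v[[j]] + (1 - b2) * g^2
        w[[j]] <- w[[j]] - lr_t * m[[j]] / (sqrt(v[[j]]) + eps)
      }
    }
    vl <- .val_loss(w, val_set, config)
    hist_train <- c(hist_train, mean(losses))
    hist_val <- c(hist_val, vl)
    if (vl < best$loss) {
      best <- list(loss = vl, weights = w, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (is.finite(config$patience) && bad > config$patience) break
    }
  }
  model$weights <- best$weights
  model$config <- config
  history <- list(train_loss = hist_train, val_loss = hist_val,
                  stopped_epoch = length(hist_train),
                  best_epoch = best$epoch, best_val_loss = best$loss)
  list(model = model, history = history)
}

#' Predict a label mask for one slice
#'
#' Per-pixel argmax over the three class scores; ties break toward the lower
#' class index (background before uterus before tumor).
#'
#' @param model a trained `unet_model`
#' @param image numeric matrix on the 0-255 scale, shape
#'   `in_size x in_size`
#' @return integer label mask coded 0/1/2
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  s <- model$config$in_size
  if (!all(dim(image) == c(s, s)))
    stop("image shape ", paste(dim(image), collapse = "x"),
         " does not match configured in_size ", s)
  lg <- cpp_unet_logits(image / 255, model$weights, model$config$depth,
                        model$config$base_channels)
  scores <- cbind(as.vector(lg[, , 1]), as.vector(lg[, , 2]),
                  as.vector(lg[, , 3]))
  matrix(max.col(scores, ties.method = "first") - 1L, nrow(image))
}

#' Bilinear image resize / nearest-neighbour mask resize
#'
#' The documented resize policy for feeding arbitrary-size slices to a fixed
#' `in_size` network: intensities are interpolated bilinearly, label masks
#' are resampled nearest-neighbour so codes stay in {0, 1, 2}.
#'
#' @param image numeric matrix
#' @param mask integer label matrix
#' @param size target side length
#' @return resized matrix
#' @name resize
NULL

#' @rdname resize
#' @export
resize_image <- function(image, size) {
  h <- nrow(image); wdt <- ncol(image)
  yi <- (seq_len(size) - 0.5) * h / size - 0.5
  xi <- (seq_len(size) - 0.5) * wdt / size - 0.5
  y0 <- pmin(pmax(floor(yi), 0), h - 1); x0 <- pmin(pmax(floor(xi), 0), wdt - 1)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, wdt - 1)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a <- image[y0 + 1, x0 + 1, drop = FALSE]; b <- image[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- image[y1 + 1, x0 + 1, drop = FALSE]; d <- image[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, size, size); wx <- matrix(fx, size, size, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

#' @rdname resize
#' @export
resize_mask <- function(mask, size) {
  h <- nrow(mask); wdt <- ncol(mask)
  yi <- pmin(pmax(round((seq_len(size) - 0.5) * h / size + 0.5), 1), h)
  xi <- pmin(pmax(round((seq_len(size) - 0.5) * wdt / size + 0.5), 1), wdt)
  mask[yi, xi, drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' Weights go to a single serialized file, the configuration to a JSON
#' sidecar, so a checkpoint is self-describing.
#'
#' @param model a `unet_model`
#' @param dir checkpoint directory
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns the restored `unet_model`
#' @name checkpoint
NULL

#' @rdname checkpoint
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "unet_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  cfg <- model$config
  cfg$patience <- if (is.infinite(cfg$patience)) -1 else cfg$patience
  jsonlite::write_json(c(unclass(cfg), list(sequence = model$sequence)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  sequence <- cfg$sequence
  cfg$sequence <- NULL
  if (!is.null(cfg$patience) && cfg$patience < 0) cfg$patience <- Inf
  cw <- cfg$class_weights
  config <- unet_config(depth = cfg$depth, base_channels = cfg$base_channels,
                        in_size = cfg$in_size,
                        learning_rate = cfg$learning_rate,
                        max_epochs = cfg$max_epochs, patience = cfg$patience,
                        batch_size = cfg$batch_size, seed = cfg$seed,
                        per_sequence = cfg$per_sequence,
                        augment_flip = cfg$augment_flip,
                        class_weights = if (length(cw)) cw else NULL)
  structure(list(config = config,
                 weights = readRDS(file.path(dir, "weights.rds")),
                 sequence = sequence),
            class = "unet_model")
}
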