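#' Truncated-normal sampling by rejection
#'
#' Draws from `Normal(mean, sd)` conditioned on `(lower, upper)` by rejection,
#' which keeps the moments close to the untruncated ones whenever the
#' truncated mass is large (the case for all default TUR distributions).
#' `sd = 0` is the degenerate point mass at `mean`.
#'
#' @param n number of draws
#' @param mean,sd moments of the untruncated normal
#' @param lower,upper open truncation interval
#' @return numeric vector of length `n`
#' @export
rnorm_truncated <- function(n, mean, sd, lower = 0, upper = 1) {
  stopifnot(n >= 0, sd >= 0, lower < upper)
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean <= lower || mean >= upper)
      stop("degenerate mean outside the truncation interval")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw > lower & draw < upper])
  }
  out[seq_len(n)]
}

# per-sequence mean intensities (8-bit scale) for background / uterus / tumor;
# tumor is brightest on DWI (b = 800) where diffusion restriction dominates,
# and moderately hyperintense to myometrium on T2WI
.sequence_contrast <- function(sequence) {
  switch(sequence,
    axial_t2w    = c(60, 115, 175),
    axial_dwi    = c(35, 90, 210),
    sagittal_t2w = c(70, 125, 185),
    stop("unknown sequence kind: ", sequence)
  )
}

#' Parameters of the synthetic pelvic phantom
#'
#' Stage-conditional TUR moments default to the per-sequence values observed
#' clinically: IA/IB means (SD) of 0.165 (0.083) / 0.307 (0.112) on axial
#' T2WI, 0.190 (0.077) / 0.335 (0.117) on axial DWI and 0.103 (0.077) /
#' 0.334 (0.125) on sagittal T2WI.
#'
#' @param sequence one of `r paste(TUR_SEQUENCES, collapse = ", ")`
#' @param image_size pixels per side (square slices); at least 32
#' @param tur_ia_mean,tur_ia_sd,tur_ib_mean,tur_ib_sd stage-conditional TUR
#'   moments (unitless ratios); defaults are the sequence-specific values
#' @param noise_sd additive Gaussian intensity noise, 8-bit units
#' @param distractor_prob probability of a bright tumor-like blob outside the
#'   uterus (pelvic-effusion-style confound), labelled background
#' @return a validated `phantom_params` list
#' @export
phantom_params <- function(sequence,
                           image_size = 128L,
                           tur_ia_mean = NULL, tur_ia_sd = NULL,
                           tur_ib_mean = NULL, tur_ib_sd = NULL,
                           noise_sd = 8,
                           distractor_prob = 0) {
  sequence <- match.arg(sequence, TUR_SEQUENCES)
  defaults <- switch(sequence,
    axial_t2w    = c(0.165, 0.083, 0.307, 0.112),
    axial_dwi    = c(0.190, 0.077, 0.335, 0.117),
    sagittal_t2w = c(0.103, 0.077, 0.334, 0.125)
  )
  if (is.null(tur_ia_mean)) tur_ia_mean <- defaults[1]
  if (is.null(tur_ia_sd))   tur_ia_sd   <- defaults[2]
  if (is.null(tur_ib_mean)) tur_ib_mean <- defaults[3]
  if (is.null(tur_ib_sd))   tur_ib_sd   <- defaults[4]

  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid phantom parameter '", field, "': ", what,
                          call. = FALSE)
  }
  chk(is.numeric(image_size) && image_size >= 32 && image_size %% 2 == 0,
      "image_size", "must be an even integer >= 32")
  for (f in c("tur_ia_mean", "tur_ib_mean"))
    chk(get(f) > 0 && get(f) < 1, f, "must lie in (0, 1)")
  for (f in c("tur_ia_sd", "tur_ib_sd"))
    chk(get(f) >= 0, f, "must be non-negative")
  chk(noise_sd >= 0, "noise_sd", "must be non-negative")
  chk(distractor_prob >= 0 && distractor_prob <= 1, "distractor_prob",
      "must lie in [0, 1]")

  structure(list(sequence = sequence, image_size = as.integer(image_size),
                 tur_ia_mean = tur_ia_mean, tur_ia_sd = tur_ia_sd,
                 tur_ib_mean = tur_ib_mean, tur_ib_sd = tur_ib_sd,
                 noise_sd = noise_sd, distractor_prob = distractor_prob),
            class = "phantom_params")
}

#' Default per-sequence phantom parameters
#'
#' @param image_size pixels per side for all three sequences
#' @param distractors logical; enable the bright-distractor confound preset
#' @return named list of [phantom_params()] keyed by sequence kind
#' @export
default_phantom_params <- function(image_size = 128L, distractors = FALSE) {
  p <- if (distractors) 0.5 else 0
  stats::setNames(lapply(TUR_SEQUENCES, function(s)
    phantom_params(s, image_size = image_size, distractor_prob = p)),
    TUR_SEQUENCES)
}

# random filled ellipse covering 5-50% of the image; returns logical matrix
.random_ellipse <- function(s) {
  for (try in 1:50) {
    cx <- s / 2 + runif(1, -0.08, 0.08) * s
    cy <- s / 2 + runif(1, -0.08, 0.08) * s
    a <- runif(1, 0.18, 0.35) * s
    b <- runif(1, 0.15, 0.30) * s
    theta <- runif(1, 0, pi)
    xs <- matrix(rep(seq_len(s) - 1, each = s), nrow = s)   # column index
    ys <- matrix(rep(seq_len(s) - 1, times = s), nrow = s)  # row index
    dx <- xs - cx; dy <- ys - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    q <- u^2 + v^2
    inside <- q <= 1
    frac <- sum(inside) / s^2
    if (frac >= 0.05 && frac <= 0.5) return(list(mask = inside, q = q))
  }
  stop("failed to draw a uterus ellipse within the area bounds")
}

# grow an irregular connected blob inside `support` until it has n_target
# pixels; random subsets of the 4-connected frontier are annexed each round
.grow_blob <- function(support, q, n_target) {
  s <- nrow(support)
  tum <- matrix(FALSE, s, s)
  core <- which(support & q <= 0.5)
  if (length(core) == 0) core <- which(support)
  tum[core[sample.int(length(core), 1)]] <- TRUE
  n <- 1L
  while (n < n_target) {
    # frontier: uterus pixels 4-adjacent to the current tumor
    nb <- matrix(FALSE, s, s)
    nb[-1, ] <- nb[-1, ] | tum[-s, ]
    nb[-s, ] <- nb[-s, ] | tum[-1, ]
    nb[, -1] <- nb[, -1] | tum[, -s]
    nb[, -s] <- nb[, -s] | tum[, -1]
    frontier <- which(nb & support & !tum)
    if (length(frontier) == 0) stop("tumor growth exhausted the uterus support")
    need <- n_target - n
    k <- min(need, max(1L, rbinom(1, length(frontier), 0.5)))
    take <- if (k >= length(frontier)) frontier else
      frontier[sample.int(length(frontier), k)]
    tum[take] <- TRUE
    n <- n + length(take)
  }
  tum
}

#' Render one synthetic pelvic slice
#'
#' Draws a randomized filled-ellipse uterus (5-50% of the image area) and
#' grows one connected, irregular tumor blob strictly inside it until the
#' tumor-to-uterus pixel ratio matches `intended_tur` to within +/- 0.01.
#' Intensities follow a per-sequence three-level contrast table plus optional
#' Gaussian noise; with probability `distractor_prob` a bright tumor-like
#' blob is placed outside the uterus and labelled background.
#'
#' @param stage `"IA"` or `"IB"` (metadata only; geometry depends on the TUR)
#' @param sequence MRI sequence kind
#' @param intended_tur target tumor/(tumor+uterus) pixel ratio in (0, 1)
#' @param params a [phantom_params()] object
#' @param seed optional integer; when given the slice is rendered from a
#'   private RNG state so repeated calls are bit-identical
#' @return list with `image` (numeric matrix, 0-255), `mask` (integer matrix
#'   coded 0/1/2), `intended_tur`, `realized_tur`, `stage`, `sequence`
#' @export
render_slice <- function(stage, sequence, intended_tur, params, seed = NULL) {
  stage <- match.arg(stage, c("IA", "IB"))
  sequence <- match.arg(sequence, TUR_SEQUENCES)
  stopifnot(inherits(params, "phantom_params"))
  if (!(intended_tur > 0 && intended_tur < 1))
    stop("intended_tur must lie in (0, 1)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  s <- params$image_size
  ell <- .random_ellipse(s)
  A <- sum(ell$mask)
  n_t <- max(1L, round(intended_tur * A))
  if (n_t >= A) stop("intended_tur unreachable: tumor would fill the uterus")
  tum <- .grow_blob(ell$mask, ell$q, n_t)

  mask <- matrix(LBL_BG, s, s)
  mask[ell$mask] <- LBL_UTERUS
  mask[tum] <- LBL_TUMOR

  lv <- .sequence_contrast(sequence)
  img <- matrix(lv[1], s, s)
  img[mask == LBL_UTERUS] <- lv[2]
  img[mask == LBL_TUMOR] <- lv[3]

  if (params$distractor_prob > 0 && runif(1) < params$distractor_prob) {
    for (try in 1:20) {
      r <- runif(1, 0.03, 0.06) * s
      cx <- runif(1, r, s - r); cy <- runif(1, r, s - r)
      xs <- matrix(rep(seq_len(s) - 1, each = s), nrow = s)
      ys <- matrix(rep(seq_len(s) - 1, times = s), nrow = s)
      disc <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      if (!any(disc & mask != LBL_BG)) {
        img[disc] <- lv[3]  # tumor-like brightness, background label
        break
      }
    }
  }
  if (params$noise_sd > 0)
    img <- img + matrix(rnorm(s * s, 0, params$noise_sd), s, s)
  img <- pmin(pmax(img, 0), 255)

  realized <- sum(tum) / A
  stopifnot(abs(realized - intended_tur) <= 0.01)
  list(image = img, mask = mask, intended_tur = intended_tur,
       realized_tur = realized, stage = stage, sequence = sequence)
}

#' Sample a synthetic multi-sequence cohort
#'
#' Each patient receives one slice per MRI sequence. The intended TUR of each
#' slice is drawn from the stage- and sequence-specific truncated normal
#' (rejection truncation to (0.02, 0.95) keeps the moments nearly intact
#' while guaranteeing a renderable tumor).
#'
#' @param n_ia,n_ib number of stage IA / IB patients
#' @param params named list of per-sequence [phantom_params()]
#'   (default [default_phantom_params()])
#' @param seed integer; the cohort is a deterministic function of it
#' @return list of phantom cases; each has `patient_id`, `stage`, and a
#'   `slices` list keyed by sequence kind
#' @export
sample_cohort <- function(n_ia, n_ib, params = default_phantom_params(),
                          seed = 1L) {
  stopifnot(n_ia >= 0, n_ib >= 0)
  if (!all(TUR_SEQUENCES %in% names(params)))
    stop("invalid phantom parameter 'params': one phantom_params per sequence required")
  for (s in TUR_SEQUENCES)
    if (!inherits(params[[s]], "phantom_params"))
      stop("invalid phantom parameter 'params$", s, "': not a phantom_params object")
  set.seed(seed)
  n <- n_ia + n_ib
  if (n == 0) return(list())
  stages <- c(rep("IA", n_ia), rep("IB", n_ib))
  ids <- sprintf("P%03d", seq_len(n))
  lapply(seq_len(n), function(i) {
    slices <- lapply(TUR_SEQUENCES, function(sq) {
      p <- params[[sq]]
      mu <- if (stages[i] == "IA") p$tur_ia_mean else p$tur_ib_mean
      sg <- if (stages[i] == "IA") p$tur_ia_sd else p$tur_ib_sd
      tur <- rnorm_truncated(1, mu, sg, 0.02, 0.95)
      render_slice(stages[i], sq, tur, p)
    })
    names(slices) <- TUR_SEQUENCES
    structure(list(patient_id = ids[i], stage = stages[i], slices = slices),
              class = "phantom_case")
  })
}

#' Write a cohort to disk as PNG slices plus a manifest
#'
#' Images are written as 8-bit grayscale PNG; masks as 8-bit single-channel
#' PNG holding the raw codes 0/1/2 (lossless round trip via [read_mask()]).
#'
#' @param cases list of phantom cases from [sample_cohort()]
#' @param dir output directory (created if missing)
#' @return (invisibly) the manifest data frame, also written to
#'   `dir/manifest.csv` with columns
#'   patient_id, stage, sequence, image_path, mask_path, intended_tur
#' @export
write_cohort <- function(cases, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cs in cases) {
    for (sq in names(cs$slices)) {
      sl <- cs$slices[[sq]]
      ip <- file.path("images", paste0(cs$patient_id, "_", sq, ".png"))
      mp <- file.path("masks", paste0(cs$patient_id, "_", sq, "_mask.png"))
      write_image(sl$image, file.path(dir, ip))
      write_mask(sl$mask, file.path(dir, mp))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = cs$patient_id, stage = cs$stage, sequence = sq,
        image_path = ip, mask_path = mp, intended_tur = sl$intended_tur,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), stage = character(),
               sequence = character(), image_path = character(),
               mask_path = character(), intended_tur = numeric())
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read / write grayscale slice images and label masks
#'
#' Images hold intensities on the 0-255 scale; masks hold the integer label
#' codes 0 (background), 1 (uterus), 2 (tumor).
#'
#' @param path PNG file path
#' @param image numeric matrix, values in [0, 255]
#' @param mask integer matrix with values in {0, 1, 2}
#' @return matrices as described; writers return the path invisibly
#' @name slice_io
NULL

#' @rdname slice_io
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * 255
}

#' @rdname slice_io
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' @rdname slice_io
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  m <- round(x * 255)
  if (!all(m %in% c(LBL_BG, LBL_UTERUS, LBL_TUMOR)))
    stop("mask file holds labels outside {0,1,2}: ", path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname slice_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask %in% c(LBL_BG, LBL_UTERUS, LBL_TUMOR)))
  png::writePNG(mask / 255, path)
  invisible(path)
}
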