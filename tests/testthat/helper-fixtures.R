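# shared fixtures: tiny phantom settings and hand-built masks

tiny_params <- function(size = 32, noise_sd = 8, distractor_prob = 0) {
  stats::setNames(lapply(TUR_SEQUENCES, function(s)
    phantom_params(s, image_size = size, noise_sd = noise_sd,
                   distractor_prob = distractor_prob)), TUR_SEQUENCES)
}

# mask with nt tumor and nu uterus pixels laid out row-wise on an r x c grid
flat_mask <- function(r, c, nu = 0, nt = 0) {
  m <- matrix(0L, r, c)
  if (nu > 0) m[seq_len(nu)] <- 1L
  if (nt > 0) m[nu + seq_len(nt)] <- 2L
  m
}

# brute-force Dice by explicit pixel loop (independent oracle)
dsc_pixel_loop <- function(ref, pred, structure, whole_organ = TRUE) {
  inter <- 0; nx <- 0; ny <- 0
  memb <- function(v) {
    if (structure == "tumor") v == 2
    else if (whole_organ) v %in% c(1, 2) else v == 1
  }
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) {
      x <- memb(ref[i, j]); y <- memb(pred[i, j])
      nx <- nx + x; ny <- ny + y
      if (x && y) inter <- inter + 1
    }
  }
  if (nx + ny == 0) 1 else 2 * inter / (nx + ny)
}

# brute-force all-pairs Mann-Whitney AUC with ties counted 1/2
mw_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# one labelled shape in LabelMe JSON form
labelme_doc <- function(shapes, h = 10, w = 10) {
  jsonlite::toJSON(list(
    imageHeight = h, imageWidth = w,
    shapes = lapply(shapes, function(s)
      list(label = s$label,
           points = lapply(seq_len(nrow(s$pts)), function(i)
             as.list(s$pts[i, ]))))
  ), auto_unbox = TRUE)
}

rect_pts <- function(x0, y0, x1, y1)
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
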