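#' Tumor-to-uterus area ratio (TUR) of a label mask
#'
#' The staging score: tumor pixel count divided by the total organ pixel
#' count (tumor + uterus labels). Being a ratio of counts on one slice it is
#' voxel-size independent. A mask with no uterus and no tumor pixels raises
#' an error rather than returning 0, so segmentation failures surface.
#'
#' @param mask integer label mask (0 = background, 1 = uterus, 2 = tumor)
#' @return TUR in [0, 1]
#' @export
compute_tur <- function(mask) {
  nt <- sum(mask == LBL_TUMOR)
  nu <- sum(mask == LBL_UTERUS)
  if (nt + nu == 0)
    stop("empty segmentation: mask has no uterus or tumor pixels")
  nt / (nt + nu)
}

#' ROC analysis of TUR scores against true stage
#'
#' Operating points are evaluated at every distinct TUR value under the
#' decision rule "call IB when tur >= threshold" (IB is the positive class:
#' it has the larger mean TUR on every sequence). The AUC is the trapezoid
#' area, identical to the Mann-Whitney U statistic with ties counted 1/2.
#' The reported criterion maximizes Youden's J = sensitivity + specificity
#' - 1, ties broken toward the smallest threshold.
#'
#' @param tur numeric TUR scores
#' @param true_stage character vector of `"IA"` / `"IB"`, same length
#' @return `roc_result` list: `thresholds`, `sensitivity`, `specificity`
#'   (per threshold, ascending), `auc`, `criterion`, `sens_at_criterion`,
#'   `spec_at_criterion`
#' @export
roc_curve <- function(tur, true_stage) {
  stopifnot(length(tur) == length(true_stage))
  if (!all(true_stage %in% c("IA", "IB"))) stop("stages must be IA or IB")
  pos <- tur[true_stage == "IB"]
  neg <- tur[true_stage == "IA"]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both stages must be present to build an ROC")
  th <- sort(unique(tur))
  pc <- tabulate(match(pos, th), nbins = length(th))
  nc <- tabulate(match(neg, th), nbins = length(th))
  # P(pos >= th[k]) and P(neg < th[k]) via cumulative counts
  sens <- rev(cumsum(rev(pc))) / length(pos)
  spec <- cumsum(c(0, nc))[seq_along(th)] / length(neg)
  # trapezoid over the full curve incl. the (0,0) endpoint above max(tur)
  fpr <- c(1 - spec, 0); tpr <- c(sens, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # thresholds ascend, so first = smallest
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, criterion = th[best],
                 sens_at_criterion = sens[best],
                 spec_at_criterion = spec[best]),
            class = "roc_result")
}

#' Closed-form AUC of two Gaussian score distributions
#'
#' For IA scores ~ N(mu_ia, sd_ia^2) and IB scores ~ N(mu_ib, sd_ib^2),
#' the probability that a random IB score exceeds a random IA score is
#' `pnorm((mu_ib - mu_ia) / sqrt(sd_ia^2 + sd_ib^2))` — the analytic oracle
#' for simulation-based ROC checks.
#'
#' @param mu_ia,sd_ia,mu_ib,sd_ib stage-conditional moments; SDs > 0
#' @return AUC in (0, 1)
#' @export
gaussian_auc <- function(mu_ia, sd_ia, mu_ib, sd_ib) {
  if (sd_ia <= 0 || sd_ib <= 0) stop("standard deviations must be positive")
  pnorm((mu_ib - mu_ia) / sqrt(sd_ia^2 + sd_ib^2))
}

#' Classify a TUR score against a staging criterion
#'
#' @param tur numeric TUR score(s)
#' @param criterion staging threshold in [0, 1]
#' @return `"IB"` where `tur >= criterion`, else `"IA"`
#' @export
classify_stage <- function(tur, criterion) {
  if (criterion < 0 || criterion > 1) stop("criterion must lie in [0, 1]")
  ifelse(tur >= criterion, "IB", "IA")
}

#' Multi-sequence fusion rule
#'
#' A fully parameterized k-of-n vote: the fused call is IB when at least `k`
#' of the per-sequence votes are IB. `mode = "single"` is the one-sequence
#' special case.
#'
#' @param mode `"single"` or `"k_of_n"`
#' @param k IB votes required for a fused IB call
#' @param sequences the sequence kinds taking part
#' @return `fusion_rule` list
#' @export
fusion_rule <- function(mode = c("k_of_n", "single"), k = 2L,
                        sequences = TUR_SEQUENCES) {
  mode <- match.arg(mode)
  sequences <- match.arg(sequences, TUR_SEQUENCES, several.ok = TRUE)
  if (mode == "single" && length(sequences) != 1)
    stop("single mode takes exactly one sequence")
  if (mode == "single") k <- 1L
  if (k < 1 || k > length(sequences))
    stop("k must lie between 1 and the number of sequences")
  structure(list(mode = mode, k = as.integer(k), sequences = sequences),
            class = "fusion_rule")
}

#' Fuse per-sequence stage votes
#'
#' @param votes named character vector of `"IA"` / `"IB"` votes, one per
#'   sequence in `rule$sequences`
#' @param rule a [fusion_rule()]
#' @return fused `"IA"` or `"IB"`
#' @export
fuse_votes <- function(votes, rule) {
  stopifnot(inherits(rule, "fusion_rule"))
  missing <- setdiff(rule$sequences, names(votes))
  if (length(missing))
    stop("missing vote for sequence: ", paste(missing, collapse = ", "))
  v <- votes[rule$sequences]
  if (!all(v %in% c("IA", "IB"))) stop("votes must be IA or IB")
  if (sum(v == "IB") >= rule$k) "IB" else "IA"
}

#' Staging performance against true stages
#'
#' IB is the positive class: sensitivity is the IB detection rate,
#' specificity the IA detection rate. When a class is absent the
#' corresponding rate is `NA` (undefined), never 0.
#'
#' @param predicted,truth character vectors of `"IA"` / `"IB"`
#' @return `performance_summary` list: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`
#' @export
evaluate_staging <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  if (!all(c(predicted, truth) %in% c("IA", "IB")))
    stop("stages must be IA or IB")
  tp <- sum(predicted == "IB" & truth == "IB")
  tn <- sum(predicted == "IA" & truth == "IA")
  fp <- sum(predicted == "IB" & truth == "IA")
  fn <- sum(predicted == "IA" & truth == "IB")
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ), class = "performance_summary")
}

#' Stage a cohort from its TUR table
#'
#' Applies the per-sequence criteria to every patient's TUR scores and fuses
#' the votes under the given rule.
#'
#' @param tur_table data frame with columns `patient_id`, `sequence`, `tur`
#'   (and optionally `true_stage`)
#' @param criteria named numeric vector of per-sequence staging thresholds
#' @param rule a [fusion_rule()]
#' @return data frame with one row per patient: per-sequence votes, the
#'   fused call, and `true_stage` when available
#' @export
stage_cohort <- function(tur_table, criteria, rule = fusion_rule()) {
  stopifnot(all(c("patient_id", "sequence", "tur") %in% names(tur_table)))
  missing <- setdiff(rule$sequences, names(criteria))
  if (length(missing))
    stop("missing criterion for sequence: ", paste(missing, collapse = ", "))
  pats <- unique(tur_table$patient_id)
  out <- do.call(rbind, lapply(pats, function(p) {
    rows <- tur_table[tur_table$patient_id == p, ]
    votes <- vapply(rule$sequences, function(sq) {
      r <- rows[rows$sequence == sq, ]
      if (nrow(r) == 0) stop("patient ", p, ": missing vote for sequence: ", sq)
      classify_stage(r$tur[1], criteria[[sq]])
    }, "")
    rec <- data.frame(patient_id = p, stringsAsFactors = FALSE)
    for (sq in rule$sequences) rec[[paste0("vote_", sq)]] <- votes[[sq]]
    rec$fused <- fuse_votes(votes, rule)
    if ("true_stage" %in% names(rows)) rec$true_stage <- rows$true_stage[1]
    rec
  }))
  rownames(out) <- NULL
  out
}
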