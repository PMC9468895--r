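#' Dice similarity coefficient of one structure
#'
#' `DSC = 2|X intersect Y| / (|X| + |Y|)` between the reference and predicted
#' pixel sets of a structure. For the uterus the default membership is
#' whole-organ: pixels labelled uterus *or* tumor, because the tumor lies
#' inside the uterine outline and the organ contour encloses both
#' (`mode = "strict"` restricts membership to the uterus label alone). For
#' the tumor, membership is the tumor label. When both sets are empty the
#' DSC is defined as 1 (perfect agreement); an empty reference against a
#' non-empty prediction gives 0.
#'
#' @param reference,predicted integer label masks (0/1/2) of equal shape
#' @param structure `"uterus"` or `"tumor"`
#' @param mode uterus membership rule, `"whole_organ"` (default) or
#'   `"strict"`
#' @return DSC in [0, 1]
#' @export
dsc <- function(reference, predicted, structure = c("uterus", "tumor"),
                mode = c("whole_organ", "strict")) {
  structure <- match.arg(structure)
  mode <- match.arg(mode)
  if (!all(dim(reference) == dim(predicted)))
    stop("reference and predicted masks differ in shape")
  member <- function(m) {
    if (structure == "tumor") m == LBL_TUMOR
    else if (mode == "whole_organ") m == LBL_UTERUS | m == LBL_TUMOR
    else m == LBL_UTERUS
  }
  x <- member(reference); y <- member(predicted)
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0) return(1)
  2 * sum(x & y) / (nx + ny)
}

#' Cohort DSC summaries by sequence and structure
#'
#' @param records data frame with columns `sequence`, `structure`, `dsc`
#'   (and typically `patient_id`)
#' @return data frame with one row per sequence x structure group:
#'   `mean`, `sd` (sample, n-1 denominator; 0 for n = 1), `median`, `n`
#' @export
summarize_dsc <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("sequence", "structure", "dsc") %in% names(records)))
  groups <- unique(records[, c("sequence", "structure")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- records[records$sequence == groups$sequence[i] &
                   records$structure == groups$structure[i], "dsc"]
    data.frame(sequence = groups$sequence[i],
               structure = groups$structure[i],
               mean = mean(g),
               sd = if (length(g) > 1) sd(g) else 0,
               median = median(g), n = length(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample comparison of DSC (or TUR) groups
#'
#' Two-sided t-test; the Welch (unequal-variance) form by default, with
#' Student and paired forms available.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2
#' @param paired paired test (requires equal lengths)
#' @param var_equal classic Student form instead of Welch
#' @return two-sided p-value
#' @export
compare_groups <- function(sample_a, sample_b, paired = FALSE,
                           var_equal = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 observations")
  t.test(sample_a, sample_b, paired = paired, var.equal = var_equal)$p.value
}
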