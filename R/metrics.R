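# Epoch-wise (microscopic) agreement statistics.

#' Per-epoch accuracy
#'
#' Fraction of epochs whose predicted stage equals the reference stage.
#'
#' @param pred,truth Equal-length non-empty stage vectors.
#' @return Fraction in `[0, 1]`.
#' @export
per_epoch_accuracy <- function(pred, truth) {
  pred <- assert_stages(pred, "pred", allow_empty = FALSE)
  truth <- assert_stages(truth, "truth", allow_empty = FALSE)
  assert_same_length(pred, truth)
  mean(pred == truth)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` from the product of the marginal class frequencies.
#' When both raters are concentrated on the same single class
#' (`p_e = 1`, `p_o = 1`) the agreement is perfect and 1 is returned.
#'
#' @param pred,truth Equal-length non-empty class vectors.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(c(1, 2, 2, 4), c(1, 2, 3, 4))
#' @export
cohens_kappa <- function(pred, truth) {
  assert_same_length(pred, truth)
  if (length(pred) == 0) abort("Inputs must be non-empty.")
  lev <- sort(unique(c(pred, truth)))
  p <- factor(pred, levels = lev)
  t <- factor(truth, levels = lev)
  n <- length(p)
  po <- mean(p == t)
  pe <- sum(as.numeric(table(p)) * as.numeric(table(t))) / n^2
  if (abs(1 - pe) < 1e-15) {
    return(if (po == 1) 1 else NaN)
  }
  (po - pe) / (1 - pe)
}

#' Multiclass Matthews correlation coefficient
#'
#' The K-class generalization of the Matthews correlation computed from
#' the full contingency table: with `c` the number of correct
#' predictions, `s` the sample size, `p_k` the times class k was
#' predicted and `t_k` the times it truly occurred,
#' `R_K = (c*s - sum p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`.
#' 1 is perfect classification, -1 perfect misclassification, 0 the
#' level of random guessing. Degenerate inputs (a single class in both
#' vectors, zero denominator) return 0 with a warning.
#'
#' @param pred,truth Equal-length non-empty class vectors.
#' @return Value in `[-1, 1]`.
#' @export
mmcc <- function(pred, truth) {
  assert_same_length(pred, truth)
  if (length(pred) == 0) abort("Inputs must be non-empty.")
  lev <- sort(unique(c(pred, truth)))
  p <- factor(pred, levels = lev)
  t <- factor(truth, levels = lev)
  s <- length(p)
  c_corr <- sum(p == t)
  pk <- as.numeric(table(p))
  tk <- as.numeric(table(t))
  num <- c_corr * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) {
    warn("Degenerate contingency table; MMCC defined as 0.",
         class = "sleepcascade_undefined_metric")
    return(0)
  }
  num / den
}

#' Column-normalized confusion matrix (percent)
#'
#' Rows are predicted stages, columns are ground-truth stages; each
#' column is normalized to sum to 100, so cell `(r, c)` is the percent of
#' truth-stage-`c` epochs predicted as stage `r`. Truth stages absent
#' from the input give `NaN` columns.
#'
#' @param pred,truth Equal-length non-empty stage vectors.
#' @return 4x4 numeric matrix with stage-name dimnames
#'   (`predicted` x `truth`).
#' @export
confusion_matrix_pct <- function(pred, truth) {
  pred <- assert_stages(pred, "pred", allow_empty = FALSE)
  truth <- assert_stages(truth, "truth", allow_empty = FALSE)
  assert_same_length(pred, truth)
  tab <- table(factor(pred, levels = STAGES), factor(truth, levels = STAGES))
  m <- sweep(unclass(tab), 2, colSums(tab), "/") * 100
  dimnames(m) <- list(predicted = STAGE_LABELS, truth = STAGE_LABELS)
  m
}

#' Correcting power
#'
#' Among epochs the device mislabelled, the fraction the model fixed
#' (predicted stage equals the reference). Undefined when the device made
#' no errors; `NA` is then returned with a warning.
#'
#' @param device,pred,truth Equal-length stage vectors: device labels,
#'   model predictions, reference labels.
#' @return Fraction in `[0, 1]`, or `NA` if no epoch was mislabelled.
#' @export
correcting_power <- function(device, pred, truth) {
  device <- assert_stages(device, "device", allow_empty = FALSE)
  pred <- assert_stages(pred, "pred", allow_empty = FALSE)
  truth <- assert_stages(truth, "truth", allow_empty = FALSE)
  assert_same_length(device, pred, "device", "pred")
  assert_same_length(device, truth, "device", "truth")
  wrong <- device != truth
  if (!any(wrong)) {
    warn("Device mislabelled no epochs; correcting power undefined.",
         class = "sleepcascade_undefined_metric")
    return(NA_real_)
  }
  mean(pred[wrong] == truth[wrong])
}

#' Over-correcting rate
#'
#' Among epochs the device labelled correctly, the fraction the model
#' broke (predicted stage differs from the reference). Undefined when the
#' device got nothing right; `NA` is then returned with a warning.
#'
#' @inheritParams correcting_power
#' @return Fraction in `[0, 1]`, or `NA` if no epoch was device-correct.
#' @export
over_correcting_rate <- function(device, pred, truth) {
  device <- assert_stages(device, "device", allow_empty = FALSE)
  pred <- assert_stages(pred, "pred", allow_empty = FALSE)
  truth <- assert_stages(truth, "truth", allow_empty = FALSE)
  assert_same_length(device, pred, "device", "pred")
  assert_same_length(device, truth, "device", "truth")
  right <- device == truth
  if (!any(right)) {
    warn("Device labelled no epochs correctly; over-correcting rate undefined.",
         class = "sleepcascade_undefined_metric")
    return(NA_real_)
  }
  mean(pred[right] != truth[right])
}

#' Relative performance change against a baseline
#'
#' Signed percent change `(m_proposal - m_baseline) / m_baseline * 100`.
#' A negative value on an error-type metric is a reduction; e.g. a bias
#' score falling from 0.617 to 0.179 is a change of -71.0%, i.e. a 71.0%
#' reduction.
#'
#' @param m_proposal,m_baseline Metric values; `m_baseline` must be
#'   non-zero.
#' @return Signed percent.
#' @examples
#' delta_improvement(0.179, 0.617)
#' @export
delta_improvement <- function(m_proposal, m_baseline) {
  if (any(m_baseline == 0)) abort("Baseline metric must be non-zero.")
  (m_proposal - m_baseline) / m_baseline * 100
}

#' Total minutes spent in each sleep stage
#'
#' Aggregates epoch-wise stage labels to stage durations:
#' `0.5 min * count(stage == i)`. The four durations sum to half the
#' epoch count (in minutes). An empty input gives all zeros.
#'
#' @param stages Integer vector of stage codes.
#' @return Tibble with columns `stage` (code), `label`, `minutes`.
#' @examples
#' stage_durations(c(2, 2, 4))
#' @export
stage_durations <- function(stages) {
  stages <- assert_stages(stages, "stages")
  counts <- tabulate(stages, nbins = 4)
  tibble(stage = STAGES, label = STAGE_LABELS, minutes = 0.5 * counts)
}

#' Shannon diversity of a stage distribution
#'
#' `H = -sum_i p_i ln p_i` over the four stages, with zero-probability
#' stages contributing 0. `H` ranges from 0 (one stage only) to
#' `ln 4 ~ 1.386` (exactly uniform stages); lower values mean a more
#' imbalanced night.
#'
#' @param labels Non-empty stage vector.
#' @return Value in `[0, ln 4]`.
#' @examples
#' shannon_diversity(rep(1:4, 25))
#' @export
shannon_diversity <- function(labels) {
  labels <- assert_stages(labels, "labels", allow_empty = FALSE)
  p <- tabulate(labels, nbins = 4) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}
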