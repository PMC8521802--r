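# Dataset-characterization statistics: the two-sample Anderson-Darling
# shift statistic and performance/characteristic correlations.

#' Two-sample Anderson-Darling shift statistic
#'
#' Quantifies how much a test set's stage distribution departs from the
#' training set's, using the k-sample Anderson-Darling statistic of
#' Scholz & Stephens in its midrank (tie-corrected) form with k = 2 --
#' appropriate here because stage codes are heavily tied ordinal values.
#' Larger values indicate a larger train/test shift; identical samples
#' attain the minimum for their configuration.
#'
#' With pooled size `N`, distinct pooled values `z_j` of multiplicity
#' `l_j`, `M_aij` the midrank count of sample i at `z_j` and `B_aj` the
#' pooled midrank count, the statistic is
#' `A2 = (N-1)/N * sum_i 1/n_i sum_j l_j/N *
#'   (N M_aij - n_i B_aj)^2 / (B_aj (N - B_aj) - N l_j / 4)`.
#'
#' @param train_labels,test_labels Non-empty numeric/ordinal vectors
#'   (here: stage codes 1-4).
#' @param standardized If `TRUE`, return the standardized form
#'   `(A2 - (k-1)) / sigma_N` used for p-value lookup; default returns
#'   the raw statistic.
#' @return The Anderson-Darling statistic (single number).
#' @examples
#' ad_shift(rep(1:4, 25), rep(1:4, c(10, 60, 20, 10)))
#' @export
ad_shift <- function(train_labels, test_labels, standardized = FALSE) {
  if (length(train_labels) == 0 || length(test_labels) == 0) {
    abort("Both label vectors must be non-empty.")
  }
  samples <- list(as.numeric(train_labels), as.numeric(test_labels))
  n <- lengths(samples)
  pooled <- c(samples[[1]], samples[[2]])
  N <- length(pooled)
  z <- sort(unique(pooled))
  L <- length(z)
  if (L == 1) return(0)  # a single pooled value carries no shift information
  lj <- as.numeric(table(factor(pooled, levels = z)))
  Bj <- cumsum(lj) - lj / 2
  a2 <- 0
  for (i in 1:2) {
    fij <- as.numeric(table(factor(samples[[i]], levels = z)))
    Mij <- cumsum(fij) - fij / 2
    denom <- Bj * (N - Bj) - N * lj / 4
    ok <- denom > 0
    a2 <- a2 + (1 / n[i]) * sum((lj[ok] / N) *
                                  (N * Mij[ok] - n[i] * Bj[ok])^2 / denom[ok])
  }
  a2 <- a2 * (N - 1) / N
  if (!standardized) return(a2)
  # variance of the k-sample statistic (Scholz-Stephens), k = 2
  k <- 2
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  g <- 0
  for (ii in 1:(N - 2)) g <- g + sum(1 / ((N - ii) * (ii + 1):(N - 1)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k +
    (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  var_a2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  (a2 - (k - 1)) / sqrt(var_a2)
}

#' Correlate a performance measure with a dataset characteristic
#'
#' Pearson correlation (with two-tailed p-value) between a per-subject
#' performance measure (accuracy, kappa, ...) and a per-subject dataset
#' statistic (Shannon diversity of the test set, Anderson-Darling shift).
#' Zero variance in either vector leaves the correlation undefined; `NA`
#' is returned with a warning.
#'
#' @param metric_by_subject,stat_by_subject Paired numeric vectors,
#'   `n >= 3`.
#' @return One-row tibble with `r`, `p`, `n`.
#' @export
correlate_performance <- function(metric_by_subject, stat_by_subject) {
  if (length(metric_by_subject) != length(stat_by_subject)) {
    abort("Inputs must be paired (equal length).")
  }
  ok <- complete.cases(metric_by_subject, stat_by_subject)
  x <- metric_by_subject[ok]
  y <- stat_by_subject[ok]
  if (length(x) < 3) abort("Correlation needs at least 3 complete pairs.")
  if (var(x) == 0 || var(y) == 0) {
    warn("Zero variance; Pearson correlation undefined.",
         class = "sleepcascade_undefined_metric")
    return(tibble(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
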