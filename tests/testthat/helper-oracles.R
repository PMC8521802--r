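# Independent oracle implementations used only to verify package results.
# Each takes a route different from the package code: a different library,
# a closed form, or a naive loop transcription.

# Cohen's kappa through caret's confusion-matrix machinery.
oracle_kappa <- function(pred, truth) {
  lev <- sort(unique(c(pred, truth)))
  cm <- caret::confusionMatrix(factor(pred, levels = lev),
                               factor(truth, levels = lev))
  unname(cm$overall["Kappa"])
}

# Binary Matthews correlation from the TP/TN/FP/FN closed form
# (positive class = the larger label).
oracle_binary_mcc <- function(pred, truth) {
  pos <- max(c(pred, truth))
  tp <- sum(pred == pos & truth == pos)
  tn <- sum(pred != pos & truth != pos)
  fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  (tp * tn - fp * fn) / den
}

# Stationary distribution by power iteration (no eigen-decomposition).
oracle_stationary <- function(P, iters = 10000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.numeric(v %*% P)
  v / sum(v)
}

# Two-sample midrank Anderson-Darling statistic, naive loop transcription:
# counts computed per distinct value with explicit sums, no cumsums.
oracle_ad <- function(x, y) {
  samples <- list(as.numeric(x), as.numeric(y))
  pooled <- c(samples[[1]], samples[[2]])
  N <- length(pooled)
  z <- sort(unique(pooled))
  if (length(z) == 1) return(0)
  a2 <- 0
  for (i in 1:2) {
    si <- samples[[i]]
    ni <- length(si)
    inner <- 0
    for (j in seq_along(z)) {
      lj <- sum(pooled == z[j])
      fij <- sum(si == z[j])
      Maij <- sum(si < z[j]) + fij / 2
      Baj <- sum(pooled < z[j]) + lj / 2
      denom <- Baj * (N - Baj) - N * lj / 4
      if (denom > 0) {
        inner <- inner + (lj / N) * (N * Maij - ni * Baj)^2 / denom
      }
    }
    a2 <- a2 + inner / ni
  }
  a2 * (N - 1) / N
}

# One-sample t statistic and two-tailed p, textbook formulas.
oracle_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Pearson correlation from the raw sums formula, p from the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    (sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# fit_fun candidates for grid-search tests: a majority-vote rule and the
# true generative rule; selection must find the latter.
rule_fit_fun <- function(counter = NULL) {
  function(features, labels, params, seed) {
    if (!is.null(counter)) counter$train_rows <- c(counter$train_rows, length(labels))
    if (params$rule == "majority") {
      maj <- as.integer(names(which.max(table(labels))))
      function(f) rep(maj, nrow(f))
    } else {
      function(f) ifelse(f$x > 0, 2L, 1L)
    }
  }
}

# Small deterministic aligned record for feature/metric tests.
make_toy_record <- function(n = 12, seed = 11) {
  truth <- simulate_hypnogram(n, seed = seed)
  device <- corrupt_stages(truth, seed = seed + 1)
  hr <- simulate_heart_rate(truth, missing_rate = 0, seed = seed + 2)
  align_epochs(device, truth, hr)
}

toy_demographics <- list(age = 25, sex = 1, psqi = 4)

# Small cohort for harness tests.
make_test_cohort <- function(n_subjects = 3, epochs = c(100, 140), seed = 5) {
  simulate_cohort(sim_config(n_subjects = n_subjects, epochs_range = epochs,
                             master_seed = seed))
}
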