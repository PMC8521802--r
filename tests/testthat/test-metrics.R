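test_that("per-epoch accuracy counts agreeing epochs", {
  s <- simulate_hypnogram(40, seed = 1)
  expect_equal(per_epoch_accuracy(s, s), 1)
  expect_equal(per_epoch_accuracy(rep(1L, 10), rep(2L, 10)), 0)
  # six-epoch worked example: three agreements out of six
  expect_equal(per_epoch_accuracy(c(4L, 4L, 2L, 2L, 3L, 3L),
                                  c(4L, 4L, 4L, 4L, 2L, 3L)), 0.5)
  expect_error(per_epoch_accuracy(1:3, 1:4), "equal length")
  expect_error(per_epoch_accuracy(integer(0), integer(0)), "non-empty")
})

test_that("Cohen's kappa matches hand values and the library oracle", {
  s <- simulate_hypnogram(30, seed = 2)
  expect_equal(cohens_kappa(s, s), 1)
  # constant prediction against 50/50 truth: p_o = p_e = 0.5 -> 0
  expect_equal(cohens_kappa(rep(1L, 10), rep(c(1L, 2L), 5)), 0)
  # single shared class in both raters: perfect, p_e = 1
  expect_equal(cohens_kappa(rep(3L, 5), rep(3L, 5)), 1)

  set.seed(3)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    pred <- sample(1:4, n, TRUE)
    truth <- sample(1:4, n, TRUE)
    expect_equal(cohens_kappa(pred, truth), oracle_kappa(pred, truth),
                 tolerance = 1e-12)
  }
})

test_that("multiclass MCC matches its binary special case and bounds", {
  s <- simulate_hypnogram(40, seed = 4)
  expect_equal(mmcc(s, s), 1)
  # perfect two-class misclassification
  expect_equal(mmcc(c(1, 1, 2, 2), c(2, 2, 1, 1)), -1)
  expect_warning(expect_equal(mmcc(rep(1L, 5), rep(1L, 5)), 0), "Degenerate")

  set.seed(5)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    pred <- sample(1:2, n, TRUE)
    truth <- sample(1:2, n, TRUE)
    if (length(unique(pred)) < 2 || length(unique(truth)) < 2) next
    expect_equal(mmcc(pred, truth), oracle_binary_mcc(pred, truth),
                 tolerance = 1e-12)
  }

  # bounded on random four-class instances
  set.seed(6)
  for (i in 1:50) {
    pred <- sample(1:4, 30, TRUE)
    truth <- sample(1:4, 30, TRUE)
    v <- suppressWarnings(mmcc(pred, truth))
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("confusion matrix is column-normalized over ground truth", {
  s <- simulate_hypnogram(60, seed = 7)
  cm <- confusion_matrix_pct(s, s)
  expect_equal(diag(cm), rep(100, 4), ignore_attr = TRUE)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # worked example: the single truth-light epoch was predicted REM
  cm2 <- confusion_matrix_pct(c(4L, 4L, 2L, 2L, 3L, 3L),
                              c(4L, 4L, 4L, 4L, 2L, 3L))
  expect_equal(unname(cm2[, "light"]), c(0, 0, 100, 0))

  pred <- sample(1:4, 200, TRUE); truth <- sample(1:4, 200, TRUE)
  expect_equal(unname(colSums(confusion_matrix_pct(pred, truth))),
               rep(100, 4), tolerance = 1e-9)
})

test_that("correcting power and over-correcting rate count the right strata", {
  device <- c(4L, 4L, 2L, 2L, 3L, 3L)
  truth <- c(4L, 4L, 4L, 4L, 2L, 3L)
  # epochs 3,4 corrected; epoch 5 left wrong -> CP = 2/3
  pred_cp <- c(4L, 4L, 4L, 4L, 3L, 3L)
  expect_equal(correcting_power(device, pred_cp, truth), 2 / 3)
  # flip one device-correct epoch (epoch 6) -> OR = 1/3
  pred_or <- c(4L, 4L, 2L, 2L, 3L, 1L)
  expect_equal(over_correcting_rate(device, pred_or, truth), 1 / 3)

  expect_equal(correcting_power(device, truth, truth), 1)
  expect_equal(correcting_power(device, device, truth), 0)
  expect_equal(over_correcting_rate(device, device, truth), 0)
  expect_equal(over_correcting_rate(device, truth, truth), 0)

  # undefined strata are signalled, not silently zeroed
  expect_warning(
    expect_true(is.na(correcting_power(truth, truth, truth))),
    class = "sleepcascade_undefined_metric")
  expect_warning(
    expect_true(is.na(over_correcting_rate(5 - truth, truth, truth))),
    class = "sleepcascade_undefined_metric")
})

test_that("CP and OR satisfy the error-conservation identity", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    device <- sample(1:4, n, TRUE)
    truth <- sample(1:4, n, TRUE)
    pred <- sample(1:4, n, TRUE)
    n_wrong <- sum(device != truth)
    n_right <- n - n_wrong
    if (n_wrong == 0 || n_right == 0) next
    cp <- correcting_power(device, pred, truth)
    orr <- over_correcting_rate(device, pred, truth)
    total_errors <- sum(pred != truth)
    expect_equal(n_right * orr + n_wrong * (1 - cp), total_errors)
  }
})

test_that("relative improvement is exact and scale-invariant", {
  expect_equal(delta_improvement(0.179, 0.617), -71.0, tolerance = 0.05)
  expect_equal(delta_improvement(0.010, 0.617), -98.4, tolerance = 0.05)
  expect_equal(delta_improvement(0.33, 0.33), 0)
  expect_error(delta_improvement(1, 0), "non-zero")
  set.seed(9)
  for (i in 1:10) {
    x <- runif(1, 0.1, 2); y <- runif(1, 0.1, 2); a <- runif(1, 0.1, 5)
    expect_equal(delta_improvement(a * x, a * y), delta_improvement(x, y),
                 tolerance = 1e-9)
  }
})

test_that("stage durations aggregate epochs to minutes and conserve time", {
  d <- stage_durations(c(2L, 2L, 4L))
  expect_equal(d$minutes[d$label == "light"], 1.0)
  expect_equal(d$minutes[d$label == "wake"], 0.5)
  expect_equal(sum(d$minutes), 1.5)
  expect_equal(stage_durations(integer(0))$minutes, rep(0, 4))
  # a full 1,176-epoch night spans 588 min = 9.8 h
  expect_equal(sum(stage_durations(rep(2L, 1176))$minutes), 588)
  for (seed in 1:5) {
    s <- simulate_hypnogram(sample(50:300, 1), seed = seed)
    expect_equal(sum(stage_durations(s)$minutes), 0.5 * length(s))
  }
})

test_that("Shannon diversity hits its closed forms and its maximum", {
  expect_equal(shannon_diversity(rep(2L, 50)), 0)
  expect_equal(shannon_diversity(rep(1:4, 25)), log(4))
  expect_equal(shannon_diversity(rep(c(1L, 2L), 25)), log(2))
  # uniform is the unique maximum
  set.seed(10)
  for (i in 1:10) {
    s <- sample(1:4, 100, TRUE, prob = runif(4, 0.05, 1))
    expect_lte(shannon_diversity(s), log(4) + 1e-12)
  }
  expect_error(shannon_diversity(integer(0)), "non-empty")
})
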