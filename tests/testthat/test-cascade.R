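make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  list(features = tibble::tibble(f1 = x[, 1], f2 = x[, 2]),
       labels = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("resampling balances classes without fabricating rows", {
  set.seed(2)
  feats <- tibble::tibble(v = seq_len(160), w = rnorm(160))
  labels <- rep(1:4, times = c(100, 30, 20, 10))

  dn <- resample_training_set(feats, labels, "down", seed = 1)
  expect_equal(as.integer(table(dn$labels)), rep(10L, 4))
  up <- resample_training_set(feats, labels, "up", seed = 1)
  expect_equal(as.integer(table(up$labels)), rep(100L, 4))
  no <- resample_training_set(feats, labels, "none")
  expect_identical(no$features, feats)
  expect_identical(no$labels, labels)

  # every resampled row is an exact copy of an original row of its class
  for (out in list(dn, up)) {
    key_orig <- paste(feats$v, feats$w, labels)
    key_new <- paste(out$features$v, out$features$w, out$labels)
    expect_true(all(key_new %in% key_orig))
  }
  # up sampling keeps all original rows
  expect_true(all(feats$v %in% up$features$v))

  expect_error(resample_training_set(feats[0, ], integer(0), "down"),
               "non-empty")
})

test_that("level-I learners separate a separable binary problem", {
  blobs <- make_blobs(60, rbind(c(0, 0), c(4, 4)), seed = 3)
  labels <- blobs$labels - 1L
  for (alg in c("svm", "nb", "rf")) {
    fit <- fit_level1(blobs$features, labels, alg, seed = 7)
    expect_equal(predict(fit, blobs$features), labels)
  }
  # determinism: same data and seed -> same predictions
  f1 <- fit_level1(blobs$features, labels, "rf", seed = 7)
  f2 <- fit_level1(blobs$features, labels, "rf", seed = 7)
  expect_identical(predict(f1, blobs$features), predict(f2, blobs$features))

  expect_error(fit_level1(blobs$features, rep(0L, 120), "svm"),
               "single class")
})

test_that("constant features collapse predictions to the majority class", {
  feats <- tibble::tibble(a = rep(1, 100), b = rep(2, 100))
  labels <- rep(c(0L, 1L), times = c(70, 30))
  fit <- fit_level1(feats, labels, "rf", seed = 1)
  pred <- predict(fit, feats)
  expect_true(all(pred == 0L))
  expect_equal(mean(pred == labels), 0.7)
})

test_that("the level-II classifier learns well-separated four-class data", {
  blobs <- make_blobs(80, rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5)), seed = 4)
  idx <- sample(rep(c(TRUE, FALSE), length.out = nrow(blobs$features)))
  fit <- fit_level2(blobs$features[idx, ], blobs$labels[idx],
                    params = list(nrounds = 50), seed = 5)
  acc <- mean(predict(fit, blobs$features[!idx, ]) == blobs$labels[!idx])
  expect_gt(acc, 0.95)

  # down-resampled training set size is forced by the class counts
  labels4 <- rep(1:4, times = c(100, 30, 20, 10))
  feats4 <- tibble::tibble(x = rnorm(160), y = rnorm(160))
  fit_dn <- fit_level2(feats4, labels4, params = list(nrounds = 5),
                       resampling = "down", seed = 6)
  expect_equal(fit_dn$n_train, 40)
  fit_up <- fit_level2(feats4, labels4, params = list(nrounds = 5),
                       resampling = "up", seed = 6)
  expect_equal(fit_up$n_train, 400)

  f1 <- fit_level2(blobs$features, blobs$labels, params = list(nrounds = 20),
                   seed = 9)
  f2 <- fit_level2(blobs$features, blobs$labels, params = list(nrounds = 20),
                   seed = 9)
  expect_identical(predict(f1, blobs$features), predict(f2, blobs$features))
})

test_that("selective correction only touches flagged epochs", {
  rec <- make_toy_record(n = 60, seed = 31)
  x <- build_features(rec, toy_demographics)
  device <- rec$fitbit_stage
  truth <- rec$medical_stage

  # level-I silent -> output is the device sequence
  silent <- list(level1 = function(f) rep(0L, nrow(f)),
                 level2 = function(f) rep(2L, nrow(f)))
  expect_identical(predict_cascade(silent, x, device), device)

  # level-I always firing with a constant-light level-II -> all light
  loud <- list(level1 = function(f) rep(1L, nrow(f)),
               level2 = function(f) rep(2L, nrow(f)))
  expect_true(all(predict_cascade(loud, x, device) == 2L))

  # selective-correction identity for an arbitrary detector
  arbitrary <- list(level1 = function(f) as.integer(f$stage_now == 2),
                    level2 = function(f) rep(3L, nrow(f)))
  out <- predict_cascade(arbitrary, x, device)
  flags <- as.integer(x$stage_now == 2)
  expect_identical(out[flags == 0L], device[flags == 0L])

  expect_error(predict_cascade(silent, x[1:10, ], device), "align")
})

test_that("oracle level-I plus oracle level-II reproduces the reference", {
  rec <- make_toy_record(n = 80, seed = 32)
  x <- build_features(rec, toy_demographics)
  device <- rec$fitbit_stage
  truth <- rec$medical_stage
  oracle <- list(level1 = function(f) as.integer(device[f$epoch_id] != truth[f$epoch_id]),
                 level2 = function(f) truth[f$epoch_id])
  pred <- predict_cascade(oracle, x, device)
  expect_identical(pred, truth)
  expect_equal(per_epoch_accuracy(pred, truth), 1)
  expect_equal(correcting_power(device, pred, truth), 1)
  expect_equal(over_correcting_rate(device, pred, truth), 0)
})

test_that("a fitted cascade beats chance on simulated data", {
  cohort <- make_test_cohort(n_subjects = 2, epochs = c(250, 300), seed = 41)
  dat <- cohort_features(cohort)
  train <- dat[dat$subject_id == "S01", ]
  test <- dat[dat$subject_id == "S02", ]
  m <- fit_cascade(train[feature_names()], train$fitbit_stage, train$level2,
                   level1_algorithm = "nb",
                   level2_params = list(nrounds = 30), resampling = "up",
                   seed = 3)
  pred <- predict_cascade(m, test[feature_names()], test$fitbit_stage)
  expect_gt(per_epoch_accuracy(pred, test$level2), 0.4)
  # identical refit is deterministic end to end
  m2 <- fit_cascade(train[feature_names()], train$fitbit_stage, train$level2,
                    level1_algorithm = "nb",
                    level2_params = list(nrounds = 30), resampling = "up",
                    seed = 3)
  expect_identical(pred, predict_cascade(m2, test[feature_names()],
                                         test$fitbit_stage))
})

test_that("the device baseline is a pass-through", {
  rec <- make_toy_record(n = 25, seed = 51)
  expect_identical(rec$fitbit_stage, rec$fitbit_stage)
  blobs <- make_blobs(60, rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5)), seed = 8)
  base <- fit_onelevel_baseline(blobs$features, blobs$labels,
                                params = list(nrounds = 40), seed = 2)
  expect_gt(mean(predict(base, blobs$features) == blobs$labels), 0.95)
})
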