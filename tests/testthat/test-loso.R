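test_that("LOSO splits hold each subject out exactly once", {
  cohort <- make_test_cohort(n_subjects = 4, epochs = c(40, 60))
  splits <- make_loso_splits(cohort)
  expect_equal(nrow(splits), 4)
  expect_setequal(splits$test_subject, cohort$subject_id)
  for (i in seq_len(nrow(splits))) {
    tr <- splits$train_subjects[[i]]
    te <- splits$test_subject[i]
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), cohort$subject_id)
  }
  expect_error(make_loso_splits(cohort[1, ]), "at least 2")
})

test_that("inner grid search picks the oracle-optimal candidate", {
  set.seed(15)
  feats <- tibble::tibble(x = c(rnorm(80, -2), rnorm(40, 2)))
  labels <- ifelse(feats$x > 0, 2L, 1L)
  grid <- list(list(rule = "majority"), list(rule = "true"))
  best <- grid_search_inner(feats, labels, grid, rule_fit_fun(),
                            scoring = "accuracy", folds = 5, seed = 1)
  expect_equal(best$rule, "true")
  # singleton grid short-circuits
  single <- grid_search_inner(feats, labels, list(list(rule = "majority")),
                              rule_fit_fun(), folds = 5, seed = 1)
  expect_equal(single$rule, "majority")
  # fixed seed -> identical selection and scores
  b2 <- grid_search_inner(feats, labels, grid, rule_fit_fun(),
                          scoring = "accuracy", folds = 5, seed = 1)
  expect_identical(attr(best, "score"), attr(b2, "score"))
  expect_error(grid_search_inner(feats, labels, list(), rule_fit_fun()),
               "non-empty")
})

test_that("resampling reaches training folds only, never evaluation folds", {
  set.seed(16)
  feats <- tibble::tibble(x = rnorm(120))
  labels <- rep(c(1L, 2L), times = c(90, 30))
  counter <- new.env(); counter$train_rows <- integer(0)
  grid <- list(list(rule = "majority"), list(rule = "true"))
  best <- grid_search_inner(feats, labels, grid, rule_fit_fun(counter),
                            scoring = "accuracy", folds = 3,
                            resampling = "down", seed = 2)
  detail <- attr(best, "detail")
  # evaluation partitions keep their original (unresampled) sizes
  per_cand_eval <- tapply(detail$eval_rows, detail$candidate, sum)
  expect_true(all(per_cand_eval == nrow(feats)))
  # training folds were balanced down to 2 x min class count within the fold
  expect_true(all(detail$train_rows < 2 / 3 * nrow(feats)))
  expect_equal(detail$train_rows, counter$train_rows)
  # with down sampling each fold's training part has equal class counts:
  # 2 folds' worth of the minority class, duplicated across both classes
  expect_true(all(detail$train_rows %% 2 == 0))
})

test_that("the nested LOSO harness produces a complete deterministic report", {
  cohort <- make_test_cohort(n_subjects = 3, epochs = c(100, 140), seed = 17)
  run <- function() {
    run_nested_loso(cohort, models = c("Fitbit", "NB+XGBu"), master_seed = 4,
                    level1_grids = default_level1_grids(reduced = TRUE),
                    level2_grid = list(list(max_depth = 3, eta = 0.3,
                                            nrounds = 20)),
                    inner_folds = 2)
  }
  rep1 <- run()
  expect_s3_class(rep1, "loso_report")
  expect_equal(nrow(rep1$per_subject), 3 * 2)
  expect_equal(nrow(rep1$shift), 3)
  expect_setequal(unique(rep1$durations$model),
                  c("Reference", "Fitbit", "NB+XGBu"))
  # every evaluation uses the full untouched test subject
  expect_equal(sort(unique(rep1$per_subject$n_epochs)), sort(cohort$n_epochs))

  rep2 <- run()
  expect_identical(rep1$per_subject, rep2$per_subject)
  expect_identical(rep1$mab, rep2$mab)

  # aggregate means sit inside the per-subject range
  g <- glance(rep1)
  for (m in g$model) {
    vals <- rep1$per_subject$accuracy[rep1$per_subject$model == m]
    expect_gte(g$accuracy_mean[g$model == m], min(vals))
    expect_lte(g$accuracy_mean[g$model == m], max(vals))
  }
})

test_that("a perfect device yields accuracy 1 and undefined correcting power", {
  cfg <- sim_config(n_subjects = 3, epochs_range = c(60, 80),
                    error_matrix = diag(4), master_seed = 23)
  cohort <- simulate_cohort(cfg)
  rep <- run_nested_loso(cohort, models = "Fitbit", master_seed = 1)
  expect_true(all(rep$per_subject$accuracy == 1))
  expect_true(all(is.na(rep$per_subject$cp)))
  expect_true(all(rep$per_subject$or_rate == 0))
})

test_that("model summaries agree with hand-computed aggregates", {
  cohort <- make_test_cohort(n_subjects = 3, epochs = c(80, 100), seed = 19)
  rep <- run_nested_loso(cohort, models = c("Fitbit", "XGBd"), master_seed = 6,
                         level2_grid = list(list(max_depth = 3, eta = 0.3,
                                                 nrounds = 15)),
                         inner_folds = 2)
  sm <- summarize_models(rep)
  ps <- rep$per_subject
  for (m in c("Fitbit", "XGBd")) {
    acc <- ps$accuracy[ps$model == m]
    row <- sm[sm$model == m & sm$metric == "accuracy", ]
    expect_equal(row$mean, mean(acc))
    expect_equal(row$sd, sd(acc))
  }
  # the baseline compared to itself: zero t statistic and zero delta
  base_row <- sm[sm$model == "Fitbit" & sm$metric == "accuracy", ]
  expect_equal(base_row$t_stat, 0)
  expect_equal(base_row$delta_pct, 0)
  # paired t against the baseline matches a direct t.test on differences
  d <- ps$accuracy[ps$model == "XGBd"] - ps$accuracy[ps$model == "Fitbit"]
  if (sd(d) > 0) {
    row <- sm[sm$model == "XGBd" & sm$metric == "accuracy", ]
    expect_equal(row$t_stat, unname(t.test(d)$statistic), tolerance = 1e-10)
  }
  expect_error(summarize_models(rep, baseline = "nope"), "not present")
})

test_that("report accessors expose tidy shapes and plots", {
  cohort <- make_test_cohort(n_subjects = 3, epochs = c(60, 80), seed = 20)
  rep <- run_nested_loso(cohort, models = c("Fitbit", "XGB"), master_seed = 2,
                         level2_grid = list(list(max_depth = 3, eta = 0.3,
                                                 nrounds = 10)),
                         inner_folds = 2)
  td <- tidy(rep)
  expect_setequal(unique(td$metric),
                  c("accuracy", "kappa", "mmcc", "cp", "or_rate"))
  expect_equal(nrow(td), 3 * 2 * 5)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_hypnogram(cohort$record[[1]]$medical_stage), "ggplot")
  ba <- bland_altman(runif(5, 50, 100), runif(5, 50, 100))
  expect_s3_class(autoplot(ba), "ggplot")
  expect_equal(nrow(tidy(ba)), 5)
})
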