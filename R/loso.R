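# Nested leave-one-subject-out cross-validation harness.
#
# Outer loop: each subject held out once, models trained on the merged
# remaining subjects. Inner loop: hyperparameters tuned by stratified
# k-fold grid search on the training subjects only; resampling is applied
# inside each inner training fold, never to evaluation rows.

#' The model catalogue evaluated by the harness
#'
#' Thirteen models: the device pass-through (`Fitbit`), three one-level
#' four-class re-classifiers (`XGB`, `XGBd`, `XGBu`: XGBoost with no,
#' down and up resampling), and nine two-level cascades combining a
#' level-I detector (`NB`, `RF`, `SVM`) with the three level-II
#' resampling variants (e.g. `SVM+XGBu`).
#'
#' @return Character vector of model names.
#' @export
model_catalog <- function() {
  c("Fitbit", "XGB", "XGBd", "XGBu",
    paste0(rep(c("NB", "RF", "SVM"), each = 3),
           "+XGB", rep(c("", "d", "u"), 3)))
}

parse_model <- function(name) {
  if (name == "Fitbit") return(list(kind = "device"))
  rs_code <- function(suffix) {
    switch(paste0("x", suffix), x = "none", xd = "down", xu = "up")
  }
  m <- regmatches(name, regexec("^(NB|RF|SVM)\\+XGB(d|u)?$", name))[[1]]
  if (length(m)) {
    return(list(kind = "cascade",
                level1 = tolower(m[2]),
                resampling = rs_code(m[3])))
  }
  m <- regmatches(name, regexec("^XGB(d|u)?$", name))[[1]]
  if (length(m)) {
    return(list(kind = "onelevel", resampling = rs_code(m[2])))
  }
  abort(sprintf("Unknown model \"%s\"; see model_catalog().", name))
}

#' Leave-one-subject-out splits
#'
#' One split per subject, ordered by subject id; in each split that
#' subject is the test set and all others form the training set.
#'
#' @param cohort Cohort tibble with a `subject_id` column (>= 2
#'   subjects).
#' @return Tibble with `fold`, `test_subject` and list column
#'   `train_subjects`.
#' @export
make_loso_splits <- function(cohort) {
  ids <- sort(unique(cohort$subject_id))
  if (length(ids) < 2) abort("LOSO-CV needs at least 2 subjects.")
  tibble(
    fold = seq_along(ids),
    test_subject = ids,
    train_subjects = purrr::map(ids, ~ setdiff(ids, .x))
  )
}

stratified_fold_ids <- function(labels, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fold
  })
}

#' Inner grid search with resampling confined to training folds
#'
#' Scores every hyperparameter candidate by stratified k-fold
#' cross-validation on the supplied (training) data. Within each fold,
#' the training part may be rebalanced by [resample_training_set()]; the
#' evaluation part is never touched. Ties are broken by first-in-grid
#' order, and a singleton grid is returned directly. The returned
#' parameters carry a `detail` attribute recording, for every fold and
#' candidate, the resampled training row count and the (unresampled)
#' evaluation row count.
#'
#' @param features Training feature table.
#' @param labels Training labels (level-I 0/1 or level-II stages).
#' @param grid Non-empty list of hyperparameter lists.
#' @param fit_fun Function `(features, labels, params, seed)` returning a
#'   fitted object usable with `predict(object, features)` (or a plain
#'   prediction function).
#' @param scoring `"accuracy"` or `"kappa"` (inner model-selection
#'   metric).
#' @param folds Number of inner folds (default 10).
#' @param resampling Strategy applied to inner training folds.
#' @param seed Optional integer seed (fold assignment and resampling).
#' @return The selected hyperparameter list, with attributes `score` and
#'   `detail`.
#' @export
grid_search_inner <- function(features, labels, grid, fit_fun,
                              scoring = c("accuracy", "kappa"),
                              folds = 10, resampling = "none", seed = NULL) {
  scoring <- match.arg(scoring)
  if (length(grid) == 0) abort("Hyperparameter grid must be non-empty.")
  if (length(grid) == 1) {
    out <- grid[[1]]
    attr(out, "score") <- NA_real_
    attr(out, "detail") <- tibble(fold = integer(0), candidate = integer(0),
                                  train_rows = integer(0),
                                  eval_rows = integer(0),
                                  score = numeric(0))
    return(out)
  }
  k <- min(folds, min(table(labels)))
  if (k < 2) abort("Too few instances per class for inner cross-validation.")
  fold_id <- stratified_fold_ids(labels, k, seed = seed)
  score_fun <- if (scoring == "accuracy") {
    function(p, y) mean(p == y)
  } else {
    function(p, y) cohens_kappa(p, y)
  }
  detail <- list()
  scores <- numeric(length(grid))
  for (g in seq_along(grid)) {
    fs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold_id != f
      rs <- resample_training_set(features[tr, , drop = FALSE], labels[tr],
                                  resampling,
                                  seed = derive_seed(seed %||% 0L, f, g))
      fit <- fit_fun(rs$features, rs$labels, grid[[g]],
                     derive_seed(seed %||% 0L, f, g + 1000L))
      pred <- predict_component(fit, features[!tr, , drop = FALSE])
      fs[f] <- score_fun(pred, labels[!tr])
      detail[[length(detail) + 1]] <- tibble(
        fold = f, candidate = g,
        train_rows = nrow(rs$features), eval_rows = sum(!tr), score = fs[f])
    }
    scores[g] <- mean(fs)
  }
  best <- which.max(scores)  # which.max takes the first maximum: tie-break
  out <- grid[[best]]
  attr(out, "score") <- scores[best]
  attr(out, "detail") <- bind_rows(detail)
  out
}

#' Default level-I hyperparameter grids
#'
#' Small standard grids: SVM cost, naive-Bayes variance smoothing, random
#' forest size and features per split. `reduced = TRUE` collapses each to
#' a single sensible point for fast runs.
#'
#' @param reduced Use singleton grids?
#' @return Named list (`svm`, `nb`, `rf`) of lists of parameter lists.
#' @export
default_level1_grids <- function(reduced = FALSE) {
  if (reduced) {
    return(list(svm = list(list(cost = 1)),
                nb = list(list(eps = 1e-9)),
                rf = list(list(num_trees = 100, mtry = NULL))))
  }
  list(
    svm = lapply(c(0.01, 0.1, 1, 10), function(c) list(cost = c)),
    nb = lapply(c(1e-9, 1e-6), function(e) list(eps = e)),
    rf = {
      g <- expand.grid(num_trees = c(100, 500), mtry_rule = c("sqrt", "third"),
                       stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i) {
        list(num_trees = g$num_trees[i],
             mtry = if (g$mtry_rule[i] == "sqrt") floor(sqrt(21)) else 7L)
      })
    }
  )
}

#' Default level-II (XGBoost) hyperparameter grid
#'
#' Depth x learning rate x boosting rounds. `reduced = TRUE` returns a
#' two-point grid (shallow-fast vs deeper-slower) for quick runs.
#'
#' @param reduced Use the two-point grid?
#' @return List of parameter lists.
#' @export
default_level2_grid <- function(reduced = FALSE) {
  if (reduced) {
    return(list(list(max_depth = 3, eta = 0.3, nrounds = 50),
                list(max_depth = 6, eta = 0.1, nrounds = 100)))
  }
  g <- expand.grid(max_depth = c(3, 6, 9), eta = c(0.05, 0.1, 0.3),
                   nrounds = c(50, 100, 200))
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
}

l1_fit_fun <- function(algorithm) {
  function(features, labels, params, seed) {
    fit_level1(features, labels, algorithm, params = params, seed = seed)
  }
}

l2_fit_fun <- function() {
  function(features, labels, params, seed) {
    # resampling already applied by the caller to the training fold
    fit_level2(features, labels, params = params, resampling = "none",
               seed = seed)
  }
}

#' Run the nested LOSO-CV evaluation
#'
#' For every leave-one-subject-out split: builds features and labels for
#' the merged training subjects, tunes each required learner by inner
#' stratified grid search (level-I scored by accuracy, level-II by
#' Cohen's kappa; resampling inside training folds only), refits on the
#' full training data, and evaluates every requested model on the
#' untouched held-out subject. Level-I fits are shared across the three
#' resampling variants of a cascade family, and each level-II fit is
#' shared between the cascade and the one-level baseline that use it.
#'
#' @param cohort Cohort tibble (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param models Character vector of model names (see [model_catalog()]),
#'   or `"all"`.
#' @param master_seed Integer seed governing fold assignment, resampling
#'   and learner randomness.
#' @param level1_grids,level2_grid Hyperparameter grids (see
#'   [default_level1_grids()], [default_level2_grid()]).
#' @param inner_folds Inner CV folds (default 10).
#' @param level1_resampling Resampling for level-I training (default
#'   `"none"`).
#' @param verbose Print per-iteration progress?
#' @return Object of class `loso_report`: per-subject metrics, shift
#'   statistics, stage durations, bias table, per-model MAB,
#'   Bland-Altman summaries and performance/characteristic correlations.
#' @export
run_nested_loso <- function(cohort, models = "all", master_seed = 1L,
                            level1_grids = default_level1_grids(reduced = TRUE),
                            level2_grid = default_level2_grid(reduced = TRUE),
                            inner_folds = 10, level1_resampling = "none",
                            verbose = FALSE) {
  if (identical(models, "all")) models <- model_catalog()
  specs <- setNames(lapply(models, parse_model), models)
  splits <- make_loso_splits(cohort)
  dat <- cohort_features(cohort)
  feat_cols <- feature_names()

  l1_algs <- unique(unlist(lapply(specs, function(s) s$level1)))
  l2_strats <- unique(unlist(lapply(specs, function(s) s$resampling)))

  per_subject <- list(); shift <- list(); durations <- list()
  for (i in seq_len(nrow(splits))) {
    test_id <- splits$test_subject[i]
    tr <- dat[dat$subject_id != test_id, ]
    te <- dat[dat$subject_id == test_id, ]
    xtr <- tr[feat_cols]; xte <- te[feat_cols]
    seed_i <- derive_seed(master_seed, i, 0L)
    if (verbose) {
      message(sprintf("[loso %d/%d] test subject %s (%d train / %d test epochs)",
                      i, nrow(splits), test_id, nrow(tr), nrow(te)))
    }

    l1_fits <- list()
    for (alg in l1_algs) {
      best <- grid_search_inner(xtr, tr$level1, level1_grids[[alg]],
                                l1_fit_fun(alg), scoring = "accuracy",
                                folds = inner_folds,
                                resampling = level1_resampling,
                                seed = derive_seed(master_seed, i, 1L))
      l1_fits[[alg]] <- fit_level1(xtr, tr$level1, alg, params = best,
                                   resampling = level1_resampling,
                                   seed = seed_i)
    }
    l2_fits <- list()
    for (strat in l2_strats) {
      best <- grid_search_inner(xtr, tr$level2, level2_grid, l2_fit_fun(),
                                scoring = "kappa", folds = inner_folds,
                                resampling = strat,
                                seed = derive_seed(master_seed, i, 2L))
      l2_fits[[strat]] <- fit_level2(xtr, tr$level2, params = best,
                                     resampling = strat, seed = seed_i)
    }

    durations[[length(durations) + 1]] <- stage_durations(te$level2) %>%
      mutate(subject_id = test_id, model = "Reference")
    for (mn in names(specs)) {
      sp <- specs[[mn]]
      pred <- switch(sp$kind,
        device = te$fitbit_stage,
        onelevel = predict(l2_fits[[sp$resampling]], xte),
        cascade = predict_cascade(
          list(level1 = l1_fits[[sp$level1]], level2 = l2_fits[[sp$resampling]]),
          xte, te$fitbit_stage)
      )
      cp <- withCallingHandlers(
        correcting_power(te$fitbit_stage, pred, te$level2),
        sleepcascade_undefined_metric = function(w) invokeRestart("muffleWarning"))
      orr <- withCallingHandlers(
        over_correcting_rate(te$fitbit_stage, pred, te$level2),
        sleepcascade_undefined_metric = function(w) invokeRestart("muffleWarning"))
      mcc_val <- withCallingHandlers(
        mmcc(pred, te$level2),
        sleepcascade_undefined_metric = function(w) invokeRestart("muffleWarning"))
      per_subject[[length(per_subject) + 1]] <- tibble(
        subject_id = test_id, model = mn,
        accuracy = per_epoch_accuracy(pred, te$level2),
        kappa = cohens_kappa(pred, te$level2),
        mmcc = mcc_val,
        cp = cp, or_rate = orr, n_epochs = nrow(te)
      )
      durations[[length(durations) + 1]] <- stage_durations(pred) %>%
        mutate(subject_id = test_id, model = mn)
    }
    shift[[length(shift) + 1]] <- tibble(
      subject_id = test_id,
      sdi = shannon_diversity(te$level2),
      ad = ad_shift(tr$level2, te$level2)
    )
  }

  per_subject <- bind_rows(per_subject)
  shift <- bind_rows(shift)
  durations <- bind_rows(durations) %>%
    select("subject_id", "model", "stage", "label", "minutes")

  bias <- bias_table(durations)
  mab_tbl <- if (length(unique(bias$model)) >= 2) {
    tibble(model = unique(bias$model)) %>%
      mutate(mab = purrr::map_dbl(.data$model, ~ mab(bias, .x)))
  } else {
    tibble(model = character(0), mab = numeric(0))
  }

  ba <- durations %>%
    filter(.data$model != "Reference") %>%
    left_join(durations %>% filter(.data$model == "Reference") %>%
                select("subject_id", "stage", ref = "minutes"),
              by = c("subject_id", "stage")) %>%
    group_by(.data$model, .data$stage, .data$label) %>%
    summarise(res = list(if (n() >= 3) glance(bland_altman(.data$minutes, .data$ref))
                         else NULL),
              .groups = "drop") %>%
    filter(!purrr::map_lgl(.data$res, is.null)) %>%
    tidyr::unnest("res")

  corr <- per_subject %>%
    left_join(shift, by = "subject_id") %>%
    tidyr::pivot_longer(c("accuracy", "kappa", "mmcc", "cp", "or_rate"),
                        names_to = "metric", values_to = "value") %>%
    tidyr::pivot_longer(c("sdi", "ad"), names_to = "characteristic",
                        values_to = "stat") %>%
    group_by(.data$model, .data$metric, .data$characteristic) %>%
    summarise(res = list({
      ok <- complete.cases(.data$value, .data$stat)
      if (sum(ok) >= 3 && var(.data$value[ok]) > 0 && var(.data$stat[ok]) > 0) {
        correlate_performance(.data$value[ok], .data$stat[ok])
      } else {
        tibble(r = NA_real_, p = NA_real_, n = sum(ok))
      }
    }), .groups = "drop") %>%
    tidyr::unnest("res")

  structure(list(
    per_subject = per_subject, shift = shift, durations = durations,
    bias = bias, mab = mab_tbl, bland_altman = ba, correlations = corr,
    models = models, n_subjects = nrow(splits), master_seed = master_seed
  ), class = "loso_report")
}
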