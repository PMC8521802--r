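# Two-level selective-correction cascade.
#
# Level I: binary detector of device misclassification (naive Bayes,
# random forest, or linear SVM). Level II: XGBoost four-stage
# re-classifier, optionally trained on a resampled (balanced) training
# set. Prediction keeps the device label wherever level I says "correct"
# and substitutes the level-II stage elsewhere.

default_level1_params <- function(algorithm) {
  switch(algorithm,
         svm = list(cost = 1),
         nb = list(eps = 1e-9),
         rf = list(num_trees = 500, mtry = NULL),
         abort(sprintf("Unknown level-I algorithm \"%s\".", algorithm)))
}

default_level2_params <- function() {
  list(max_depth = 6, eta = 0.1, nrounds = 100)
}

as_feature_matrix <- function(features) {
  m <- as.matrix(as.data.frame(features))
  storage.mode(m) <- "double"
  m
}

#' Fit the level-I misclassification detector
#'
#' Trains a binary classifier predicting whether the device's stage label
#' for an epoch is wrong (1) or right (0). Three algorithms are
#' supported: Gaussian naive Bayes, random forest, and a linear-kernel
#' SVM. Features are z-score standardized (statistics fitted on the
#' training partition) for the SVM only; the other learners consume raw
#' features.
#'
#' @param features Data frame of the 21 epoch features.
#' @param labels Binary vector in `{0, 1}`; both classes must be present.
#' @param algorithm `"svm"`, `"nb"` or `"rf"`.
#' @param params Hyperparameters: `cost` (SVM), `eps` (NB variance
#'   smoothing at prediction), `num_trees`/`mtry` (RF). Missing entries
#'   take defaults.
#' @param resampling Optional rebalancing of the training rows
#'   (see [resample_training_set()]); default `"none"`.
#' @param seed Optional integer seed (controls RF bootstrap and
#'   resampling).
#' @return Object of class `level1_fit`; `predict()` returns an integer
#'   0/1 vector.
#' @export
fit_level1 <- function(features, labels, algorithm = c("svm", "nb", "rf"),
                       params = list(), resampling = "none", seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (!all(labels %in% c(0, 1))) abort("Level-I labels must be 0/1.")
  if (length(unique(labels)) < 2) {
    abort("Level-I training labels contain a single class; cannot fit.")
  }
  params <- utils::modifyList(default_level1_params(algorithm), params)
  rs <- resample_training_set(features, labels, resampling,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  x <- as_feature_matrix(rs$features)
  y <- factor(rs$labels, levels = c(0, 1))
  center <- scale <- NULL
  fit <- with_seed(seed, {
    if (algorithm == "svm") {
      center <- colMeans(x)
      scale <- apply(x, 2, sd)
      scale[scale == 0] <- 1
      xs <- sweep(sweep(x, 2, center), 2, scale, "/")
      e1071::svm(xs, y, kernel = "linear", cost = params$cost, scale = FALSE)
    } else if (algorithm == "nb") {
      e1071::naiveBayes(x, y)
    } else {
      ranger::ranger(
        x = x, y = y,
        num.trees = params$num_trees,
        mtry = params$mtry %||% floor(sqrt(ncol(x))),
        seed = if (is.null(seed)) 1L else seed,
        num.threads = 1
      )
    }
  })
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 center = center, scale = scale),
            class = "level1_fit")
}

#' @export
predict.level1_fit <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  out <- switch(object$algorithm,
    svm = {
      xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
      predict(object$fit, xs)
    },
    nb = predict(object$fit, x, type = "class", eps = object$params$eps),
    rf = predict(object$fit, data = x, num.threads = 1)$predictions
  )
  as.integer(as.character(out))
}

#' Fit the level-II four-stage re-classifier
#'
#' Trains an XGBoost multiclass model predicting the reference stage
#' (1 deep, 2 light, 3 REM, 4 wake) of every epoch. Class imbalance --
#' light sleep typically dominates the night -- can be countered by
#' random up or down resampling, applied to the training rows only.
#'
#' @param features Data frame of the 21 epoch features.
#' @param labels Stage vector in `{1, 2, 3, 4}`.
#' @param params XGBoost hyperparameters `max_depth`, `eta`, `nrounds`;
#'   missing entries take defaults.
#' @param resampling `"none"`, `"up"` or `"down"`.
#' @param seed Optional integer seed.
#' @return Object of class `level2_fit`; `predict()` returns stage codes
#'   1-4.
#' @export
fit_level2 <- function(features, labels, params = list(),
                       resampling = c("none", "up", "down"), seed = NULL) {
  resampling <- match.arg(resampling)
  labels <- assert_stages(labels, "labels", allow_empty = FALSE)
  params <- utils::modifyList(default_level2_params(), params)
  rs <- resample_training_set(features, labels, resampling,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  x <- as_feature_matrix(rs$features)
  fit <- with_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "multi:softmax", num_class = 4,
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1, seed = if (is.null(seed)) 0 else seed),
      data = xgboost::xgb.DMatrix(x, label = rs$labels - 1L),
      nrounds = params$nrounds, verbose = 0
    )
  })
  structure(list(fit = fit, params = params, resampling = resampling,
                 n_train = nrow(x)),
            class = "level2_fit")
}

#' @export
predict.level2_fit <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  as.integer(predict(object$fit, xgboost::xgb.DMatrix(x))) + 1L
}

#' Fit a complete two-level cascade
#'
#' Derives the level-I (device right/wrong) and level-II (reference
#' stage) labels from the training record and fits both classifiers on
#' the same 21-feature table.
#'
#' @param features Data frame of the 21 epoch features.
#' @param device_stages,reference_stages Aligned stage vectors for the
#'   training epochs.
#' @param level1_algorithm `"svm"`, `"nb"` or `"rf"`.
#' @param level1_params,level2_params Hyperparameter lists (see
#'   [fit_level1()], [fit_level2()]).
#' @param resampling Level-II resampling strategy.
#' @param level1_resampling Level-I resampling strategy (default off).
#' @param seed Optional integer seed.
#' @return Object of class `cascade_model` with components `level1` and
#'   `level2`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 2,
#'                                      epochs_range = c(150, 200)))
#' dat <- cohort_features(cohort)
#' m <- fit_cascade(dat[feature_names()], dat$fitbit_stage, dat$level2,
#'                  level1_algorithm = "nb",
#'                  level2_params = list(nrounds = 20), seed = 1)
#' pred <- predict_cascade(m, dat[feature_names()], dat$fitbit_stage)
#' @export
fit_cascade <- function(features, device_stages, reference_stages,
                        level1_algorithm = "svm",
                        level1_params = list(), level2_params = list(),
                        resampling = "none", level1_resampling = "none",
                        seed = NULL) {
  labels <- convert_labels(device_stages, reference_stages)
  structure(list(
    level1 = fit_level1(features, labels$level1, level1_algorithm,
                        params = level1_params,
                        resampling = level1_resampling, seed = seed),
    level2 = fit_level2(features, labels$level2, params = level2_params,
                        resampling = resampling, seed = seed),
    meta = list(level1_algorithm = level1_algorithm,
                resampling = resampling, seed = seed)
  ), class = "cascade_model")
}

# Components may be fitted objects (predict() dispatch) or plain
# functions features -> labels, which makes oracle-composition checks easy.
predict_component <- function(component, features) {
  if (is.function(component)) component(features) else predict(component, features)
}

#' Apply selective correction to a night of device labels
#'
#' Runs the level-I detector over every epoch; epochs judged correctly
#' labelled keep their device stage, epochs judged misclassified receive
#' the level-II predicted stage. Output stages therefore differ from the
#' device's only where level I fired.
#'
#' @param model A `cascade_model`, or any list with components `level1`
#'   and `level2` (fitted objects or plain prediction functions).
#' @param features Feature table aligned 1:1 with `device_stages`.
#' @param device_stages Device stage codes for the same epochs.
#' @return Integer vector of corrected stage codes.
#' @export
predict_cascade <- function(model, features, device_stages) {
  device_stages <- assert_stages(device_stages, "device_stages")
  if (nrow(features) != length(device_stages)) {
    abort("`features` rows and `device_stages` must align 1:1.")
  }
  flagged <- as.integer(predict_component(model$level1, features))
  if (!all(flagged %in% c(0L, 1L))) {
    abort("Level-I predictions must be 0/1.")
  }
  out <- device_stages
  if (any(flagged == 1L)) {
    idx <- which(flagged == 1L)
    relab <- predict_component(model$level2, features[idx, , drop = FALSE])
    out[idx] <- assert_stages(relab, "level-II predictions")
  }
  out
}

#' Fit a one-level re-classification baseline
#'
#' The one-level baselines re-classify *every* epoch with a four-class
#' XGBoost model (optionally resampled), instead of selectively
#' correcting flagged epochs. The device pass-through baseline needs no
#' fitting: its predictions are the device stages themselves.
#'
#' @inheritParams fit_level2
#' @return Object of class `level2_fit` (applied to all epochs).
#' @export
fit_onelevel_baseline <- function(features, labels, params = list(),
                                  resampling = c("none", "up", "down"),
                                  seed = NULL) {
  fit_level2(features, labels, params = params,
             resampling = resampling, seed = seed)
}
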