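# Macroscopic (duration-level) agreement: Bland-Altman analysis and the
# mean normalized absolute bias across models.

#' Bland-Altman agreement analysis
#'
#' Compares per-subject values of a sleep metric (e.g. minutes of deep
#' sleep) estimated by a model against the reference. Differences are
#' taken as `reference - model`, so a positive bias means the model
#' underestimates. Reports the mean difference (bias), the 95% limits of
#' agreement `bias +/- 1.96 SD`, a two-tailed one-sample t-test of the
#' bias against 0, and the least-squares slope of the differences on the
#' pair means with its test (a proportional-trend check).
#'
#' @param model_values,true_values Paired numeric vectors, `n >= 3`.
#' @return Object of class `ba_result`; see [glance.ba_result()].
#' @examples
#' ba <- bland_altman(c(100, 110, 118), c(101, 112, 121))
#' glance(ba)
#' @export
bland_altman <- function(model_values, true_values) {
  if (length(model_values) != length(true_values)) {
    abort("`model_values` and `true_values` must be paired (equal length).")
  }
  n <- length(model_values)
  if (n < 3) abort("Bland-Altman analysis needs at least 3 pairs.")
  diffs <- true_values - model_values
  means <- (true_values + model_values) / 2
  bias <- mean(diffs)
  s <- sd(diffs)
  if (s == 0) {
    t_stat <- if (bias == 0) 0 else sign(bias) * Inf
    p <- if (bias == 0) 1 else 0
  } else {
    tt <- t.test(diffs, mu = 0)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  if (var(means) == 0) {
    slope <- 0; slope_p <- NA_real_
  } else {
    fit <- lm(diffs ~ means)
    slope <- unname(coef(fit)[2])
    # summary.lm warns on an essentially perfect fit; the NA guard below
    # already covers that case
    cf <- suppressWarnings(summary(fit)$coefficients)
    slope_p <- if (nrow(cf) >= 2 && !is.nan(cf[2, 4])) cf[2, 4] else NA_real_
  }
  structure(list(
    n = n, bias = bias, sd = s,
    loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
    t_stat = t_stat, p_value = p,
    slope = slope, slope_p = slope_p,
    data = tibble(mean = means, difference = diffs)
  ), class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.3f [LOA %.3f, %.3f], t = %.3f (p = %.3g), trend slope %.4f (p = %.3g)\n",
    x$n, x$bias, x$loa_lower, x$loa_upper, x$t_stat, x$p_value,
    x$slope, x$slope_p))
  invisible(x)
}

#' Glance at a Bland-Altman result
#'
#' @param x A `ba_result`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `bias`, `sd`, `loa_lower`,
#'   `loa_upper`, `t_stat`, `p_value`, `slope`, `slope_p`.
#' @method glance ba_result
#' @export
glance.ba_result <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd = x$sd,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper,
         t_stat = x$t_stat, p_value = x$p_value,
         slope = x$slope, slope_p = x$slope_p)
}

#' Tidy the paired differences of a Bland-Altman result
#'
#' @param x A `ba_result`.
#' @param ... Unused.
#' @return Tibble with one row per pair: `mean`, `difference`.
#' @method tidy ba_result
#' @export
tidy.ba_result <- function(x, ...) {
  x$data
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias line (solid), the 95%
#' limits of agreement (dashed) and the fitted trend (dotted).
#'
#' @param object A `ba_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ba_result
#' @export
autoplot.ba_result <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "Mean of reference and model (min)",
                  y = "Reference - model (min)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Mean normalized absolute bias of a model
#'
#' Given the per-stage signed biases of several competing models (the
#' mean reference-minus-model duration differences), the absolute bias
#' of each model for each stage is min-max normalized across models, and
#' the four normalized values (wake, light, deep, REM) are averaged:
#' `MAB_j = (1/4) sum_i (|e_ij| - min_i) / (max_i - min_i)`.
#' A model attaining the smallest absolute bias in every stage scores 0,
#' the largest in every stage scores 1. A stage where all models tie
#' (`max = min`) contributes 0 by convention.
#'
#' @param bias_table Tibble with columns `model`, `stage` (codes 1-4 or
#'   labels) and `bias` (signed, minutes); at least two models.
#' @param model Model identifier to score.
#' @return Value in `[0, 1]`.
#' @examples
#' bt <- tidyr::expand_grid(model = c("A", "B"), stage = 1:4)
#' bt$bias <- ifelse(bt$model == "A", 1, 3)
#' mab(bt, "A"); mab(bt, "B")
#' @export
mab <- function(bias_table, model) {
  need <- c("model", "stage", "bias")
  if (!is.data.frame(bias_table) || !all(need %in% names(bias_table))) {
    abort("`bias_table` must have columns model, stage, bias.")
  }
  if (length(unique(bias_table$model)) < 2) {
    abort("`bias_table` must contain at least two models.")
  }
  if (!model %in% bias_table$model) {
    abort(sprintf("Model \"%s\" is absent from `bias_table`.", model))
  }
  terms <- bias_table %>%
    mutate(abs_bias = abs(.data$bias)) %>%
    group_by(.data$stage) %>%
    mutate(lo = min(.data$abs_bias), hi = max(.data$abs_bias)) %>%
    ungroup() %>%
    filter(.data$model == !!model) %>%
    mutate(term = ifelse(.data$hi > .data$lo,
                         (.data$abs_bias - .data$lo) / (.data$hi - .data$lo),
                         0))
  if (nrow(terms) != 4) {
    abort("`bias_table` must contain exactly the four stages per model.")
  }
  mean(terms$term)
}

#' Per-stage duration bias table across models
#'
#' Builds the input of [mab()] from per-subject stage durations: for each
#' model and stage, the bias is the mean over subjects of
#' `reference minutes - model minutes`.
#'
#' @param durations Tibble with columns `subject_id`, `model`, `stage`,
#'   `minutes`, including a reference model named by `reference`.
#' @param reference Name of the reference model (default
#'   `"Reference"`).
#' @return Tibble `model`, `stage`, `bias` (reference excluded).
#' @export
bias_table <- function(durations, reference = "Reference") {
  need <- c("subject_id", "model", "stage", "minutes")
  if (!is.data.frame(durations) || !all(need %in% names(durations))) {
    abort("`durations` must have columns subject_id, model, stage, minutes.")
  }
  if (!reference %in% durations$model) {
    abort(sprintf("Reference model \"%s\" absent from `durations`.", reference))
  }
  ref <- durations %>%
    filter(.data$model == reference) %>%
    select("subject_id", "stage", ref_minutes = "minutes")
  durations %>%
    filter(.data$model != reference) %>%
    left_join(ref, by = c("subject_id", "stage")) %>%
    group_by(.data$model, .data$stage) %>%
    summarise(bias = mean(.data$ref_minutes - .data$minutes),
              .groups = "drop")
}
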