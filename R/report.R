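# Report methods for nested LOSO-CV results.

#' Tidy per-subject results of a LOSO report
#'
#' @param x A `loso_report`.
#' @param ... Unused.
#' @return Long tibble: `subject_id`, `model`, `metric`, `value`.
#' @method tidy loso_report
#' @export
tidy.loso_report <- function(x, ...) {
  x$per_subject %>%
    tidyr::pivot_longer(c("accuracy", "kappa", "mmcc", "cp", "or_rate"),
                        names_to = "metric", values_to = "value")
}

#' Aggregate a LOSO report across subjects
#'
#' Mean and SD of every microscopic metric per model, joined with the
#' model's mean normalized absolute bias.
#'
#' @param x A `loso_report`.
#' @param ... Unused.
#' @return Tibble with one row per model.
#' @method glance loso_report
#' @export
glance.loso_report <- function(x, ...) {
  agg <- x$per_subject %>%
    group_by(.data$model) %>%
    summarise(across(c("accuracy", "kappa", "mmcc", "cp", "or_rate"),
                     list(mean = ~ mean(.x, na.rm = TRUE),
                          sd = ~ sd(.x, na.rm = TRUE))),
              n_subjects = dplyr::n(), .groups = "drop")
  left_join(agg, x$mab, by = "model")
}

#' Compare every model against the device baseline
#'
#' For accuracy, kappa and MMCC: per-model mean and SD across held-out
#' subjects, the relative change against the device pass-through
#' baseline (percent), and a paired two-tailed t-test of the per-subject
#' metric differences against the baseline. The paired form matches the
#' within-subject design: every subject yields one value per model.
#'
#' @param report A `loso_report` containing the `Fitbit` baseline.
#' @param baseline Baseline model name (default `"Fitbit"`).
#' @return Tibble: `model`, `metric`, `mean`, `sd`, `delta_pct`,
#'   `t_stat`, `p_value`.
#' @export
summarize_models <- function(report, baseline = "Fitbit") {
  stopifnot(inherits(report, "loso_report"))
  if (!baseline %in% report$per_subject$model) {
    abort(sprintf("Baseline \"%s\" not present in the report.", baseline))
  }
  long <- tidy(report) %>%
    filter(.data$metric %in% c("accuracy", "kappa", "mmcc"))
  base <- long %>%
    filter(.data$model == baseline) %>%
    select("subject_id", "metric", base_value = "value")
  long %>%
    left_join(base, by = c("subject_id", "metric")) %>%
    group_by(.data$model, .data$metric) %>%
    summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      delta_pct = delta_improvement(mean(.data$value),
                                    mean(.data$base_value)),
      t_stat = {
        d <- .data$value - .data$base_value
        if (sd(d) == 0) 0 else unname(t.test(d)$statistic)
      },
      p_value = {
        d <- .data$value - .data$base_value
        if (sd(d) == 0) NA_real_ else t.test(d)$p.value
      },
      .groups = "drop"
    ) %>%
    arrange(.data$metric, dplyr::desc(.data$mean))
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf("Nested LOSO-CV report: %d subjects, %d models (seed %d)\n\n",
              x$n_subjects, length(x$models), x$master_seed))
  print(as.data.frame(glance(x)[c("model", "accuracy_mean", "accuracy_sd",
                                  "kappa_mean", "mmcc_mean", "mab")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.loso_report <- function(object, ...) {
  summarize_models(object)
}

#' Boxplots of per-subject performance by model
#'
#' @param object A `loso_report`.
#' @param metrics Metrics to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loso_report
#' @export
autoplot.loso_report <- function(object,
                                 metrics = c("accuracy", "kappa", "mmcc"),
                                 ...) {
  tidy(object) %>%
    filter(.data$metric %in% metrics) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Held-out per-subject performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a hypnogram
#'
#' Step plot of stage codes over the night, on the conventional inverted
#' axis (wake on top, deep sleep at the bottom).
#'
#' @param stages Integer stage vector.
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(stages) {
  stages <- assert_stages(stages, "stages", allow_empty = FALSE)
  tibble(hours = (seq_along(stages) - 1) / 120, stage = stages) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$hours, y = .data$stage)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_reverse(breaks = STAGES, labels = STAGE_LABELS) +
    ggplot2::labs(x = "Time from record start (h)", y = NULL,
                  title = "Hypnogram") +
    ggplot2::theme_minimal()
}
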