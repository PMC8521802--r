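# Epoch-wise feature construction: 10 static + 11 dynamic = 21 features.

#' Names of the 21 epoch features, in fixed column order
#'
#' Ten static features (demographics and daily sleep metrics, constant
#' within a night) followed by eleven dynamic ones (epoch index, the
#' device stage at offsets -3..+3, the epoch's mean heart rate and its
#' changes against the neighbouring epochs).
#'
#' @return Character vector of length 21.
#' @export
feature_names <- function() {
  c("age", "sex", "psqi",
    "tst_min", "waso_min", "se_percent",
    "wake_ratio", "light_ratio", "deep_ratio", "rem_ratio",
    "epoch_id",
    "stage_lag3", "stage_lag2", "stage_lag1", "stage_now",
    "stage_lead1", "stage_lead2", "stage_lead3",
    "hr_mean", "hr_diff_prev", "hr_diff_next")
}

# shift with replication padding at the boundaries
shift_pad <- function(x, k) {
  n <- length(x)
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  x[idx]
}

#' Build the 21-column epoch feature table
#'
#' One row per epoch. Static features are the subject's demographics
#' (age, sex, PSQI) and the device-derived daily sleep metrics (TST,
#' WASO, SE and the four stage ratios, computed from the device stages
#' unless `metrics` is supplied). Dynamic features are the epoch index,
#' the device stage for the current epoch and the three preceding and
#' three succeeding epochs (boundary offsets replicate the nearest
#' existing epoch), the epoch mean heart rate, and the heart-rate change
#' against the previous epoch and of the next epoch against the current
#' one (0 at the boundaries, consistent with replication padding).
#'
#' @param record Tibble with `epoch_id`, `fitbit_stage`, `hr_mean`
#'   (as produced by [align_epochs()]).
#' @param demographics List or one-row data frame with `age`, `sex`
#'   (0 male / 1 female), `psqi`.
#' @param metrics Optional one-row tibble from [compute_daily_metrics()];
#'   computed from `record$fitbit_stage` when `NULL`.
#' @return Tibble with exactly the 21 columns of [feature_names()].
#' @examples
#' truth <- simulate_hypnogram(50, seed = 1)
#' rec <- align_epochs(corrupt_stages(truth, seed = 2), truth,
#'                     simulate_heart_rate(truth, seed = 3))
#' x <- build_features(rec, list(age = 25, sex = 1, psqi = 4))
#' ncol(x)
#' @export
build_features <- function(record, demographics, metrics = NULL) {
  need <- c("epoch_id", "fitbit_stage", "hr_mean")
  if (!is.data.frame(record) || !all(need %in% names(record))) {
    abort("`record` must have columns epoch_id, fitbit_stage, hr_mean.")
  }
  n <- nrow(record)
  if (n < 1) abort("`record` must contain at least one epoch.")
  if (anyNA(record[need])) abort("`record` must be complete (no NA) after alignment.")
  for (f in c("age", "sex", "psqi")) {
    if (is.null(demographics[[f]])) {
      abort(sprintf("`demographics` must supply `%s`.", f))
    }
  }
  if (is.null(metrics)) metrics <- compute_daily_metrics(record$fitbit_stage)

  s <- as.integer(record$fitbit_stage)
  hr <- as.numeric(record$hr_mean)
  tibble(
    age = rep(as.numeric(demographics$age), n),
    sex = rep(as.numeric(demographics$sex), n),
    psqi = rep(as.numeric(demographics$psqi), n),
    tst_min = rep(metrics$tst_min, n),
    waso_min = rep(metrics$waso_min, n),
    se_percent = rep(metrics$se_percent, n),
    wake_ratio = rep(metrics$wake_ratio, n),
    light_ratio = rep(metrics$light_ratio, n),
    deep_ratio = rep(metrics$deep_ratio, n),
    rem_ratio = rep(metrics$rem_ratio, n),
    epoch_id = as.numeric(record$epoch_id),
    stage_lag3 = as.numeric(shift_pad(s, -3L)),
    stage_lag2 = as.numeric(shift_pad(s, -2L)),
    stage_lag1 = as.numeric(shift_pad(s, -1L)),
    stage_now = as.numeric(s),
    stage_lead1 = as.numeric(shift_pad(s, 1L)),
    stage_lead2 = as.numeric(shift_pad(s, 2L)),
    stage_lead3 = as.numeric(shift_pad(s, 3L)),
    hr_mean = hr,
    hr_diff_prev = hr - shift_pad(hr, -1L),
    hr_diff_next = shift_pad(hr, 1L) - hr
  )
}

#' Features and labels for every subject of a cohort
#'
#' Convenience wrapper running [build_features()] and [convert_labels()]
#' over each subject of a simulated (or imported) cohort.
#'
#' @param cohort Cohort tibble from [simulate_cohort()] or
#'   [read_cohort()].
#' @return Tibble with `subject_id`, the 21 feature columns, `level1`,
#'   `level2` and `fitbit_stage`, one row per epoch.
#' @export
cohort_features <- function(cohort) {
  purrr::pmap(
    list(cohort$subject_id, cohort$record,
         cohort$age, cohort$sex, cohort$psqi),
    function(id, rec, age, sex, psqi) {
      x <- build_features(rec, list(age = age, sex = sex, psqi = psqi))
      y <- convert_labels(rec$fitbit_stage, rec$medical_stage)
      dplyr::bind_cols(tibble(subject_id = id), x,
                       y[c("level1", "level2")],
                       tibble(fitbit_stage = as.integer(rec$fitbit_stage)))
    }
  ) %>% bind_rows()
}
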