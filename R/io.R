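# Plain-text cohort and configuration I/O.

#' Export a cohort to a directory of CSV files
#'
#' Writes `manifest.csv` (`subject_id`, `age`, `sex`, `psqi`), one
#' `<subject>_epochs.csv` per subject (`epoch_id`, `fitbit_stage`,
#' `medical_stage`, `hr_mean`) and, when raw heart rate is present, one
#' `<subject>_hr.csv` (`timestamp_s`, `bpm`). Output is deterministic:
#' the same cohort always produces byte-identical files.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort[c("subject_id", "age", "sex", "psqi")],
                   file.path(dir, "manifest.csv"))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    readr::write_csv(cohort$record[[i]],
                     file.path(dir, paste0(id, "_epochs.csv")))
    if (!is.null(cohort$heart_rate)) {
      readr::write_csv(cohort$heart_rate[[i]],
                       file.path(dir, paste0(id, "_hr.csv")))
    }
  }
  invisible(dir)
}

#' Read a cohort back from a directory of CSV files
#'
#' Inverse of [write_cohort()]; the round trip reproduces the cohort
#' tables exactly.
#'
#' @param dir Directory written by [write_cohort()].
#' @return Cohort tibble.
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_csv(
    file.path(dir, "manifest.csv"),
    col_types = readr::cols(subject_id = readr::col_character(),
                            age = readr::col_double(),
                            sex = readr::col_integer(),
                            psqi = readr::col_integer()))
  records <- purrr::map(manifest$subject_id, function(id) {
    readr::read_csv(
      file.path(dir, paste0(id, "_epochs.csv")),
      col_types = readr::cols(epoch_id = readr::col_integer(),
                              fitbit_stage = readr::col_integer(),
                              medical_stage = readr::col_integer(),
                              hr_mean = readr::col_double()))
  })
  hr_files <- file.path(dir, paste0(manifest$subject_id, "_hr.csv"))
  out <- manifest %>%
    mutate(n_epochs = purrr::map_int(records, nrow), record = records)
  if (all(file.exists(hr_files))) {
    out$heart_rate <- purrr::map(hr_files, function(f) {
      readr::read_csv(f, col_types = readr::cols(
        timestamp_s = readr::col_integer(), bpm = readr::col_double()))
    })
  }
  out
}

#' Write a simulator configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- list(
    n_subjects = config$n_subjects,
    epochs_range = config$epochs_range,
    transition = apply(config$transition, 1, as.numeric, simplify = FALSE),
    target_proportions = config$target_proportions,
    error_matrix = apply(config$error_matrix, 1, as.numeric, simplify = FALSE),
    hr_spec = list(means = as.list(config$hr_spec$means),
                   sds = as.list(config$hr_spec$sds),
                   baseline_sd = config$hr_spec$baseline_sd),
    hr_missing_rate = config$hr_missing_rate,
    demographics = config$demographics,
    master_seed = config$master_seed
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a simulator configuration from YAML
#'
#' @param path File written by [write_sim_config()].
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  as_mat <- function(rows) {
    m <- do.call(rbind, lapply(rows, as.numeric))
    dimnames(m) <- list(STAGE_LABELS, STAGE_LABELS)
    m
  }
  sim_config(
    n_subjects = obj$n_subjects,
    epochs_range = unlist(obj$epochs_range),
    transition = as_mat(obj$transition),
    target_proportions = lapply(obj$target_proportions, unlist),
    error_matrix = as_mat(obj$error_matrix),
    hr_spec = sleep_hr_spec(means = unlist(obj$hr_spec$means),
                            sds = unlist(obj$hr_spec$sds),
                            baseline_sd = obj$hr_spec$baseline_sd),
    hr_missing_rate = obj$hr_missing_rate,
    demographics = obj$demographics,
    master_seed = obj$master_seed
  )
}
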