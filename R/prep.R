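# Preprocessing: vendor label mapping, stream alignment + interpolation,
# daily sleep metrics, level-I/level-II label conversion.

#' Map vendor stage labels to numeric codes
#'
#' Converts device labels (`deep`, `light`, `REM`, `wake`, optionally
#' suffixed with "sleep"/"fulness") or clinical reference labels
#' (`N1`, `N2`, `N3`, `R`, `W`, optionally prefixed with "stage") to the
#' common coding 1 deep, 2 light, 3 REM, 4 wake. N1 and N2 both map to
#' light sleep (2); N3 maps to deep sleep (1).
#'
#' @param raw_labels Character vector of vendor labels.
#' @param source `"device"` (consumer tracker vocabulary) or
#'   `"reference"` (clinical N1/N2/N3/R/W vocabulary).
#' @return Integer vector of stage codes.
#' @examples
#' map_stage_labels(c("W", "N1", "N2", "N3", "R"), "reference")
#' map_stage_labels(c("deep sleep", "light sleep", "REM sleep",
#'                    "wakefulness"), "device")
#' @export
map_stage_labels <- function(raw_labels, source = c("device", "reference")) {
  source <- match.arg(source)
  if (length(raw_labels) == 0) return(integer(0))
  key <- tolower(trimws(raw_labels))
  key <- gsub("^stage\\s*", "", key)
  key <- gsub("\\s*sleep$", "", key)
  key <- gsub("fulness$", "", key)  # "wakefulness" -> "wake"
  map <- if (source == "device") {
    c(deep = 1L, light = 2L, rem = 3L, wake = 4L)
  } else {
    c(n3 = 1L, n1 = 2L, n2 = 2L, r = 3L, w = 4L,
      # tolerate spelled-out clinical exports
      rem = 3L, wake = 4L)
  }
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(sprintf("Unknown %s stage label \"%s\" at position %d.",
                  source, raw_labels[bad], bad),
          class = "sleepcascade_label_error")
  }
  out
}

# Accept either a bare stage vector (epochs assumed 1..N) or a tibble with
# epoch_id + stage columns; return tibble(epoch_id, stage).
as_stage_tbl <- function(x, arg) {
  if (is.data.frame(x)) {
    stage_col <- intersect(c("stage", "fitbit_stage", "medical_stage"),
                           names(x))[1]
    if (is.na(stage_col) || !"epoch_id" %in% names(x)) {
      abort(sprintf("`%s` must have columns `epoch_id` and `stage`.", arg))
    }
    tibble(epoch_id = as.integer(x$epoch_id),
           stage = as.integer(x[[stage_col]]))
  } else {
    tibble(epoch_id = seq_along(x), stage = as.integer(x))
  }
}

#' Align device, reference and heart-rate streams into an epoch record
#'
#' Restricts both stage streams to their overlapping epoch span, averages
#' the heart-rate samples falling in each 30-s epoch (half-open window
#' `[epoch start, epoch end)`), fills epochs without any sample by linear
#' interpolation between neighbouring epoch means (edges extended), and
#' fills missing stage epochs by carrying the previous observation
#' forward. A stream with more than `max_missing` of its epochs missing
#' causes rejection of the whole record, mirroring the night-exclusion
#' rule used when screening wearable recordings.
#'
#' @param device,reference Stage streams: integer vectors (epochs 1..N)
#'   or tibbles with `epoch_id` and `stage`. `NA` marks a missing epoch.
#' @param heart_rate Tibble with `timestamp_s` (seconds from epoch 1
#'   start) and `bpm`.
#' @param max_missing Maximum tolerated missing fraction per stream.
#' @return Tibble `epoch_id`, `fitbit_stage`, `medical_stage`, `hr_mean`
#'   with no missing values.
#' @examples
#' truth <- simulate_hypnogram(40, seed = 1)
#' device <- corrupt_stages(truth, seed = 2)
#' hr <- simulate_heart_rate(truth, seed = 3)
#' align_epochs(device, truth, hr)
#' @export
align_epochs <- function(device, reference, heart_rate, max_missing = 0.5) {
  dev <- as_stage_tbl(device, "device")
  ref <- as_stage_tbl(reference, "reference")
  lo <- max(min(dev$epoch_id), min(ref$epoch_id))
  hi <- min(max(dev$epoch_id), max(ref$epoch_id))
  if (lo > hi) abort("Device and reference streams do not overlap.")
  ids <- lo:hi
  grid <- tibble(epoch_id = ids)
  dev <- left_join(grid, dev, by = "epoch_id")
  ref <- left_join(grid, ref, by = "epoch_id")

  reject_if <- function(frac, stream) {
    if (frac > max_missing) {
      abort(sprintf(
        "Stream \"%s\" has %.0f%% of epochs missing (> %.0f%% allowed); night rejected.",
        stream, 100 * frac, 100 * max_missing),
        class = "sleepcascade_rejection")
    }
  }
  reject_if(mean(is.na(dev$stage)), "device")
  reject_if(mean(is.na(ref$stage)), "reference")

  if (!is.data.frame(heart_rate) ||
      !all(c("timestamp_s", "bpm") %in% names(heart_rate))) {
    abort("`heart_rate` must have columns `timestamp_s` and `bpm`.")
  }
  hr <- heart_rate[!is.na(heart_rate$bpm), ]
  # half-open [start, end): epoch n covers seconds [30(n-1), 30n)
  hr_epoch <- floor(hr$timestamp_s / 30) + 1L
  in_span <- hr_epoch %in% ids
  means <- rep(NA_real_, length(ids))
  if (any(in_span)) {
    agg <- tapply(hr$bpm[in_span], hr_epoch[in_span], mean)
    means[match(as.integer(names(agg)), ids)] <- as.numeric(agg)
  }
  reject_if(mean(is.na(means)), "heart_rate")

  # stages: previous-observation-carried-forward (leading gaps backfilled)
  fill_stages <- function(s) {
    s <- zoo::na.locf(s, na.rm = FALSE)
    as.integer(zoo::na.locf(s, fromLast = TRUE, na.rm = FALSE))
  }
  hr_mean <- as.numeric(zoo::na.approx(means, na.rm = FALSE, rule = 2))

  tibble(
    epoch_id = ids,
    fitbit_stage = fill_stages(dev$stage),
    medical_stage = fill_stages(ref$stage),
    hr_mean = hr_mean
  )
}

#' Daily sleep metrics from a stage sequence
#'
#' Standard actigraphy summaries of one night scored in 30-s epochs:
#' total sleep time `TST = 0.5 min * #(stage != wake)`, wake after sleep
#' onset `WASO = 0.5 min * #(wake epochs after the first non-wake epoch)`,
#' sleep efficiency `SE = 100 * TST / time in bed`, and the fraction of
#' epochs spent in each stage.
#'
#' @param stages Integer vector of stage codes (1-4), non-empty.
#' @return One-row tibble: `tst_min`, `waso_min`, `se_percent`,
#'   `wake_ratio`, `light_ratio`, `deep_ratio`, `rem_ratio`.
#' @examples
#' compute_daily_metrics(c(4, 2, 2, 4))
#' @export
compute_daily_metrics <- function(stages) {
  stages <- assert_stages(stages, "stages", allow_empty = FALSE)
  n <- length(stages)
  tst <- 0.5 * sum(stages != 4L)
  onset <- which(stages != 4L)[1]
  waso <- if (is.na(onset)) 0 else 0.5 * sum(stages[-seq_len(onset)] == 4L)
  tibble(
    tst_min = tst,
    waso_min = waso,
    se_percent = 100 * tst / (0.5 * n),
    wake_ratio = mean(stages == 4L),
    light_ratio = mean(stages == 2L),
    deep_ratio = mean(stages == 1L),
    rem_ratio = mean(stages == 3L)
  )
}

#' Convert device/reference stages to two-level training labels
#'
#' Level-I labels mark device misclassification: 0 where the device and
#' the reference agree on an epoch, 1 where they disagree. Level-II
#' labels are the reference stages themselves, the targets of the
#' four-class re-classifier.
#'
#' @param device,reference Integer stage vectors of equal length.
#' @return Tibble `epoch_id`, `level1` (0/1), `level2` (1-4).
#' @examples
#' convert_labels(c(4, 4, 2, 2, 3, 3), c(4, 4, 4, 4, 2, 3))
#' @export
convert_labels <- function(device, reference) {
  device <- assert_stages(device, "device")
  reference <- assert_stages(reference, "reference")
  assert_same_length(device, reference, "device", "reference")
  tibble(
    epoch_id = seq_along(device),
    level1 = as.integer(device != reference),
    level2 = reference
  )
}
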