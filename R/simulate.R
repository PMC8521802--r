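# Synthetic cohort simulator: Markov-chain hypnograms, device-confusion
# label corruption, stage-dependent per-second heart rate, demographics.

#' Default sleep-stage transition matrix
#'
#' First-order Markov transition matrix over the four stages
#' (1 deep, 2 light, 3 REM, 4 wake) built so that its stationary
#' distribution sits at `target`, the normalized midpoints of the typical
#' adult stage-proportion ranges (light 40-60%, REM 15-25%, deep 15-20%,
#' wake 5-15%). At every epoch the chain stays put with probability
#' `1 - switch_prob` and otherwise redraws the stage from the stationary
#' distribution, giving mean bout lengths of a few minutes.
#'
#' @param target Stationary stage probabilities (length 4, order
#'   deep/light/rem/wake). Normalized to sum to 1.
#' @param switch_prob Per-epoch probability of redrawing the stage.
#' @return A 4x4 row-stochastic matrix with dimnames
#'   `deep/light/rem/wake`.
#' @examples
#' P <- sleep_transition_matrix()
#' stationary_distribution(P)
#' @export
sleep_transition_matrix <- function(target = c(deep = 0.175, light = 0.50,
                                               rem = 0.20, wake = 0.10),
                                    switch_prob = 0.1) {
  if (length(target) != 4 || any(target <= 0)) {
    abort("`target` must be 4 positive stage probabilities.")
  }
  if (switch_prob <= 0 || switch_prob > 1) {
    abort("`switch_prob` must be in (0, 1].")
  }
  pi <- unname(target) / sum(target)
  P <- (1 - switch_prob) * diag(4) + switch_prob * matrix(pi, 4, 4, byrow = TRUE)
  dimnames(P) <- list(STAGE_LABELS, STAGE_LABELS)
  P
}

#' Stationary distribution of a stage transition matrix
#'
#' Solves `pi P = pi` by eigen-decomposition of `t(P)`.
#'
#' @param transition 4x4 row-stochastic matrix.
#' @return Named numeric vector of length 4 summing to 1.
#' @export
stationary_distribution <- function(transition) {
  assert_stochastic(transition, "transition")
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  setNames(v, STAGE_LABELS)
}

#' Simulate a night's hypnogram
#'
#' Draws a first-order Markov chain of 30-second epoch stage codes
#' (1 deep, 2 light, 3 REM, 4 wake). The initial stage is drawn from
#' `init` (default: the stationary distribution of `transition`).
#'
#' @param n_epochs Number of 30-s epochs (>= 0).
#' @param transition 4x4 row-stochastic transition matrix.
#' @param seed Optional integer seed; fixed seed gives a reproducible night.
#' @param init Optional initial stage distribution (length 4).
#' @return Integer vector of stage codes of length `n_epochs`.
#' @examples
#' stages <- simulate_hypnogram(960, seed = 1)
#' table(stages) / length(stages)
#' @export
simulate_hypnogram <- function(n_epochs, transition = sleep_transition_matrix(),
                               seed = NULL, init = NULL) {
  if (length(n_epochs) != 1 || is.na(n_epochs) || n_epochs < 0) {
    abort("`n_epochs` must be a single non-negative count.")
  }
  n_epochs <- as.integer(n_epochs)
  assert_stochastic(transition, "transition")
  if (is.null(init)) init <- stationary_distribution(transition)
  if (length(init) != 4 || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    abort("`init` must be 4 probabilities summing to 1.")
  }
  if (n_epochs == 0) return(integer(0))
  with_seed(seed, {
    out <- integer(n_epochs)
    out[1] <- sample(STAGES, 1, prob = init)
    if (n_epochs > 1) {
      # vector of uniforms + cumulative rows keeps the loop cheap
      cum <- t(apply(transition, 1, cumsum))
      u <- runif(n_epochs - 1)
      for (t in 2:n_epochs) {
        out[t] <- findInterval(u[t - 1], cum[out[t - 1], ], left.open = TRUE) + 1L
      }
    }
    out
  })
}

#' Default device-error (confusion) matrix
#'
#' Conditional probabilities `P(device stage = j | true stage = i)` for a
#' wrist-worn consumer tracker, with rows indexed by the true stage and
#' columns by the device stage (order deep/light/rem/wake). Values follow
#' the published stage-wise accuracy profile of the Fitbit Charge 2
#' against a clinical EEG reference (e.g. a true light-sleep epoch is
#' labelled light by the device 69.3% of the time); rows are renormalized
#' to sum to exactly 1.
#'
#' @return 4x4 row-stochastic matrix.
#' @export
fitbit_error_matrix <- function() {
  m <- rbind(
    deep  = c(0.609, 0.291, 0.029, 0.027),
    light = c(0.216, 0.693, 0.059, 0.032),
    rem   = c(0.035, 0.317, 0.596, 0.053),
    wake  = c(0.065, 0.503, 0.081, 0.350)
  )
  colnames(m) <- STAGE_LABELS
  m / rowSums(m)
}

#' Corrupt a true hypnogram through a device-error matrix
#'
#' Each epoch's device label is drawn independently from the error-matrix
#' row of its true stage, emulating the epoch-wise confusion structure of
#' a consumer tracker.
#'
#' @param truth Integer vector of true stage codes (1-4).
#' @param error_matrix 4x4 row-stochastic matrix,
#'   `P(device = j | truth = i)`.
#' @param seed Optional integer seed.
#' @return Integer vector of device stage codes, same length as `truth`.
#' @examples
#' truth <- simulate_hypnogram(480, seed = 1)
#' device <- corrupt_stages(truth, seed = 2)
#' mean(device == truth)
#' @export
corrupt_stages <- function(truth, error_matrix = fitbit_error_matrix(),
                           seed = NULL) {
  truth <- assert_stages(truth, "truth")
  assert_stochastic(error_matrix, "error_matrix")
  if (length(truth) == 0) return(integer(0))
  with_seed(seed, {
    cum <- t(apply(error_matrix, 1, cumsum))
    u <- runif(length(truth))
    out <- integer(length(truth))
    for (s in STAGES) {
      idx <- truth == s
      out[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    out
  })
}

#' Default stage-dependent heart-rate model
#'
#' Mean beats-per-minute and within-stage noise SD for each sleep stage,
#' plus a between-subject baseline SD. Means follow the usual nocturnal
#' pattern: lowest in deep sleep, elevated and more variable in REM,
#' highest during wake.
#'
#' @param means Per-stage mean bpm (order deep/light/rem/wake).
#' @param sds Per-stage per-second noise SD (bpm).
#' @param baseline_sd Between-subject SD of a constant bpm offset applied
#'   to all four stage means (used by [simulate_cohort()]).
#' @return A list with elements `means`, `sds`, `baseline_sd`.
#' @export
sleep_hr_spec <- function(means = c(deep = 52, light = 58, rem = 65, wake = 72),
                          sds = c(deep = 2.5, light = 3, rem = 5, wake = 6),
                          baseline_sd = 5) {
  if (length(means) != 4 || length(sds) != 4) {
    abort("`means` and `sds` must each have 4 entries (deep/light/rem/wake).")
  }
  if (any(means <= 0) || any(sds < 0) || baseline_sd < 0) {
    abort("Heart-rate parameters must be positive (means) and non-negative (SDs).")
  }
  list(means = setNames(as.numeric(means), STAGE_LABELS),
       sds = setNames(as.numeric(sds), STAGE_LABELS),
       baseline_sd = as.numeric(baseline_sd))
}

#' Simulate per-second heart rate over a hypnogram
#'
#' Generates one bpm sample per second across the night (30 samples per
#' epoch), with stage-dependent mean and Gaussian noise, then removes an
#' i.i.d. fraction `missing_rate` of samples and, optionally, a number of
#' contiguous gaps, emulating the irregular sampling of wrist-worn optical
#' heart-rate sensors.
#'
#' @param truth Integer vector of stage codes; epoch `n` covers seconds
#'   `[30(n-1), 30n)`.
#' @param hr_spec Output of [sleep_hr_spec()].
#' @param missing_rate Fraction of samples dropped i.i.d., in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param n_gaps,gap_length Number and length (seconds) of additional
#'   contiguous dropout gaps.
#' @return Tibble with columns `timestamp_s`, `bpm` (missing samples are
#'   absent rows, not `NA`s).
#' @examples
#' hr <- simulate_heart_rate(simulate_hypnogram(20, seed = 1), seed = 2)
#' nrow(hr)
#' @export
simulate_heart_rate <- function(truth, hr_spec = sleep_hr_spec(),
                                missing_rate = 0.1, seed = NULL,
                                n_gaps = 0, gap_length = 0) {
  truth <- assert_stages(truth, "truth")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  if (any(hr_spec$means <= 0) || any(hr_spec$sds < 0)) {
    abort("Heart-rate means must be positive and SDs non-negative.")
  }
  n_sec <- 30L * length(truth)
  if (n_sec == 0) {
    return(tibble(timestamp_s = integer(0), bpm = numeric(0)))
  }
  with_seed(seed, {
    stage_sec <- rep(truth, each = 30L)
    bpm <- hr_spec$means[stage_sec] + rnorm(n_sec, 0, hr_spec$sds[stage_sec])
    bpm <- pmax(bpm, 25)  # floor: optical sensors never report near-zero bpm
    keep <- rep(TRUE, n_sec)
    if (missing_rate > 0) keep <- runif(n_sec) >= missing_rate
    if (n_gaps > 0 && gap_length > 0) {
      starts <- sample.int(max(n_sec - gap_length, 1), n_gaps, replace = TRUE)
      for (s in starts) keep[seq(s, min(s + gap_length - 1, n_sec))] <- FALSE
    }
    tibble(timestamp_s = (0:(n_sec - 1))[keep], bpm = unname(bpm[keep]))
  })
}

#' Simulator configuration
#'
#' Bundles and validates every parameter of the synthetic cohort
#' generator. Defaults reproduce the design of a small wearable-validation
#' study: 23 adults, one night each of 480-1,176 thirty-second epochs
#' (4.0-9.8 h), stage proportions inside the typical adult ranges, and a
#' consumer-device error profile.
#'
#' @param n_subjects Number of subjects.
#' @param epochs_range Min/max epochs per night (inclusive).
#' @param transition Stage transition matrix (see
#'   [sleep_transition_matrix()]).
#' @param target_proportions List of per-stage proportion intervals used
#'   for documentation and calibration checks.
#' @param error_matrix Device-confusion matrix (see
#'   [fitbit_error_matrix()]).
#' @param hr_spec Heart-rate model (see [sleep_hr_spec()]).
#' @param hr_missing_rate Fraction of heart-rate samples dropped, `[0,1)`.
#' @param demographics List with `age_range` (years), `female_ratio`
#'   (probability a subject is female), `psqi_mean` (Poisson mean of the
#'   PSQI score, truncated to 0-21).
#' @param master_seed Integer master seed; all subject-level seeds derive
#'   from it.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 3, epochs_range = c(100, 120))
#' @export
sim_config <- function(n_subjects = 23,
                       epochs_range = c(480, 1176),
                       transition = sleep_transition_matrix(),
                       target_proportions = list(
                         deep = c(0.15, 0.20), light = c(0.40, 0.60),
                         rem = c(0.15, 0.25), wake = c(0.05, 0.15)
                       ),
                       error_matrix = fitbit_error_matrix(),
                       hr_spec = sleep_hr_spec(),
                       hr_missing_rate = 0.1,
                       demographics = list(age_range = c(19, 35),
                                           female_ratio = 9 / 23,
                                           psqi_mean = 4.3),
                       master_seed = 1L) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (length(epochs_range) != 2 || epochs_range[1] < 1 ||
      epochs_range[2] < epochs_range[1]) {
    abort("`epochs_range` must be (min, max) with min >= 1.")
  }
  assert_stochastic(transition, "transition")
  assert_stochastic(error_matrix, "error_matrix")
  if (hr_missing_rate < 0 || hr_missing_rate >= 1) {
    abort("`hr_missing_rate` must be in [0, 1).")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    epochs_range = as.integer(epochs_range),
    transition = transition,
    target_proportions = target_proportions,
    error_matrix = error_matrix,
    hr_spec = hr_spec,
    hr_missing_rate = hr_missing_rate,
    demographics = demographics,
    master_seed = as.integer(master_seed)
  ), class = "sim_config")
}

#' Simulate a synthetic cohort
#'
#' Generates `n_subjects` single-night records: a true hypnogram, a
#' device-corrupted stage sequence, per-second heart rate with dropout,
#' and demographics (age, sex, PSQI). Streams are aligned into a
#' per-epoch record with [align_epochs()]. Every subject's seeds derive
#' deterministically from `master_seed`, so the same configuration always
#' reproduces the identical cohort.
#'
#' @param config A [sim_config()].
#' @param keep_heart_rate Keep the raw per-second series as a list column?
#' @return Tibble with one row per subject: `subject_id`, `age`, `sex`
#'   (0 male, 1 female), `psqi`, `n_epochs`, and list columns `record`
#'   (per-epoch tibble: `epoch_id`, `fitbit_stage`, `medical_stage`,
#'   `hr_mean`) and, optionally, `heart_rate`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 2,
#'                                      epochs_range = c(60, 80)))
#' cohort$n_epochs
#' @export
simulate_cohort <- function(config = sim_config(), keep_heart_rate = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  ms <- config$master_seed
  dem <- config$demographics
  rows <- purrr::map(seq_len(config$n_subjects), function(i) {
    n_ep <- with_seed(derive_seed(ms, i, 0L), {
      sample(seq(config$epochs_range[1], config$epochs_range[2]), 1)
    })
    truth <- simulate_hypnogram(n_ep, config$transition,
                                seed = derive_seed(ms, i, 1L))
    device <- corrupt_stages(truth, config$error_matrix,
                             seed = derive_seed(ms, i, 2L))
    hr_spec_i <- config$hr_spec
    demo <- with_seed(derive_seed(ms, i, 3L), {
      offset <- rnorm(1, 0, config$hr_spec$baseline_sd)
      list(
        age = round(runif(1, dem$age_range[1], dem$age_range[2])),
        sex = rbinom(1, 1, dem$female_ratio),
        psqi = min(rpois(1, dem$psqi_mean), 21),
        offset = offset
      )
    })
    hr_spec_i$means <- hr_spec_i$means + demo$offset
    hr <- simulate_heart_rate(truth, hr_spec_i, config$hr_missing_rate,
                              seed = derive_seed(ms, i, 4L))
    record <- align_epochs(device, truth, hr)
    tibble(
      subject_id = sprintf("S%02d", i),
      age = demo$age, sex = demo$sex, psqi = demo$psqi,
      n_epochs = n_ep,
      record = list(record),
      heart_rate = list(hr)
    )
  })
  cohort <- bind_rows(rows)
  if (!keep_heart_rate) cohort$heart_rate <- NULL
  cohort
}
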