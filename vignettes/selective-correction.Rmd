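---
title: "Selective correction of wearable sleep staging: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective correction of wearable sleep staging: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcascade)
```

## The problem

Consumer wrist-worn trackers label every 30-second epoch of a night with
one of four sleep stages — deep (N3), light (N1+N2), REM, wakefulness —
coded here as 1–4. Against clinical references they are right often
enough to be useful and wrong often enough to distort stage totals.
Re-classifying *every* epoch from scratch throws away the device's
correct calls; `sleepcascade` instead implements *selective correction*:

1. a **level-I** binary classifier decides, epoch by epoch, whether the
   device's label is wrong (1) or right (0);
2. a **level-II** four-class classifier re-labels only the epochs that
   level I flagged.

Formally the corrected label is `y = f_II(f_I(x))` where an epoch with
`f_I(x) = 0` keeps its device stage. Both levels consume the same
21-feature vector per epoch: ten static features (age, sex, PSQI score,
and the device-derived daily metrics TST, WASO, SE and the four stage
ratios) and eleven dynamic ones (epoch index, the device stage at
offsets −3…+3, the epoch mean heart rate, and its first differences
against the neighbouring epochs).

Level I can be a Gaussian naive Bayes, a random forest, or a
linear-kernel SVM (with z-score standardization fitted on the training
partition; the other learners see raw features). Level II is an XGBoost
multiclass model. Because light sleep dominates a normal night, the
level-II training set can be rebalanced by random down sampling (all
classes cut to the minimum count) or random up sampling (all classes
duplicated up to the maximum count). Resampling is applied to training
partitions only — inside inner cross-validation folds as well — and
resampled rows are always exact copies of original rows.

## Evaluation protocol

Sleep data are chronological and subject-specific, so models are
evaluated by nested leave-one-subject-out cross-validation
(`run_nested_loso()`): each subject is held out once, hyperparameters
are tuned on the remaining subjects by stratified k-fold grid search
(level I scored by accuracy, level II by Cohen's kappa — kappa guards
the imbalanced four-class objective; both are configurable), the model
is refit on the full training set, and the untouched held-out subject is
scored. Thirteen models are available (`model_catalog()`): the device
pass-through, three one-level XGBoost baselines (no/down/up
resampling), and the nine cascade combinations.

Epoch-wise ("microscopic") measures: per-epoch accuracy, Cohen's kappa,
the multiclass Matthews correlation coefficient (MMCC), a
column-normalized confusion matrix (columns are ground-truth stages),
and two cascade-specific rates — correcting power (CP: the fraction of
device-wrong epochs fixed) and over-correcting rate (OR: the fraction of
device-right epochs broken). Duration-level ("macroscopic") measures:
per-stage minutes, Bland–Altman analysis with bias, 1.96-SD limits of
agreement, a one-sample t-test of the bias and a trend test, and the
mean normalized absolute bias (MAB) — each model's absolute stage bias
min–max normalized across the competing models and averaged over the
four stages. Dataset characteristics: the Shannon diversity of each test
night's stage distribution (imbalance) and the two-sample
Anderson–Darling statistic between training and test stage distributions
(shift), correlated against the performance measures with Pearson's r.

Two conventions worth spelling out. The confusion matrix is normalized
by ground-truth column (so each column sums to 100%), matching the usual
stage-wise accuracy layout. Bland–Altman differences are
`reference − model`, so a positive bias means underestimation by the
model.

## The synthetic cohort generator

No human data ship with the package; `simulate_cohort()` generates
cohorts with the statistical structure the pipeline assumes, so every
stage of the pipeline is testable end to end.

* **Hypnograms** are first-order Markov chains over the four stages. The
  default transition matrix (`sleep_transition_matrix()`) is pre-solved
  so its stationary distribution sits at the normalized midpoints of the
  typical adult stage-proportion ranges (light 40–60%, REM 15–25%, deep
  15–20%, wake 5–15%), i.e. roughly light 0.513, REM 0.205, deep 0.179,
  wake 0.103. The per-epoch switch probability defaults to 0.1, giving
  mean bout lengths of a few minutes. This is deliberately the simplest
  process honouring those proportions: it has no ultradian cycles, no
  REM latency, no wake-consolidation structure.
* **Device labels** are drawn per epoch from a 4×4 confusion matrix
  conditional on the true stage. The default
  (`fitbit_error_matrix()`) follows the published stage-wise confusion
  profile of a Fitbit Charge 2 against a clinical EEG reference (e.g.
  a true light-sleep epoch keeps its label with probability 0.693), with
  rows renormalized to sum to one. Errors are conditionally independent
  across epochs, which is harsher than reality, where device errors
  cluster at stage transitions.
* **Heart rate** is sampled once per second at a stage-dependent mean
  with Gaussian noise (defaults: deep 52, light 58, REM 65, wake 72 bpm;
  SDs 2.5/3/5/6), typical resting nocturnal values. A between-subject
  baseline offset (SD 5 bpm by default) shifts all four means per
  subject. An i.i.d. fraction of samples (default 10%) is dropped,
  optionally plus contiguous gaps, mimicking irregular optical-sensor
  sampling.
* **Demographics**: age uniform on 19–35 years, sex Bernoulli(9/23),
  PSQI Poisson with mean 4.3 truncated at 21 — matching a small healthy
  young-adult cohort. Defaults: 23 subjects, one night each of 480–1,176
  epochs (4.0–9.8 h).

Everything derives deterministically from a single master seed, so the
same configuration reproduces a byte-identical cohort (and CSV export).

What passing tests on these cohorts do **not** show: robustness to
temporally correlated device errors, to circadian heart-rate drift or
arousal artefacts, to device clock misalignment, or to real
between-night variability — none of which the generator emulates.

## Numerical and design choices

* **Stage-window padding.** Offsets falling before the first or after
  the last epoch replicate the nearest existing epoch's stage, and the
  heart-rate differences are 0 at the boundaries. This keeps one feature
  row per epoch so evaluation covers the whole night.
* **Epoch membership** of heart-rate samples uses the half-open window
  `[epoch start, epoch end)`, so no sample is counted twice.
* **Missing data.** Epochs without any heart-rate sample get the linear
  interpolation of neighbouring epoch means (edges extended); missing
  stage epochs are carried forward from the previous observation
  (stages are categorical; linear interpolation is undefined). A stream
  missing more than 50% of its epochs rejects the whole night.
* **Daily metrics** are computed from the device stages with standard
  actigraphy definitions (TST = 0.5 min × non-wake epochs; WASO counts
  wake epochs after the first non-wake epoch; SE = TST / time in bed),
  since on synthetic data there is no vendor API to supply them.
* **Degenerate metrics.** CP (OR) is undefined when the device made no
  errors (no correct calls); `NA` is returned with a classed warning
  rather than a silent 0. MMCC of a single-class table is defined as 0
  with a warning. A stage where all models tie in absolute bias
  contributes 0 to the MAB. Kappa returns 1 when both raters agree on a
  single class.
* **Anderson–Darling variant.** No installed package provides the
  two-sample statistic, so it is implemented directly: the
  Scholz–Stephens k-sample form with midrank tie correction (k = 2),
  which is the appropriate variant for heavily tied ordinal stage codes;
  a standardized form is available via `standardized = TRUE`.
* **Level-I decision rule** is the argmax class (threshold 0.5 for
  probabilistic outputs). Naive Bayes has no training-time variance
  smoothing in the backing implementation, so its tunable smoothing is
  the `eps` floor applied at prediction.
* **Grid search.** Default grids: SVM cost {0.01, 0.1, 1, 10}; NB eps
  {1e-9, 1e-6}; RF {100, 500} trees × {√21, 7} features per split;
  XGBoost depth {3, 6, 9} × learning rate {0.05, 0.1, 0.3} × rounds
  {50, 100, 200}. Ties break by first-in-grid order; up sampling targets
  exact balance for determinism. Inner folds are stratified on the label
  being fitted so small minority classes appear in every fold.
* **Paired comparisons.** `summarize_models()` compares each model to
  the device baseline with a *paired* two-tailed t-test across subjects,
  matching the within-subject design.

## Problem sizes used in the shipped checks

The test suite and examples favour small, fast configurations chosen as
the package's own desk-scale defaults: harness shape checks use 23
subjects × 150–250 epochs with the reduced two-point XGBoost grid and
3 inner folds; the recovery experiment uses ten cohorts of 8 subjects ×
240–360 epochs with a fully informative heart-rate signal
(`baseline_sd = 0`, the condition under which correction is learnable
from heart rate alone), fixed mid-grid hyperparameters and the SVM
cascades; calibration checks use 100,000 corrupted epochs per stage and
200 simulated nights. Full-scale runs (23 × 480–1,176 epochs, full
grids, all 13 models) use the same code paths — only `sim_config()` and
grid arguments change.

## A worked run

```{r example, eval = FALSE}
cohort <- simulate_cohort(sim_config(n_subjects = 8,
                                     epochs_range = c(240, 360),
                                     hr_spec = sleep_hr_spec(baseline_sd = 0),
                                     master_seed = 1))
report <- run_nested_loso(cohort,
                          models = c("Fitbit", "SVM+XGBu", "SVM+XGBd"),
                          master_seed = 1,
                          level1_grids = default_level1_grids(reduced = TRUE),
                          level2_grid = list(list(max_depth = 6, eta = 0.1,
                                                  nrounds = 100)),
                          inner_folds = 3)
glance(report)
summarize_models(report)
autoplot(report)
```

## Known limitations

* The simulator's independence assumptions (epoch-wise device errors,
  i.i.d. heart-rate noise) make the correction task cleaner than on real
  recordings; accuracies obtained on synthetic cohorts characterize the
  pipeline, not any device.
* With the default between-subject heart-rate baseline (SD 5 bpm),
  absolute heart rate is a weaker cue and small cohorts may not beat the
  device pass-through; the level-II learner then leans on the
  offset-invariant heart-rate differences and the stage context.
* Level-I probabilities are not calibrated; no per-level feature
  selection is performed; neural-network level-II learners are out of
  scope.
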