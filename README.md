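# sleepcascade

Consumer wrist-worn trackers stage sleep in 30-second epochs — deep,
light, REM, wake — but misstage enough epochs to distort stage totals
and downstream sleep metrics. `sleepcascade` implements **selective
correction** of those labels with a two-level cascade, together with the
full evaluation protocol needed to judge whether the correction helps,
and a synthetic cohort simulator so the entire pipeline runs and is
tested without any human data.

The core model: for each epoch with feature vector **x**, a level-I
binary classifier f_I decides whether the device's stage label is wrong;
a level-II four-class classifier f_II re-labels only flagged epochs:

    y = device stage        if f_I(x) = 0
    y = f_II(x)             if f_I(x) = 1

Both levels share one 21-feature representation per epoch: age, sex,
PSQI, the device-derived daily metrics (TST, WASO, SE, four stage
ratios), the epoch index, the device stage at offsets −3…+3, the epoch
mean heart rate and its differences against the neighbouring epochs.
Level I is naive Bayes, random forest, or linear SVM; level II is
XGBoost, optionally trained on randomly up- or down-sampled (balanced)
training data. Resampling only ever touches training partitions.

Evaluation is by nested leave-one-subject-out cross-validation with
inner stratified grid search, reporting per-epoch accuracy, Cohen's
kappa, the multiclass Matthews correlation coefficient (MMCC),
correcting power, over-correcting rate, stage durations, Bland–Altman
bias with 1.96-SD limits of agreement, the mean normalized absolute bias
(MAB) across models, Shannon diversity of each test night, the
two-sample Anderson–Darling train/test shift statistic, and the Pearson
correlations between performance and those dataset characteristics.

Intended users: sleep and wearable-validation researchers who want to
post-correct consumer-device hypnograms, or to benchmark correction
strategies under controlled, known error structure.

## Worked example

Simulate a small cohort with a known device-error structure and a fully
informative stage-dependent heart-rate signal, then evaluate the device
pass-through against two SVM + XGBoost cascades:

```r
library(sleepcascade)

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
report
#> Nested LOSO-CV report: 8 subjects, 3 models (seed 1)
#>
#>     model accuracy_mean accuracy_sd kappa_mean mmcc_mean mab
#>    Fitbit         0.614      0.0354      0.393     0.399 0.5
#>  SVM+XGBd         0.695      0.0426      0.530     0.536 0.5
#>  SVM+XGBu         0.695      0.0426      0.530     0.536 0.5

summarize_models(report)
#>      model   metric  mean     sd delta_pct t_stat p_value
#> 1 SVM+XGBd accuracy 0.695 0.0426      13.3   4.19 0.00408
#> 2 SVM+XGBu accuracy 0.695 0.0426      13.3   4.19 0.00408
#> 3   Fitbit accuracy 0.614 0.0354       0.0   0.00      NA
#> ...
```

Reading the output: the simulated device labels 61.4% of held-out epochs
correctly; selective correction lifts that to 69.5% (a 13.3% relative
gain, paired t-test across the 8 held-out subjects p ≈ 0.004), with
kappa rising from 0.39 to 0.53. On this cohort the heart-rate signal is
strong enough that the up- and down-sampled level-II variants converge
to the same corrections. `autoplot(report)` draws per-subject boxplots;
`report$bland_altman` holds the duration-level agreement per stage, e.g.
for deep sleep the device underestimates by 3.1 min on average while the
cascades cut that bias to 0.25 min.

Cohorts, configurations and reports round-trip to plain CSV/YAML via
`write_cohort()` / `read_cohort()` / `write_sim_config()`, and single
statistics are available directly: `cohens_kappa()`, `mmcc()`,
`correcting_power()`, `bland_altman()`, `mab()`, `shannon_diversity()`,
`ad_shift()`.

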