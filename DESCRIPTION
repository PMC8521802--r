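Package: sleepcascade
Title: Selective Correction of Consumer-Wearable Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for improving epoch-by-epoch sleep staging from consumer
    wearables by selective correction: a level-I classifier flags device
    epochs that are likely misclassified and a level-II four-stage
    classifier relabels only the flagged epochs. Includes a synthetic
    cohort simulator (Markov-chain hypnograms, device-confusion label
    corruption, stage-dependent heart rate), feature construction from
    device stages, heart rate and daily sleep metrics, class-imbalance
    resampling applied inside cross-validation, a nested
    leave-one-subject-out evaluation harness, and agreement statistics
    (Cohen's kappa, multiclass Matthews correlation, correcting power,
    over-correcting rate, Bland-Altman limits of agreement, mean
    normalized absolute bias, Shannon diversity and the two-sample
    Anderson-Darling shift statistic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml,
    zoo
Suggests:
    caret,
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
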