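Package: gaitmci
Title: Gait-Based Screening for Mild Cognitive Impairment from Skeletal
    Walking Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for screening mild cognitive impairment
    (MCI) from depth-camera skeletal walking recordings. Provides zero-phase
    Butterworth preprocessing of 25-joint trajectories, gait event and
    stance/swing phase detection from inter-foot distance signals, extraction
    of a 50-feature spatiotemporal gait roster (macro, temporal, spatial and
    spatiotemporal features with mean/variability/median aggregates and
    symmetry/regularity indices), ANCOVA confounder adjustment with
    normality-routed group tests and correlation-pruned feature selection,
    and logistic-regression/SVM/random-forest classification under nested
    stratified 5-fold cross-validation. A deterministic synthetic walking
    simulator with known ground truth makes the whole pipeline testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
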