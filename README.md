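# gaitmci

Gait-based screening for mild cognitive impairment (MCI) from depth-camera
skeletal walking recordings.

Older adults with MCI walk differently from cognitively healthy peers —
slower, with shorter and more variable steps, longer double support, and
less left/right regularity — and the differences grow when the walking task
adds a turning demand (an oval course instead of a straight 10-m walk).
`gaitmci` implements a complete screening pipeline over 25-joint skeletal
recordings of the kind produced by a Kinect-v2-class depth camera, for
researchers in digital gait biomarkers who want an end-to-end, reproducible
reference implementation that can be exercised without access to clinical
recordings.

## The pipeline

1. **Preprocessing** — each of the 75 coordinate channels is filtered with
   a zero-phase order-6 Butterworth low-pass at 3 Hz (effective magnitude
   `|H(f)|² = 1 / (1 + (f/3)^12)`).
2. **Gait events** — the inter-foot horizontal distance signal `d(t)` is
   computed per frame; its peaks mark steps (the peak's along-heading
   component is the step length, the perpendicular component the step
   width). Stance/swing phases per foot come from thresholding the foot's
   horizontal speed; both feet in stance is double support.
3. **Features** — a frozen 50-feature roster per trial: 2 macro features
   (velocity, cadence) and 48 micro features (per-step and per-cycle
   quantities aggregated as mean / variability / median, plus right-left
   symmetry and regularity indices). Variability is the coefficient of
   variation `var(x) = 100·sd(x)/mean(x)`; symmetry is
   `SI(x) = 1 − |x_R − x_L| / max(x_R, x_L) ∈ [0, 1]`.
4. **Cohort statistics** — ANCOVA adjustment for confounders (BMI,
   education, depression score), Shapiro-Wilk-routed Welch-t /
   Mann-Whitney group tests (p < 0.05), and redundancy pruning: among
   significant features correlated above |r| > 0.90, only the lowest-p
   representative is kept.
5. **Classification** — logistic regression, SVM and random forest under
   stratified 5-fold cross-validation with an inner 80/20 grid-search
   split; feature selection and confounder adjustment are re-fit inside
   each training fold so nothing leaks into the held-out fold. Metrics
   (accuracy, sensitivity, precision, specificity, F-score) are pooled
   over out-of-fold predictions with MCI as the positive class.
6. **Synthetic cohorts** — a deterministic event-driven walking simulator
   emits 25-joint recordings (straight or oval course) with known ground
   truth, and a cohort generator draws two groups whose demographics,
   confounders and gait parameters reproduce the group-level structure of
   a published MCI gait study (30 HC vs 25 MCI), so every stage of the
   pipeline is testable end to end.

## Worked example

```r
library(gaitmci)
library(dplyr)

# one synthetic straight 10-m walk, filtered and featurised
sim <- generate_recording(walker_params(cadence = 100, step_length_mean = 0.40),
                          seed = 42)
rec <- lowpass_filter(sim$recording)
rec
#> <skeletal_recording> subject sim (unknown, straight path)
#>   489 frames @ 30.0 Hz (16.3 s), low-pass filtered

extract_features(rec) |>
  filter(feature %in% c("velocity", "cadence", "step_time_var",
                        "step_time_sym_me", "step_length_me", "stride_length_me")) |>
  select(feature, value, unit, category)
#> # A tibble: 6 × 4
#>   feature           value unit      category
#> 1 velocity         61.5   cm/s      macro
#> 2 cadence          98.0   steps/min macro
#> 3 step_time_var     4.30  %         micro_temporal
#> 4 step_time_sym_me  0.953 index     micro_temporal
#> 5 step_length_me   41.1   cm        micro_spatial
#> 6 stride_length_me 82.4   cm        micro_spatial
```

The walker was configured for 100 steps/min with 0.40-m steps; the
pipeline recovers cadence 98, step length 41.1 cm and a near-perfect
step-time symmetry index from the rendered recording alone.

A small simulated cohort, through statistics and classification:

```r
tab <- simulate_cohort_features(cohort_config(n_hc = 12, n_mci = 12), seed = 7)
adj <- ancova_adjust(tab)                       # remove BMI/education/GDS effects
sel <- select_features(compare_groups(adj), adj)
sel
#> <gait_selection> 24 significant, 13 selected after |r| pruning
#>   double_support_time_me, step_time_sym_med, stride_time_reg_var, ...

report <- run_cv_experiment(adj, classifier_spec("random_forest", seed = 7))
report
#> <gait_eval_report> random_forest (seed 7, n = 24, positive = MCI)
#>   accuracy 83.3% | sensitivity 75.0% | precision 90.0% | specificity 91.7% | F 81.8%
glance(report)   # one-row tibble with confusion counts and metrics
```

`autoplot()` methods exist for recordings, importance rankings and
evaluation reports; `plot_distance_signal()` overlays detected step events
on the inter-foot distance signal. A thin command-line wrapper with
`simulate | events | extract | stats | classify | run` subcommands ships
in `inst/cli/gaitmci`, and `run_pipeline()` executes the whole chain from
a YAML config, persisting features, statistics, selections, reports and
logs.

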