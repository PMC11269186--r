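---
title: "Methods: gait feature extraction and MCI screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait feature extraction and MCI screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitmci)
```

This vignette documents the models, parameter choices and numerical
conventions behind `gaitmci`, and what the synthetic-data tests do and do
not establish about behaviour on real recordings.

## Data model and coordinate conventions

A `skeletal_recording` is a walking trial: timestamps plus 3-D positions
of the 25 Kinect-v2 joints in metres, in a world frame with x lateral,
y vertical (up) and z along the direction of progression. Camera-frame
inputs are expected to be registered into this frame upstream; the two
camera placements used in typical acquisition (frontal for straight
walks, lateral for oval walks) are an acquisition detail the pipeline
never sees. The sampling rate is carried per recording and defaults to
30 Hz — the native Kinect v2 rate — when a CSV file does not imply one;
it is a configuration default, not a measured fact about any particular
study. Non-uniform timestamps are linearly resampled onto a uniform grid
before filtering, with a warning once gaps exceed two nominal frames,
because frame drops beyond that suggest lost tracking rather than jitter.

## Preprocessing

Every coordinate channel is filtered with an order-6 Butterworth low-pass
at 3 Hz. The filter runs forward and backward (zero phase), so event
times read off the filtered signals are not biased by group delay; the
price is that the effective attenuation is the squared magnitude,
$|H(f)|^2 = 1/(1 + (f/f_c)^{2n})$ with $f_c = 3$ Hz, $n = 6$. Edge
transients are controlled two ways: odd-reflection padding of three
filter lengths at each end, and seeding each pass with a steady-state
filter history at the first padded sample. The second step matters — with
zero initial conditions alone, a constant signal at 0.5 m would still be
~1% off near the edges after padding; with the steady-state seed the DC
error is at machine precision, which the test suite asserts at 1e-6.

Causal filtering was a design option; zero-phase was chosen because the
whole downstream analysis is offline and unbiased event timing is worth
more than causality.

## Gait events

The inter-foot distance signal is the per-frame Euclidean separation of
`FootLeft`/`FootRight` in the horizontal (x, z) plane. The horizontal
restriction keeps vertical swing clearance out of the signal; full 3-D
distance is available as an option. Ankles may be substituted for feet on
real data, where foot tracking is noisiest.

Peaks of this signal are step events. Peak detection uses a prominence
floor of 0.05 m and a minimum spacing of 0.3 s; the spacing caps the
detectable cadence at ~200 steps/min, far above older-adult gait, and the
prominence floor sits well above post-filter sensor jitter but below any
plausible step. Partial steps before the first valley and after the last
valley are trimmed. At each peak the inter-foot vector is decomposed
along the local heading: the along-heading component is the step length,
the perpendicular component the step width. The decomposition (rather
than taking the raw peak distance as the length) keeps the two features
geometrically orthogonal — with a 0.40-m step and 0.15-m width the raw
distance would overestimate step length by 7%. The raw value is retained
per event as `peak_distance`. The local heading comes from the SpineBase
horizontal velocity smoothed over 0.5 s, which tracks the continuously
rotating heading on oval courses; heading-dependent outputs are therefore
invariant to rigid translations and yaw rotations of the whole recording,
which the suite asserts to 1e-6.

The leading foot at a peak is the foot further along the heading; exact
ties fall back to alternation from the previous event.

### Stance/swing labelling

A foot is in stance while its horizontal speed (central differences on
the filtered trajectory) stays below a threshold, swing otherwise; label
runs shorter than 0.1 s are merged into their neighbours, and frames
where both feet appear to swing — impossible in walking — are reassigned
to stance of the slower foot. The threshold is the one genuinely
sensitive parameter. A fixed low threshold (say 0.1 m/s) interacts badly
with the 3 Hz filter: the filter smears the stance-to-swing transition
symmetrically, so a threshold far below the mid-swing speed is crossed
well before true swing onset and well after true swing end, widening
swing in proportion to gait speed. Measured against simulator ground
truth at 100 steps/min, a fixed 0.1 m/s threshold mislabels ~10% of
frames and biases the stance fraction from 0.60 to 0.53. The default is
therefore speed-relative: 15% of the foot's 95th-percentile speed,
floored at 0.1 m/s (the post-filter jitter budget). Where the filtered
speed is locally linear — which it is near a threshold placed at ~15% of
peak — symmetric smearing does not move the crossing, and measured frame
agreement with ground truth exceeds 95% across cadences 50–100 with
stance-fraction error under 0.03. A fixed absolute threshold remains
available through `speed_threshold`.

### Cycles

A gait cycle spans two successive steps: from one step event to the next
event of the same foot. Stride time is the interval between the two
same-foot events; stride length the sum of the two constituent step
lengths; stance time the in-cycle time the cycle's foot is labelled
stance, swing its complement (so stance + swing = stride by construction,
asserted to one frame). Double- and single-support times are *mean bout
durations* within the cycle window — a stride contains two double-support
bouts, and per-bout duration is the convention that matches how these
quantities are reported clinically. Cycles whose events violate
left/right alternation are skipped with a warning rather than repaired.

## The 50-feature roster

The roster is frozen: 2 macro features (velocity, cadence), 24 micro
temporal, 18 micro spatial, 6 micro spatiotemporal; identical for
straight and oval trials. Aggregates are mean (`_me`), variability
(`_var`) and median (`_med`, midpoint convention for even counts).
Variability is the coefficient of variation in percent with the sample
(n−1) SD — trials contribute a few dozen steps at most, so the small-n
correction is not cosmetic. Symmetry pairs each step with the adjacent
opposite-foot step and applies
$SI = 1 - |x_R - x_L| / \max(x_R, x_L)$; regularity applies the same
index to each right-foot stride against its nearest-in-time left-foot
stride. Both are undefined (explicit missing value) when both arguments
are zero, as is any variability whose mean is within 1e-12 of zero.
Missing sub-features propagate as explicit missing values with reasons —
never imputed at trial level; imputation is the classifier's training-fold
job.

Units in reports follow the clinical presentation convention: velocities
cm/s, step/stride lengths cm, widths and heights m, times s,
variabilities %, indices unitless. Internal computation is SI throughout.

Two definitions are under-determined by the field and fixed here
explicitly:

* **Step height** is the swing foot's peak vertical position minus its
  baseline, the mean height over the contiguous stance run immediately
  preceding swing onset. Differencing against the foot's own baseline
  removes any static sensor height offset.
* **Macro velocity** on a straight path is the start-to-end displacement
  of the foot joint that completed the course, divided by trial duration;
  on an oval path start and end nearly coincide, so the horizontal arc
  length of the SpineBase trajectory replaces the displacement. Cadence
  is computed from the detected interior events,
  $60 (n-1) / (t_n - t_1)$, which is insensitive to standing time at the
  ends of a trial.

## Cohort statistics

ANCOVA adjustment fits each feature on the confounders (BMI, years of
education, depression score) *plus the group factor*, then subtracts only
the fitted covariate contribution, re-centred on the grand mean. The
group term matters: these confounders differ between groups, so a
covariates-only fit would absorb part of the genuine group effect into
the covariate coefficients and silently remove it — on simulated cohorts
where gait and confounders are linked only through group, covariates-only
adjustment costs classifiers 20+ accuracy points. Subtracting only
covariate terms means no group information enters the adjusted values,
and the operation is idempotent. Inside cross-validation the model is fit
on the training fold and applied to both portions.

Group comparisons are routed per feature: Shapiro-Wilk within each group,
Welch t-test if both pass at 0.05, Mann-Whitney U otherwise. Welch is
used rather than Student's because group variances are visibly unequal in
this domain. No multiple-testing correction is applied — a deliberate
mirror of common practice in this literature, and a caveat to keep in
mind: at 50 features, two or three false positives are expected per
cohort.

Selection is two-phase and deterministic: keep p < 0.05; then walk the
survivors in ascending p (ties broken by roster order) and drop any
candidate whose |Pearson r| with an already-accepted feature exceeds
0.90. Greedy-by-p reproduces "keep the lowest-p member of any correlated
set" for every cluster shape without needing to define clusters.

Gender is compared with the Pearson chi-square on the 2×2 table without
continuity correction — the classic formula — with a warning attached
when any expected cell count is below 1.

## Classification protocol

Stratified 5-fold outer cross-validation (stratification is forced by the
25/30 class imbalance); within each fold: training-fold median
imputation, in-fold ANCOVA adjustment, in-fold statistical selection for
LR and SVM (the random forest always sees all 50 features), z-scoring by
training statistics for LR/SVM (RF unstandardised), a single stratified
80/20 inner split, grid search scored on the inner validation set, refit
of the winner on the whole training fold, prediction of the held-out
fold. Metrics are pooled over out-of-fold predictions with MCI positive;
per-fold metrics are retained alongside.

Default grids: LR ridge penalty λ ∈ {0.01, 0.1, 1, 10}; SVM linear/RBF,
C ∈ {0.1, 1, 10, 100}, γ ∈ {scale, 0.01, 0.1}; RF trees {500, 300, 100},
depth {unlimited, 5, 3}, min node size {1, 2, 4}, mtry {√p, p/2}. With
only ~11 inner-validation subjects, ties across grid rows are routine, so
tie-breaking policy is part of the protocol: the earlier grid row wins,
and the default grids order rows by a priori preference (more trees,
unconstrained depth first). Every stochastic element — folds, inner
splits, forest growth, and forest *prediction* (majority-vote ties are
broken randomly by the RF backend) — is seeded from the single spec seed,
making reports bit-reproducible.

RF feature importance uses impurity decrease, normalised to sum to one
per fitted forest, averaged over the five per-fold forests, and
thresholded at 0.03 for the retained set.

## The synthetic walker and cohort generator

The simulator is event-driven: a step schedule (contact time, foot,
placement along the path) is drawn first, then rendered. Step durations
and lengths are Gaussian per step around the subject's means (right-side
values scaled by an asymmetry ratio), placements alternate sides of the
path centreline at half the step width, each foot is *exactly* stationary
during stance and swings along a smoothstep horizontal profile with
sinusoidal vertical clearance, and double support arises from overlapping
stance intervals at fraction $2f - 1$ of the stride for stance fraction
$f$. The pelvis follows the path midline; the remaining 22 joints are
rigid offsets with small oscillations and exist for visual plausibility
only — no analysis consumes them. Gaussian positional noise (default
3 mm) is added to every coordinate before filtering. The oval course
defaults to two 3-m straights joined by 1-m-radius semicircles (the
emulated study's exact oval geometry is not public; this is a declared
assumption). All randomness flows from one seed through a counter-derived
scheme, so any subject regenerates identically regardless of order.

Cohort defaults reproduce the group-level structure of the emulated
study's published tables: demographics and confounders per group (e.g.
BMI 24.51 ± 2.67 HC vs 26.67 ± 2.62 MCI; GDS 1.43 ± 1.33 vs 3.52 ± 1.29),
and oval-walking gait parameters (cadence 62.02 ± 9.73 vs 55.00 ± 11.67
steps/min; step length 37.58 ± 4.97 vs 32.91 ± 3.46 cm; step width
0.21 ± 0.04 vs 0.17 ± 0.03 m). Within-subject SDs were set so the
*realized* per-trial variability features land near the published
variability rows (realized step-time variability ~34% HC vs ~40% MCI
against published 34/41); stance-time and double-support variability
remain below their published values because the stance fraction is
constant within a simulated trial — real stance-phase variability has
within-trial structure this walker does not model. Confounder–group
associations arise from the per-group demographic draws; the generator
deliberately does not add within-group confounder→gait effects.

### What passing tests do and do not show

The simulator provides exact ground truth (step schedules, per-frame
phases), so the suite can measure recovery error directly: cadence within
3%, step length within 5%, stance fraction within 0.05, every event
within 2 frames on the noiseless reference walk, and ≥90% frame-level
phase agreement at 5 mm noise. These are checks of internal consistency
and of the detectors' behaviour under controlled violations — they do not
certify accuracy on real depth-camera data, which adds occlusion,
tracking dropouts, depth-dependent noise and soft-tissue artefacts the
generator intentionally omits. Likewise the classification contract
(median RF pooled accuracy ≥ 75% over ten calibrated cohorts; chance-level
accuracy under permuted labels) exercises the protocol, not the clinical
claim. One published ordering does not reproduce under these conditions:
with group effects injected as location shifts of near-Gaussian
parameters, penalised logistic regression on in-fold-selected features
slightly exceeds the random forest (median 80.0% vs 77.3% over the ten
test cohorts), whereas the emulated study reported RF clearly ahead on
real data; recovering that ordering would require non-Gaussian and
scale-difference structure this generator does not claim to model.

## Problem sizes and runtime choices

The test and acceptance workloads use trial lengths of one 10-m straight
pass or one oval lap (~15–60 s at 30 Hz), cohorts of 30 + 25 subjects,
ten cohort replicates for classifier medians, twenty permutation
replicates, and 200 null features for the type-I calibration — sizes at
which every statistical check has adequate resolution while the full
suite runs in minutes on a single core.

## Known limitations

* Turning segments of the oval path are not segmented out; all features
  are computed over the whole trial, inflating variability features on
  oval courses (consistent with how the emulated protocol reports them).
* Heel-strike/toe-off timing is frame-resolution; no sub-frame
  interpolation.
* The walker's upper body is decorative; trunk/arm features cannot be
  studied with it.
* No multiple-testing correction in the screening stage (by design, with
  the caveat above).
* Missing-data handling assumes missingness from detection failures, not
  informative missingness.
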