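---
title: "Methods: head-compensated eye-movement analytics for VR sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-compensated eye-movement analytics for VR sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vrgaze)
```

vrgaze analyzes gaze recordings made with eye trackers built into
head-mounted VR displays, where the head moves freely while the tracker
reports gaze in the head frame. The package covers the full chain from raw
samples to group-level inference: head compensation, adaptive
velocity-threshold event detection, physiological event filters,
per-scenario scanpath features, saliency and ambient/focal analyses, group
statistics, and cross-validated diagnostic classification. A calibrated
synthetic session generator provides ground-truth-annotated data for
validating every stage.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions that were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

A sample stream consists of timestamps at a nominal 90 Hz, a unit gaze
vector in the head frame, a unit quaternion giving the head orientation
(world from head, Hamilton convention), a validity flag, and
participant/scenario/phase labels. Angles are azimuth (yaw about the
vertical axis) and elevation, in degrees; time is in milliseconds. These
conventions are asserted by the I/O validators in `read_gaze()`.

Head compensation (`to_world_angles()`) rotates each head-frame gaze vector
by the concurrent head quaternion, yielding a world-frame angular trace.
Because rotation is an isometry of the sphere, event durations and
amplitudes are invariant to any global re-orientation of the head stream —
one of the property tests.

Tracker dropouts are handled by a gap policy: invalid runs of at most
`gap_interpolation_max_samples` (default 2) with valid neighbours are
interpolated along the great circle; longer gaps split the trace into
segments, and events touching a segment edge are flagged incomplete because
their durations are censored. Keeping censored fixations would bias the
duration mean downwards by more than 10% at realistic loss rates, so
`filter_events()` drops incomplete events by default.

## Event detection

Detection follows the adaptive velocity-threshold scheme of Engbert and
Kliegl. Component velocities are estimated with a 5-sample moving-window
differentiator, `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)`;
azimuth velocity is multiplied by `cos(elevation)` so both components are
true angular rates (correctness near the poles; at the elevations used here
the correction is small). Thresholds are `eta = lambda * sigma` per
component, with `sigma = sqrt(median(v^2) - median(v)^2)` — the
median-of-squares estimator, which is robust to the saccadic tail of the
velocity distribution. Note that this estimator converges to
`sqrt(qchisq(0.5, 1)) ~ 0.67` times the Gaussian SD, so the default
`lambda = 6` corresponds to roughly four noise SDs; this is the standard
behavior of the algorithm, and `lambda` and the window length are
configurable. Thresholds are estimated per scenario, matching the
per-scenario analysis grain; estimation across a whole session would be the
alternative, but scenarios can differ in noise level (head motion, scene
content).

A sample is a saccade candidate when
`(v_az/eta_az)^2 + (v_el/eta_el)^2 > 1` for at least `min_saccade_samples`
(default 2) consecutive samples; candidates separated by less than
`min_intersaccadic_ms` (default 40 ms) are merged.

At 90 Hz the velocity stencil spans ±2 samples (±22 ms), which smears
saccade boundaries outward by about one sample per side. Left uncorrected,
this inflates saccade durations by roughly 20% and shortens fixations by
about 7% — material biases for 57–67 ms saccades and ~310 ms fixations.
`detect_events()` therefore refines each candidate's boundaries from the
*position* trace: the displacement along the saccade path is normalized by
the amplitude, the 10%→90% rise time is read off by linear interpolation,
and the duration is that rise time divided by 0.608 — the 10–90% span of
the cubic sigmoid `s(u) = 3u^2 - 2u^3`, the minimum-assumption smooth
monotone profile that the session renderer also uses. For real recordings
this is a kinematic model assumption (real saccades are close to this
family); the refinement falls back to the raw run span for candidates
whose traversed amplitude is below 0.2 degrees. Saccade amplitudes are
measured between the averaged gaze directions just before and just after
the suprathreshold run — i.e. between the flanking fixation positions —
which makes them insensitive to the boundary smear.

Fixations are the complementary intervals within a segment. Their position
is the centroid direction of their samples and their `amplitude_deg` field
records the dispersion radius (maximum angular distance from the
centroid). Peak saccade acceleration is the maximum absolute first
difference of the angular speed inside the (one-sample-extended) run.

## Event filters

The cleaning windows follow the published procedure and are the
`filter_params()` defaults: saccades accepted with duration 22–300 ms
(the lower bound is two sample intervals, `floor(2 * 1000 / rate)`,
via `min_saccade_duration_ms()`), amplitude at least 0.75 degrees, and peak
acceleration at most 36 000 deg/s²; fixations accepted with duration
100–1000 ms. An event survives iff every applicable bound holds; removal
counts per rule are attached to the result and logged in the pipeline
manifest. Filters are idempotent and order-independent.

## Scanpath features

`feature_table()` aggregates filtered execution-phase events into one row
per participant and scenario: mean fixation duration, mean saccade
duration, mean saccade amplitude, event counts, the invalid-sample
percentage, and NSS. Means over empty sets are missing, never zero; the
classifier matrices impute missing cells with the column median. Group
summaries are participant-weighted (means of participant means), the
convention used for all calibration comparisons; event-weighted summaries
would overweight participants with more events.

Normalized scanpath saliency (`nss()`) z-normalizes the saliency map over
all cells (population SD) and averages the bilinearly interpolated z-value
at each fixation centroid. Zero means fixations are unrelated to the map;
the measure is invariant to affine rescaling of the map by construction.
Sampling at fixation centroids (rather than at every raw sample) weights
each fixation equally regardless of duration; an all-samples variant is
available by passing a data frame of sample angles. The synthetic setting
uses one static map per scenario; the dynamic (video-based) saliency of
real sessions is out of scope.

Ambient/focal time courses (`bin_time_course()`) divide each execution
phase into 1-s bins from the moment the instruction phase ends, assign
events by onset, and compute per bin: mean fixation duration, fixation
count, mean saccade amplitude, and the proportion of saccades landing
within the same object. A saccade enters that proportion's denominator
only when both flanking fixations carry an object label; fixations on
non-object surfaces (floor, walls, teleport waypoints) are excluded. The
partial final bin is kept.

Head-motion metrics (`head_motion_metrics()`) are the sum of successive
quaternion geodesic angles (total head rotation) and the mean per-step
angular speed.

## Group statistics

The five task-performance measures are compared with a two-sided rank-sum
Z test (`ranksum_z()`): the Mann–Whitney U with its tie-corrected normal
approximation, no continuity correction. The test family behind the
published Z values is unnamed there; the rank-sum choice is consistent
with Z statistics on bounded, skewed game scores, and the suite verifies
the approximation against exhaustive permutation at small n.

The three eye-movement features are modeled at the participant × scenario
grain with linear mixed models (`lmm_group_contrast()`, fitting delegated
to lme4): Group and Task Scenario as fixed effects, random intercepts for
Participant and Task Scenario Order (coded as per-position intercepts; the
alternative, per-ordering intercepts, is not identifiable at these sizes),
optionally a random intercept for binned invalid-sample percentage. A
tested term is assessed by the likelihood-ratio chi-square between
maximum-likelihood fits with and without it (ML, not REML, as required for
fixed-effect comparisons). Singular fits are flagged with a warning and
the result returned. The LRT's chi-square reference is asymptotic: below
roughly 20 participants it is visibly anti-conservative, so the type-I
calibration check simulates 30 participants × 8 scenarios.

Effect sizes are `phi = sqrt(chi2 / N)` with N the number of participants
in the model. P values are adjusted within each reported family by the
Benjamini–Hochberg step-up (`bh_fdr()`, delegated to `p.adjust`); note the
adjustment is monotone and deterministic but not idempotent — re-adjusting
adjusted values inflates them, which is a property of the step-up formula.

## Classification

Three feature sets mirror the study design: the five performance measures;
the 3 × n_scenarios per-scenario eye features (39 columns at the default
13 scenarios); and the three eye features of a single designated scenario.
`nested_cv()` evaluates a scaling → PCA → SVM pipeline in an outer
stratified tenfold loop while an inner grid-search loop (default 5-fold)
selects the PCA component count, kernel, cost, and gamma by inner AUC.
Scaling and PCA are fit on training folds only, so test information never
reaches the fitted pipeline — a property the suite checks by corrupting
one fold's held-out rows and verifying the fold's chosen hyperparameters
are unchanged. Default grids: components {2, 5, 10, 20}, kernels
{linear, RBF}, cost {0.1, 1, 10, 100}, gamma {1/k heuristic, 0.01, 0.001}.
ROC scores are the signed SVM decision values; the confusion matrix uses
the zero-threshold prediction, averaged over folds as percentages per true
class. AUC is the rank (Mann–Whitney) statistic, identical to the
trapezoidal area with tie handling.

`bootstrap_compare()` re-evaluates two classifier specifications on 30
bootstrap resamples of the participants (shared folds per iteration, so
the comparison is paired at the fold level) and applies a two-sided
two-sample t test across the two sets of 30 mean AUCs, df = 58. The
equal-variance unpaired form matches those degrees of freedom.

## The synthetic session generator

The generator emulates the study conditions the analysis assumes: two
groups (37 ADHD / 36 control by default), 13 scenarios per participant,
each with an instruction phase (gaze parked near a speaker location;
default 15 s) and a 90-s execution phase, sampled at 90 Hz with isotropic
tracker noise (default SD 0.1 degrees, matching a 0.5-degree-accuracy
consumer tracker's frame-to-frame jitter scale), slow sinusoidal head yaw
(±20 degrees at 0.1 Hz, static during instruction — enough to exercise
head compensation without dominating the kinematics), and bursty data loss
(geometric bursts, mean 3 samples; rates 5% ADHD / 3% control, inside the
published range and direction of group difference).

Event streams alternate fixations and saccades. Fixation durations and
saccade amplitudes are drawn from truncated normals confined to the
admissible filter windows ([100, 1000] ms and [0.75, Inf) degrees), with
the location solved by `calibrate_truncated_mean()` so the truncated mean
equals the participant's target — this makes post-filter means equal the
group targets in expectation, which is what the parameter-recovery
validation requires. The solver iterates the contraction
`loc <- loc + (target - truncated_mean(loc))` and falls back to bisection
near a bound where the truncated mean flattens. Saccade durations follow
an affine main sequence (2.2 ms per degree of amplitude) plus noise,
truncated to [22, 300] ms, with the intercept recalibrated per participant
against the realized amplitudes so the group duration target is met
without breaking the amplitude–duration coupling.

Group targets default to the published group summaries: fixation 317 (36)
vs 309 (30) ms, saccade duration 57 (8.3) vs 67 (10.1) ms, amplitude 5.44
(1.4) vs 6.29 (1.7) degrees. The printed SDs are interpreted as
between-participant SDs of participant means (they summarize
per-participant aggregates); within-participant SDs are free parameters
with defaults 80 ms / 2 degrees / 8 ms, chosen as plausible single-event
variability an order of magnitude above the between-participant spread of
means, and flagged as free in the configuration. Event rate follows from
the duration means (~2.7 events/s) rather than being a separate dial.

Two deliberate generator choices deserve emphasis:

* **Standardized between-participant draws.** `simulate_cohort()` draws
  participant trait means as z-scores that are centered and rescaled to
  sample mean 0 and SD 1 before scaling by the group parameters, so the
  realized cohort mean and between-SD equal the targets exactly rather
  than to sampling error (at n = 37 the raw sampling error of a cohort
  mean would be ~1.9% for fixation duration, larger than the 1%
  calibration the validation demands). Draws are additionally winsorized
  at ±3 between-SDs; unbounded extremes would demand near-degenerate
  truncation calibrations while contributing nothing to realism.
  `simulate_participant()` called standalone uses plain iid draws.
* **Relevance-dependent durations with a preserved mean.** Fixations
  landing on task-relevant objects run longer than on task-irrelevant ones
  by `relevance_offset_ms` (default 40 ms, so the relevance analysis has a
  recoverable signal), applied with weights proportional to the realized
  relevant/irrelevant mix so the overall duration mean is unchanged.

Performance measures (total score %, task efficacy %, navigation efficacy,
controller motion, total actions) are independent normals clipped to
admissible ranges. Their group offsets default to about 0.3
between-participant SDs in the published directions (clinical group lower
on the first three, higher on the last two) — a deliberately modest
separation: the study's headline contrast is that scenario-resolved eye
features discriminate the groups better than coarse performance scores,
and the generator encodes that ordering qualitatively without claiming the
real effect sizes, which no printed table quantifies.

Rendering (`render_gaze_trace()`) draws fixations as a stationary
direction plus isotropic angular noise and saccades as the cubic-sigmoid
great-circle sweep; the world direction is then re-expressed in the
(moving) head frame, so the downstream head compensation is genuinely
exercised rather than trivially inverted.

What the generator does **not** emulate — and hence what passing
validation does and does not show about real data: no smooth pursuit, no
vestibulo-ocular-reflex interplay between head and eye (head motion is
independent of the scanpath), no post-saccadic oscillations or drift
within fixations, no dynamic saliency, no blink kinematics beyond validity
bursts, no 3-D room geometry or object interaction. Recovery results
therefore validate the pipeline's correctness under its stated kinematic
model, not the clinical effect sizes of any real cohort — the published
real-data statistics (classification AUCs, mixed-model chi-squares) are
not reproducible without the cohort and are not targets here.

## Numerical choices and degenerate inputs

* Angles in degrees, time in ms, quaternions world←head Hamilton; azimuth
  unwrapped per segment before differentiation.
* Great-circle distances use the chord (haversine-stable) form; spherical
  interpolation is exact slerp.
* `adaptive_threshold()` requires at least 10 valid velocity samples and
  raises an instructive error on zero velocity dispersion (noiseless
  constant input): detection needs a noise floor.
* Empty traces yield empty event tables; empty feature cells are missing,
  and downstream statistics drop missing rows pairwise.
* The fixed-point calibration tolerance is 1e-8 relative (far inside the
  0.1% contract); ties in the inner grid search resolve to the first
  configuration in grid order; fold assignment is stratified with one
  re-stratification attempt before erroring.
* All randomness flows through `with_seed()` (caller RNG state restored)
  and `derive_seed()` (one master seed spawns labelled stage seeds), so a
  single integer reproduces a full run bit-wise.

## Validation problem sizes

The study-scale checks in the test suite and the acceptance script use the
printed design (37/36 participants × 13 scenarios, 90-s executions) for
generator calibration and for the rendered-trace recovery of the control
group. The estimator-behavior checks use sizes chosen for the property
being tested: the classifier permutation null uses 200 runs of 40
participants with a minimal grid (the null distribution of AUC does not
depend on the grid); the mixed-model type-I simulation uses 200 replicates
of 30 participants × 8 scenarios (asymptotic LRT calibration); the
eye-versus-performance ordering uses 20 cohort replicates with
instruction phases of length zero (instruction events enter no feature)
and a reduced shared hyperparameter grid, which affects both classifiers
symmetrically.

## Known limitations

* The boundary refinement assumes a sigmoidal displacement profile; for
  real data with strongly asymmetric saccades the 0.608 shape factor is an
  approximation (configurable in source, and the raw run span is the
  fallback).
* Per-scenario threshold estimation needs scenarios long enough for a
  stable median (tens of seconds at 90 Hz); very short scenarios should
  pool thresholds.
* The φ effect size uses N = participants; other N conventions exist and
  published φ values may not be exactly reproducible under any single one.
* The generator's instruction-phase gaze is a stylized speaker-anchored
  scanpath; instruction-phase analyses should not be over-interpreted.
* `screen_participants()` treats exactly 30% invalid as excluded; the
  boundary itself is a convention recorded here.
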