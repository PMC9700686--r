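# vrgaze

Eye-movement analytics for head-mounted VR eye tracking, built around the
kind of study design used to probe attention deficits in children: a
naturalistic VR task with 13 scenarios (instruction phase, then up to 90 s
of free execution), a 90 Hz eye tracker in the headset, two groups (a
clinical ADHD group and typically developing controls), five coarse
task-performance scores per participant, and the question whether
scenario-resolved eye-movement features classify group membership better
than the performance scores do.

The package implements the full analysis chain plus a calibrated synthetic
session generator for validation, since cohort recordings of this kind are
not openly deposited:

* **Head compensation** — eye-in-head gaze vectors are rotated into the
  world frame by the concurrent head quaternion (`to_world_angles()`), with
  spherical interpolation across short tracker dropouts and segment splits
  across long ones.
* **Event detection** — the Engbert–Kliegl adaptive velocity threshold:
  component velocities `v_n = (x_{n+2}+x_{n+1}-x_{n-1}-x_{n-2})/(6Δt)`,
  per-scenario thresholds `η = λ·σ` with the median-based estimator
  `σ = sqrt(median(v²) − median(v)²)` (λ = 6, 5-sample window), an elliptic
  two-component criterion, and displacement-based boundary refinement that
  removes the velocity-window smear at 90 Hz (`detect_events()`).
* **Physiological filters** — saccades kept with duration 22–300 ms
  (lower bound = 2 sample intervals), amplitude ≥ 0.75°, peak acceleration
  ≤ 36 000°/s²; fixations kept with duration 100–1000 ms
  (`filter_events()`).
* **Scanpath features** — per participant × scenario means of fixation
  duration, saccade duration and amplitude; normalized scanpath saliency
  (mean z-scored map value at fixation centroids); object-relevance
  statistics; 1-s ambient/focal time bins; head-rotation metrics.
* **Group statistics** — tie-corrected rank-sum Z tests for the five
  performance measures; linear mixed models (Group + Task Scenario fixed,
  Participant and Task Scenario Order random intercepts) with
  likelihood-ratio χ² contrasts and φ = √(χ²/N) effect sizes;
  Benjamini–Hochberg FDR per family.
* **Classification** — scaling → PCA → SVM with inner grid-search
  cross-validation nested in an outer stratified tenfold loop
  (`nested_cv()`), rank-based AUC, averaged ROC and confusion outputs, and
  a 30-iteration bootstrap-CV t-test between classifiers
  (df = 58, `bootstrap_compare()`).
* **Synthetic sessions** — `simulate_cohort()` generates ground-truth
  event ledgers and rendered noisy gaze streams whose post-filter group
  means are calibrated to the published summaries (fixation 317/309 ms,
  saccade duration 57/67 ms, amplitude 5.44°/6.29°) via truncated-normal
  mean calibration and a main-sequence coupling of amplitude and duration.

See `vignettes/vr-eyetracking-methods.Rmd` for the models, parameter
defaults, and design decisions.

## Worked example

Run the bundled small demonstration cohort (12 + 12 participants, 3
scenarios — about two minutes):

```r
library(vrgaze)
cfg <- system.file("extdata", "demo_config.yaml", package = "vrgaze")
res <- run_pipeline(cfg, outdir = "demo_run")
res$result$stats
```

```
        family                test statistic_name statistic p_raw p_fdr
1  performance         total_score              Z     1.155 0.248 0.524
2  performance       task_efficacy              Z     0.577 0.564 0.564
3  performance navigation_efficacy              Z     0.924 0.356 0.524
4  performance   controller_motion              Z     0.808 0.419 0.524
5  performance       total_actions              Z     0.924 0.356 0.524
6 eye_features     mean_fix_dur_ms           chi2     0.094 0.759 0.759
7 eye_features    mean_sacc_dur_ms           chi2     6.314 0.012 0.036
8 eye_features   mean_sacc_amp_deg           chi2     2.107 0.147 0.220
```

The rank-sum Z rows test the five performance measures; at this small demo
size none separates the groups. The χ² rows are mixed-model group
contrasts on the detected, filtered eye features: the saccade-duration
difference built into the generator (57 vs 67 ms) is already detectable
(p_fdr = 0.036), the weaker fixation-duration difference (317 vs 309 ms)
is not. The manifest reports a mean cross-validated AUC of 0.708 for the
eye-feature classifier versus 0.333 for the performance-measure classifier
(small-sample evaluations are noisy; at the full 37 + 36 × 13 design the
ordering is systematic — that check lives in the test suite). The output
directory contains `gaze.tsv`, `events.tsv`, `features.tsv`, `bins.tsv`,
`stats.tsv`, `auc_report.json` and `manifest.json` with per-stage counts
and file digests.

A thin command-line wrapper is installed at `inst/cli/vrgaze`
(subcommands `simulate`, `detect`, `features`, `stats`, `classify`, `all`).

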