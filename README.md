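# gaitssc

Predicting cognitive status from wearable-sensor gait patterns with
**Stable Sparse Classifiers** (SSC).

Subtle cognitive decline in older adults leaves traces in how they walk —
more variable step timing, weaker vertical trunk acceleration, shorter and
slower steps — and those traces grow when walking competes with a
concurrent cognitive task. `gaitssc` implements, as a tested R package
plus a reproducible analysis workflow, the full chain from a raw tri-axial
trunk-accelerometer recording to a stable, sparse gait-biomarker panel
that discriminates cognitively impaired from healthy elderly adults. It is
aimed at researchers in gait analysis and cognitive aging who want a
self-contained, seedable reference implementation of this pipeline.

## What is inside

* **Signal processing** (`transform_axes`, `tilt_correct`,
  `lowpass_filter`, `split_segments`, `detect_gait_events`): ISB axis
  alignment, Moe-Nilssen tilt correction, 4th-order zero-lag Butterworth
  low-pass at 3 Hz, turn detection with 3 s edge trimming, and gait-event
  detection from the integrated vertical acceleration via Gaussian
  continuous-wavelet derivatives (initial contacts at the minima of the
  first derivative, final contacts at the peaks of the second).
* **Gait features** (`compute_stride_params`, `compute_stgf`,
  `compute_dtc`, `assemble_feature_table`): sixteen spatio-temporal gait
  features (STGF) per walking task — step/stride times and their
  coefficients of variation, cadence, vertical-acceleration RMS, support
  and swing phases, inverted-pendulum step length, speed — for four tasks
  (normal, easy dual, hard dual, fast), plus dual-task costs
  `DTC = (single − dual)/single × 100`, direction-averaged into a
  96-measure table.
* **Cognitive index** (`fit_normative_model`, `compute_mdcog`,
  `cluster_groups`): the MDCog summary index, the Mahalanobis distance
  `sqrt(r' Σ⁻¹ r)` of a subject's age/education-adjusted, orientation-
  aligned cognitive residual vector `r` from normative data, and group
  definition by 1-D k-means on MDCog (1,000 restarts) with an age split.
* **Stable Sparse Classifiers** (`stability_selection`, `validate_model`,
  `operating_point`): the elastic net

  `min over (φ0, φ) of (1/2N) Σᵢ (yᵢ − φ0 − xᵢᵀφ)² + λ [ (1−γ)·½‖φ‖₂² + γ‖φ‖₁ ]`

  solved by an authored cyclic coordinate-descent core (Rcpp), wrapped in
  resampled stability selection (70% of subjects and 70% of features per
  iteration, univariate screening, cross-validated λ; stable features are
  those selected in >50% of the iterations offering them) and resampled
  ROC/AUC validation (median AUC over stratified 70/30 splits, operating
  point at 90% target sensitivity).
* **Evaluation** (`permutation_anova2`, `compare_model_aucs`,
  `baseline_classifiers`): restricted-permutation two-way ANOVA
  (GROUP × TASK), Bonferroni rank comparison of the eleven feature-subset
  models (4 single tasks, 6 pairs, all tasks), and SVM / shrinkage-LDA
  baselines on shared stratified folds.
* **Synthetic cohort** (`generate_cohort`, `generate_cognitive_scores`,
  `generate_acceleration`, `generate_feature_table`): a generator that
  emulates the study conditions — 40 young adults, 62 healthy elderly, 23
  impaired elderly with calibrated MDCog distributions, and group gait
  profiles with ground-truth events — so every stage is testable without
  any recorded data.

## Worked example

```r
library(gaitssc)

profile <- default_gait_profiles()[["MCI-E"]][["FastW"]]
sim <- generate_acceleration(profile, task = "FastW", seed = 5)
rec <- tilt_correct(sim$recording)
rec <- gaitssc:::lowpass_recording(rec)
seg <- split_segments(rec)[[1]]
events <- detect_gait_events(seg)
round(compute_stgf(compute_stride_params(events), seg, height = 160), 3)
#>      StpT   StpTCoV      StrT   StrTCoV        Cd       RMS       DSD       SSD
#>     0.499     4.514     0.999     3.285   120.192     0.191     0.122     0.377
#>   SwDurF1   SwDurF2   StDurF1   StDurF2 StepDurF1 StepDurF2    StepLg        GS
#>     0.368     0.385     0.630     0.613     0.488     0.509     0.471     0.943
```

The impaired-elderly fast-walk profile planted a mean step time of 0.50 s
with 4.2% step-time variability, an RMS of 0.19 g and a double-support
fraction of 0.14 of the stride; the detected events recover the step time
(0.499 s), the elevated variability (4.5%), the RMS (0.191 g) and the
double-support time (0.122 s). Step-time variability and RMS are the
quantities that end up carrying most of the classification signal.

The full study runs as numbered drivers:

```sh
Rscript analysis/01_simulate.R        # cohort, cognitive scores, normative data
Rscript analysis/02_gait_features.R   # signals -> events -> 96-measure table
Rscript analysis/03_cognitive_index.R # MDCog + k-means group definition
Rscript analysis/04_ssc_models.R      # SSC over the 11 task-subset models
Rscript analysis/05_baselines_anova.R # permutation ANOVA, rank comparison, baselines
```

Each writes its tables under `results/` and prints a short summary (group
sizes, the MDCog cut-off near 6, per-model median AUCs, the stable
biomarkers — dominated by fast-walk step/stride-time variability and RMS —
and the ANOVA significance counts).

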