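---
title: "From trunk acceleration to stable gait biomarkers of cognitive status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From trunk acceleration to stable gait biomarkers of cognitive status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitssc)
```

`gaitssc` turns raw tri-axial trunk-accelerometer recordings of short
walks into a sparse, stability-selected panel of gait biomarkers that
discriminates cognitively impaired from healthy elderly adults. This
vignette explains the models and procedures stage by stage, the
parameters that matter, the numerical choices behind them, and what the
synthetic-data tests do and do not establish.

## The study design the package encodes

Three groups walk four tasks over 2 × 20 m (out and back): a normal-pace
walk (NormalW), a fast walk (FastW), and two dual tasks at normal pace —
counting steps aloud (EasyD, an easy cognitive load) and counting
backwards (HardD, a hard one). The groups are young adults (YA), healthy
elderly (HE) and elderly with mild cognitive impairment (MCI-E); the
elderly split is defined from cognitive testing, not clinical diagnosis,
via the MDCog index described below. Group sizes default to 40/62/23 —
the cohort structure the synthetic generator emulates.

## Signal chain

A lumbar-worn IMU measures acceleration in its own device frame.
`transform_axes()` maps it onto the anatomical frame (anteroposterior,
mediolateral, vertical positive up) with a signed axis permutation.
`tilt_correct()` removes static sensor tilt the Moe-Nilssen way: the mean
acceleration vector over the recording — gravity, to first order, during
steady walking — is rotated onto the vertical axis, and 1 g is then
subtracted, leaving a gravity-free signal. Inputs whose mean magnitude is
below 0.5 g are treated as already gravity-compensated and have gravity
restored internally before estimating the rotation; this makes the
correction idempotent, at the cost that a recording from a genuinely
free-falling sensor is indistinguishable from a level, compensated one.

`lowpass_filter()` is a 4th-order Butterworth at 3 Hz applied forward and
backward (`signal::filtfilt`), which cancels the phase response; we pad
the signal by odd reflection (3 cutoff periods per side) because the
plain forward-backward pass otherwise leaves visible edge transients.
Walking content below 3 Hz (step frequencies are 1.5–2.5 Hz) passes
essentially untouched.

`split_segments()` cuts the recording into the two straight-walk
directions at the turn, located as the longest sustained (≥ 1 s) window
whose vertical-dynamics RMS falls below 20% of the whole-recording RMS;
the cut is the window midpoint, and 3 s are trimmed from each end of each
segment to drop gait initiation, termination and turn contamination. The
recordings give no marker of the turn, so a low-activity criterion is the
natural detector; the 20%/1 s values are free parameters exposed in the
function signature.

`detect_gait_events()` implements a McCamley-style wavelet detector. The
vertical signal is smoothed by cumulative-trapezoid integration
(demeaned, which removes sensitivity to the integration constant), then
differentiated with a derivative-of-Gaussian kernel — the discrete
Gaussian continuous-wavelet transform. Initial contacts (IC) are the
local minima of this first derivative; differentiating once more, final
contacts (FC) are the local peaks of the second derivative. The kernel
scale defaults to 0.12 of the dominant step period, estimated from the
spectral peak of the integrated signal in 0.5–3.5 Hz; detectors of this
family are scale-sensitive, and tying the scale to the measured cadence
keeps the detector working across the 0.4–0.8 s step times the cohort
spans (a fixed scale can be supplied instead). Amplitude gates (half an
SD beyond the mean) suppress the secondary ripple extrema of multi-
harmonic step shapes; ICs closer than 0.25 s are merged (the weaker
dropped) and intervals beyond 2.0 s raise a warning, bounds chosen as
physiological limits of adult stepping. Exactly one FC is kept between
consecutive ICs (the strongest peak; an isolated miss is imputed at the
median IC→FC offset), which enforces the gait-cycle event grammar
downstream code relies on. Foot labels alternate from the first detected
IC; the sensor cannot tell left from right, so `F1`/`F2` are arbitrary
but consistent.

## Gait features

From the event times, `compute_stride_params()` derives the interval
series: step time (consecutive ICs), stride time (same-foot ICs), stance
(IC to same-foot FC), swing (FC to that foot's next IC), double support
(IC to the opposite foot's FC) and single support (its complement within
the step). `compute_stgf()` reduces them to the sixteen spatio-temporal
gait features (STGF): means of the interval series; step- and stride-time
coefficients of variation (100 × sample SD / mean — the sample,
n−1, convention); cadence 60/StpT; the RMS of the gravity-free filtered
vertical acceleration; per-foot swing/stance/step durations; step length
from the inverted-pendulum model, `StepLg = 2·sqrt(2lh − h²)` with
pendulum length `l = 0.53 × height` and per-step vertical excursion `h`
obtained by double integration with per-step linear detrending (no
multiplicative correction factor by default); and speed GS = StepLg/StpT.
At least 3 steps are required before a CoV is reported.

Dual-task costs compare each STGF between the normal walk (the only
single-task walk at preferred pace, hence the reference) and a dual task:
`DTC = (single − dual)/single × 100`, signed. Per direction this gives
16 STGF × 4 tasks + 16 DTC × 2 dual tasks = 96 measures; the two walking
directions are highly correlated, so their element-wise average forms the
final feature table. DTC is computed per direction before averaging.
Subjects with any failed task/direction are dropped listwise — with a
cohort of this size, imputation would add machinery without changing
conclusions. Whether support-phase features should aggregate per step or
per stride is a convention choice; the package uses per-stride means.

## The MDCog cognitive index and group definition

Twelve measures from five neuropsychological tests (MMSE, brief test of
attention, trail-making A/B, Hopkins verbal learning, digit–symbol) are
summarized into one index. `fit_normative_model()` orients every measure
so higher = better (the timed trail-making scores are negated), regresses
each on age and education over a normative sample, and estimates the
12 × 12 residual covariance, shrunk toward its diagonal with an analytic
(Schäfer–Strimmer) intensity when its condition number exceeds 10⁶.
`compute_mdcog()` is then the Mahalanobis distance of a subject's deficit
vector (predicted minus observed performance) from the norm:
`MDCog = sqrt(r' Σ⁻¹ r)`, non-negative, larger = worse, and invariant to
invertible linear remappings of the measures. Regression-based norms were
chosen over stratified age × education bands as the minimal construction
consistent with "adjusted for age and education and their correlation";
the package makes no attempt to reproduce any published normative table —
raw scores and a normative sample are inputs.

Groups: `cluster_groups()` runs 1-D k-means (k = 2) on MDCog with 1,000
random restarts keeping the lowest within-cluster sum of squares; the
higher-centroid cluster is the impaired group, and the healthy cluster is
split at age 60 (the elderly inclusion bound) into YA and HE. On
synthetic cohorts with the default MDCog structure, the implied decision
cut falls between 5 and 7.5 (near 6.5), and under 10% of subjects land in
a different group than the generator intended.

## Stable Sparse Classifiers

The classification engine is the elastic net in its penalized
least-squares form on 0/1 group labels,

$$\min_{\varphi_0,\varphi}\;
\frac{1}{2N}\sum_{i=1}^N (y_i - \varphi_0 - x_i^\top\varphi)^2
+ \lambda\!\left[(1-\gamma)\tfrac12\lVert\varphi\rVert_2^2
+ \gamma\lVert\varphi\rVert_1\right],$$

solved by cyclic coordinate descent with soft-thresholding updates (Rcpp
core). Convergence is declared when no single coefficient update changes
the objective by more than 10⁻⁷ of the null variance — the reference-
library semantics. A plain max-coefficient-change criterion was tried
first and is pathologically slow on gait features, where columns such as
cadence and step time are near-perfect duplicates and coefficient weight
shuffles between them long after the fit has converged. The squared-error loss is implemented exactly as printed in this
literature; a logistic-loss variant sits behind `enet_config(loss =
"logistic")` for comparison (proximal-gradient solver), but the default
reproduces the linear-regression formulation. The mixing parameter
defaults to γ = 0.5 — an even ridge/lasso blend, appropriate for
correlated gait features — and the λ path is 100 log-spaced values from
λ_max (the smallest all-zero λ) down to 10⁻³ λ_max, selected by
stratified 10-fold cross-validation (CV-minimum rule; one-SE optional).
Tests verify the solver against brute-force lattice minimization on small
problems (agreement within 10⁻⁴) and against an independent library
solver, whose objective it matches or beats.

Stability selection repeats, 500 times by default: draw a stratified 70%
of subjects and a random 70% of features; screen out the weaker half of
the offered features by absolute two-sample t statistic (the screening
criterion is not specified in this literature beyond "minimal
contribution", so the t ranking is a declared stand-in); z-score using
the subsample's own statistics (no leakage; the convention is not stated
upstream, so it is fixed here conservatively); fit at the cross-validated
λ; record which coefficients are non-zero. A feature's selection
frequency divides by the number of iterations in which it was *offered*
(survived subsampling and screening) rather than by the total iteration
count — the fairer denominator under feature subsampling. Features with
frequency strictly above 50% form the stable set.

Validation refits the stable set on stratified 70/30 splits, scores the
held-out subjects with φ₀ + xᵀφ, and reports the AUC distribution over
500 splits; the 50th percentile is the accuracy measure. Pointwise 2.5/50
/97.5% ROC bands are interpolated on a fixed false-positive-rate grid.
The operating point fixes target sensitivity at 90% — missing no more
than 10% of impaired subjects — choosing the pooled-score threshold whose
sensitivity is the smallest value at or above the target and reporting
the implied specificity and prevalence-weighted accuracy. An empty
stable set yields an explicit no-biomarkers result rather than an error.
Stratification throughout protects the 62-vs-23 class imbalance.

Eleven feature-subset models are compared: each task alone, each of the
six task pairs (with the dual-task-cost columns of any included dual
task), and all tasks together.

## Statistical evaluation

`permutation_anova2()` runs a two-way GROUP × TASK ANOVA per gait feature
without normality assumptions: classical F statistics on the observed
subjects × tasks matrix, with restricted permutations — group labels
permuted across subjects for the GROUP and interaction effects, task
labels permuted within each subject for the TASK effect — and
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`. Identical values give p = 1 by
convention. The implementation is vectorized across permutations (one
`rowsum` per null), which is what makes the 1,000-replicate type-I
calibration test affordable; the function accepts n_perm ≥ 99 with a
default of 999. The interaction null permutes whole subjects on the
*residuals* after removing both main effects (the ter Braak scheme):
permuting raw data is grossly anticonservative for the interaction when
group main effects are large, which these gait features have.

`compare_model_aucs()` pools all models' AUC samples, ranks them jointly,
and compares mean ranks against a reference model with the normal
rank-sum approximation, Bonferroni-corrected over the number of
comparisons; being rank-based it is invariant to any common monotone
transform of the AUCs. `baseline_classifiers()` evaluates an RBF-kernel
SVM (library defaults) and a shrinkage-regularized LDA (pooled covariance
shrunk toward its diagonal with the analytic intensity) under repeated
stratified 10-fold cross-validation — 500 repetitions by default — with
both classifiers sharing identical fold assignments for a paired
comparison; all standardization is fitted inside training folds, and the
SVM's decision-value orientation is fixed on the training fold only.

## The synthetic cohort: what it emulates, and what it does not

Every stage is exercised by a generator rather than recorded data. The
cohort module draws 40/62/23 subjects with the reference age, height,
weight and sex structure; education is uniform on 6–20 years and
independent of group, a neutral choice in the absence of a reported
distribution. Cognitive scores depend linearly on age and education with
compound-symmetric residual correlation (ρ = 0.3); group-level deficits
live in a whitened latent space where MDCog is simply the vector norm, so
per-group (scale, shift) pairs can be calibrated by numerically matching
noncentral-chi moments to the target MDCog means and SDs (2.91 ± 0.97,
3.81 ± 1.08, 9.30 ± 1.65). The means are matched exactly in expectation;
for the two healthy groups the isotropic noncentral-chi family cannot
reach the target mean/SD ratio, so their SDs sit somewhat below target —
the means, the cluster cut near 6 and the group recovery rate are the
properties the tests assert. Group scales other than 1 have a natural
reading: study groups are more (impaired) or less (young) heterogeneous
than the broad normative population against which Σ is estimated.

Trunk signals are built per step as a two-harmonic cosine with its global
minimum at the initial contact, step intervals drawn i.i.d. with the
profile's CoV, scaled so the 3 Hz-filtered RMS hits the profile target,
with gravity, a 3° static tilt, white noise, and a 3 s low-amplitude turn
gap between the two 20 m directions. The sampling rate defaults to
100 Hz, typical for this sensor class. Ground-truth ICs are the step
onsets; FCs sit at the double-support fraction of the stride after each
IC. Group gait profiles encode the qualitative ordering reported for
such cohorts — variability MCI-E > HE > YA; cadence, RMS, step length and
speed YA > HE > MCI-E — with magnitudes chosen once for clear but
non-degenerate separation. Each subject deviates from the group profile
by one consistent lognormal factor per parameter (10% on step time, 40%
on its CoV, 22% on RMS, 12% on step length and double support) plus a
half-strength task-level factor. These spreads were set so the strongest
single-feature group contrasts (variability, RMS, step length) sit near
a standardized separation of one — the ballpark of published gait
biomarkers — because without between-subject spread all subjects of a
group are identical up to step-sampling noise and any classifier
separates the groups perfectly. Impaired subjects performing the hard
dual task get a tripled task-level factor — a nod to erratic task
compliance in that group. Note what this does and does not model: it
widens the impaired group's spread on that task, but real compliance
failure is a within-walk mixture (gait intermittently reverts to normal
when the count is abandoned), which the generator does not simulate; in
these synthetic conditions the hard dual task therefore does not lose
discriminative power the way it can in real cohorts. The group x task
profile grid is roughly
proportional rather than additive, so on the raw measurement scale the
generator carries genuine group-by-task interactions; the permutation
ANOVA accordingly flags more interactions on synthetic cohorts than a
real study would. A waveform this clean is *not* a
biomechanical gait model: no turning kinematics, no sex-specific gait, no
soft-tissue artifact, and final-contact timing inherits the waveform's
shape, so support-phase features are internally consistent rather than
anchored to independent truth. Consequently, passing tests certify that
the pipeline recovers what was planted (step timing to ~5 ms at 100 Hz,
CoV to < 1 percentage point, RMS to < 5%) and that the selection and
validation machinery is calibrated — not that real recordings of this
population would reach the same AUCs. On these synthetic cohorts group
separation is stronger than in real data, and the absolute AUCs should be
read accordingly.

## Numerical and design choices

* Filtering precedes segment splitting (tilt → filter → split → detect);
  on stationary walking segments the order does not change the events.
* The integrated signal is demeaned before the wavelet transform, removing
  drift sensitivity of the event detector.
* `cov_percent` uses the sample (n − 1) SD.
* The coordinate-descent path uses warm starts from λ_max down; λ_max is
  computed with γ floored at 10⁻³ so the ridge end of the mixing range
  keeps a finite path.
* Consistency thresholds use strict inequality (frequency > 0.5).
* All randomness flows from one root seed: `derive_seed(root, stage)`
  hashes the stage name onto the root (fixed multiplier, modulo 2³¹ − 1),
  so any stage can be rerun in isolation and full runs are byte-identical.
* Problem sizes in the shipped analysis and acceptance scripts: 100
  stability and 200 validation iterations, 50 baseline repetitions, 999
  ANOVA permutations — reduced from the protocol's 500/500 to keep a full
  eleven-model run tractable on a single CPU; the reduction widens the
  Monte-Carlo error of the reported medians slightly but changes no
  procedure.

## Known limitations

The detector assumes forward walking with a detectable turn gap; it has
no gyroscope fusion and never uses the horizontal axes for events. The
MDCog construction is the minimal regression-based reading of
"age/education-adjusted, correlation-compensated"; stratified normative
bands would be a drop-in alternative. The free-fall guard in
`tilt_correct()` cannot distinguish a truly free-falling sensor from a
pre-compensated recording. And the synthetic generator, by design,
cannot validate claims about real cohorts — it validates the pipeline.
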