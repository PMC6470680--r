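---
title: "Detecting race-walking faults from inertial sensors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting race-walking faults from inertial sensors: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racewalkr)
```

## The problem

Race walking imposes two technical constraints: at least one foot must stay
on the ground (violation: *loss of contact*, LC) and the supporting knee
must be straight during contact (violation: *knee bent*, KB). Judging is
visual, and flight phases shorter than the eye can resolve go unseen.
`racewalkr` implements an offline pipeline that discriminates regular race
walking from the two faults using the signals of seven body-worn inertial
measurement units (IMUs: pelvis, both thighs, both shanks, both feet; 3-axis
linear acceleration in m/s² and 3-axis angular velocity in °/s at 60 Hz),
plus one hand-held "coach" reference sensor.

The pipeline is: **simulate** (or load) sessions → **filter** → detect
condition **transitions** from the coach channel → **segment** strides from
the shank sagittal angular velocity → **extract** 7 features per channel per
stride → **classify** with a bank of nine classifiers under two-repetition
cross-validation → **aggregate** across athletes and apply a cascaded
**selection funnel**, then evaluate the surviving classifiers with a
simplified regular-vs-irregular model and a ROC-distance **goodness index**.

## The synthetic cohort generator

No public recordings exist for this protocol, so the package ships a
generator that emulates the study conditions: 8 athletes × 2 repetitions,
each session being three contiguous laps (regular, LC, KB, in that order)
of 120 strides per foot, sampled at 60 Hz. These are the package defaults
(`generator_config()`); tests that only probe mechanics run smaller cohorts
and say so below.

Each of the 42 kinematic channels is a truncated Fourier series (6
harmonics) over the stride cycle, with random per-channel amplitudes
(decaying as 1/k) and phases drawn once per athlete. Gait signals are
quasi-periodic, so harmonic templates capture their structure while keeping
class separation controllable. Three design features matter downstream:

* **Shank sagittal angular velocity** is fixed to
  $-100\cos(2\pi\varphi) + 30\cos(4\pi\varphi) - 10\cos(6\pi\varphi)$ °/s
  (scaled per athlete): one dominant positive mid-swing peak (+140 °/s at
  mid-cycle) and a single sharp negative minimum (−80 °/s) exactly at the
  cycle boundary, so heel-strike detection is well posed and anchored to the
  true stride boundary.
* **Fault signatures are additive and linear in the class-separation
  parameter `delta`**: LC subtracts a raised-cosine, free-fall-like dip
  (toward −9.81 m/s²) from the vertical acceleration of pelvis (twice per
  stride, one per step), shanks and feet during the flight window; KB adds
  mid-stance bumps to the sagittal angular velocity (15·δ °/s) and
  anteroposterior acceleration (5·δ m/s²) of shanks and thighs. Linearity
  makes the L2 distance between condition templates exactly proportional to
  `delta`, and `delta = 0` produces indistinguishable classes — the two
  anchors used by the calibration tests. The signature placement mirrors the
  observation that shank and foot accelerations differ visibly between the
  three conditions while angular velocities are better at timing gait
  events than at separating the conditions.
* **Right templates are left templates shifted by half a cycle**,
  reflecting gait symmetry; this is what justifies pooling left and right
  strides as rows of one dataset.

Athlete individuality is a multiplicative gain per (segment, channel) —
`athlete_variability` = 0.10 — applied to both the oscillatory part and the
fault signatures, plus a perturbed personal stride duration. Stride
durations are Gaussian with mean 0.70 s and 5% coefficient of variation.
Channel noise is additive white Gaussian, 0.5 m/s² (accelerometers) and
5 °/s (gyroscopes): deliberately far above datasheet sensor noise, as an
effective stand-in for soft-tissue artifact and strap motion. The coach
channel alternates between ±9.81 m/s², flipping sign at the first sample of
each lap.

What the generator does **not** emulate: musculoskeletal dynamics,
soft-tissue artifact structure (its noise is white), sensor bias/drift and
misalignment, fatigue and pacing drift, and real transition behaviour
(athletes easing into a fault mid-lap). Passing recovery tests on this
generator therefore demonstrates that the pipeline's machinery is correct
and calibrated, not that the reported real-athlete performance transfers.

Determinism: the master `seed` is expanded into per-athlete and per-session
sub-seeds by a fixed integer-mixing rule (kept below 2³¹), so a cohort is
byte-reproducible from its configuration while repetitions share a profile
but not a noise realization.

## Preprocessing

All kinematic channels pass a **fourth-order low-pass Butterworth filter at
20 Hz**, applied as a second-order design run forward and backward
(`signal::filtfilt`), so the net filter has fourth order and exactly zero
phase — event timing is what segmentation lives on. Odd-reflection padding
(60 samples) suppresses the start/end transients of the forward–backward
pass. The same filter is applied to the coach channel before sign
detection.

A **transition** is declared at the first sample of a sign change of the
filtered coach channel that persists for at least 30 samples (0.5 s at
60 Hz); the debounce rejects noise-induced flickers near the flip. The
ordered transitions plus the protocol's condition order form the reference
sequence, and every sample takes the label of its half-open span
`[start, next_start)`. Indices are 1-based throughout, and a transition
index is the first sample of the new condition.

## Stride segmentation

Heel strikes are detected per side from the shank sagittal angular
velocity: mid-swing candidates are prominent positive peaks (at least 40%
of the channel maximum, minimum spacing 0.4 × the median inter-peak
interval of a first pass), and the heel strike is the negative minimum
within the following 0.9 cycle — a bounded search window keeps the rule
robust to noise wiggles on the descending slope. A stride is the half-open
interval between consecutive heel strikes of the same foot; strides whose
samples span more than one condition label are discarded.

Per side and condition, the first and last 3 strides are trimmed
(adaptation to the announced condition), then all conditions are truncated
to the minimum remaining count. Truncation keeps the **earliest** strides
— a deterministic choice preferred over random subsampling for
reproducibility. Trimming is applied per side within condition (the
protocol leaves this open). The midline pelvis has no own foot; its cycles
are bounded by the left-foot heel strikes (an arbitrary but fixed
convention). Every stride is finally resampled to 100 samples per channel
by linear interpolation, preserving endpoints.

## Features

Seven features per channel per stride, in fixed order: mean, standard
deviation, maximum, minimum, and three autocorrelation features. The
autocorrelation is the *biased* sample autocovariance of the mean-removed
channel, $r(\tau) = \frac{1}{N}\sum_t (x_t-\bar x)(x_{t+\tau}-\bar x)$.
The feature list names only "main peak" and "second peak", so the package
fixes a convention and documents it prominently:

* **main peak** = $r(0)$, the signal power after mean removal (without mean
  removal the DC term would dominate and duplicate the mean feature);
* **second peak** = the largest local maximum of $r$ at lag ≥ 1 occurring
  after the first zero crossing of $r$; its height and its lag (in
  normalized samples, 0-based) are the remaining two features. Zero-variance
  channels report (0, 0, 0).

This convention makes the main-peak feature informative and lets the second
peak capture within-stride periodicity; it is flagged as a
sensitivity-relevant choice. Datasets are assembled per body segment ×
signal combination: accelerations only (21 features), angular velocities
only (21), or both (42); bilateral segments pool left and right strides as
rows. Twelve datasets per athlete-repetition result. No feature scaling
happens at this stage — standardization is a classifier concern.

## The classifier bank

Nine configurations behind one train/predict contract
(`classifier_spec()`, `train_classifier()`):

| name | family | settings |
|------|--------|----------|
| DTf | decision tree | Gini splits, ≤ 100 splits, no surrogates |
| SVMl/SVMq/SVMc | SVM | polynomial kernel degree 1/2/3, box constraint 1, kernel scale 1, one-vs-one |
| kNNf | kNN | Euclidean, k = 1 |
| kNNco | kNN | cosine distance, k = 10 |
| kNNcu | kNN | Minkowski q = 3, k = 10 |
| kNNw | kNN | Euclidean, k = 10, votes ∝ 1/d² |
| ANN | neural net | 3 hidden layers × 10 tanh units, softmax/cross-entropy, conjugate-gradient, ≤ 1000 iterations |

Design decisions worth spelling out:

* **Standardization.** Features are z-scored with training-fold statistics
  and the same transform is applied to the test fold. Distance- and
  margin-based classifiers need comparable scales; the flag is stored in
  the spec and can be toggled.
* **Cosine distance.** The textbook cosine expression is a *similarity*;
  the kNN uses `1 − similarity` so that identical directions give distance
  0.
* **Weighted kNN.** "Squared inverse" weighting is interpreted as *vote*
  weighting (neighbour votes ∝ 1/d² with Euclidean d), not per-feature
  weighting; a per-feature weighted Euclidean distance is nevertheless
  available in `pairwise_distance()`.
* **Ties** in kNN voting go to the smallest class index (regular < LC <
  KB), deterministically.
* **SVMs** are `e1071::svm` (libsvm) with kernel $(x^\top y + 1)^d$, cost
  1, `scale = FALSE` (standardization already applied); one-vs-one is
  libsvm's native multiclass scheme.
* **ANN.** Three hidden layers with 10 units each (widths are not dictated
  by anything — 10 is a configurable default), trained by conjugate
  gradient (`optim(method = "CG")`) on the cross-entropy objective with
  analytic backpropagation gradients, at most 1000 iterations, weights
  initialized from the spec seed. Conjugate gradient is the closest
  in-package routine to scaled conjugate gradient; both are
  Hessian-free conjugate-direction methods and the choice is a deliberate
  simplification.
* **Decision tree.** `rpart` with Gini impurity and surrogates disabled;
  rpart has no direct split cap, so the tree is grown with `cp = 0` and
  post-pruned to the largest complexity value with ≤ 100 splits.

Evaluation is a two-fold session cross-validation: train on repetition 1,
test on repetition 2, and vice versa; the two 3×3 confusion matrices are
averaged elementwise. The full bank is 4 segments × 3 combinations × 9
classifiers = 108 result records per athlete, named
`<classifier><combo><segment>` (e.g. `SVMqaSH` = quadratic SVM, shank
accelerations).

## Aggregation, funnel, goodness index

Per confusion matrix: overall accuracy A = trace/total; one-vs-rest recall
R, precision P and F1 per class; overall P and F1 are unweighted class
means. With balanced classes mean(R) = A exactly. A class never predicted
has undefined precision; it is reported as 0 **with a warning**, which
makes funnel rejection conservative. Metrics are averaged across athletes
(mean and sample SD).

The **selection funnel** applies four criteria in order, each at 0.80:
mean A; min per-class mean R; mean overall P; min per-class mean P.
Comparisons use means **rounded to two decimals**, the precision at which
cohort tables are reported — a 0.795 passes, mirroring how printed 0.80
cells pass. Survivor sets are nested by construction.

For survivors, the per-athlete confusion matrices are pooled and collapsed
to 2×2 by merging LC and KB into "irregular": confusions between the two
faults land on the diagonal, so binary accuracy can never be below the
3-class accuracy. The **goodness index** is the ROC-space distance to the
perfect classifier, computed over *rates*:
$G = \sqrt{(1-TP)^2 + (1-TN)^2}$ with TP the true-positive (irregular)
rate and TN the true-negative (regular) rate. G is bounded by $\sqrt 2$
(a wider 0–2 range is sometimes stated, but the formula cannot exceed
$\sqrt 2$; the package follows the formula). Chance (TP = TN = 0.5) gives
$\sqrt{0.5} \approx 0.707$, conventionally reported as 0.70; categories are
optimum (≤ 0.25), good (≤ 0.70), bad (> 0.70). The positive class is the
fault ("irregular") because fault detection is the purpose; the chance
value is invariant to that choice. Post-funnel statistical comparison of
survivor F1 scores (repeated-measures ANOVA with Bonferroni corrections,
Shapiro–Wilk normality checks) is standard hypothesis testing, deliberately
delegated to base R (`aov`, `pairwise.t.test`, `shapiro.test`) by the user
and not wrapped by the package, which reports the descriptive tables.

## Reference benchmark tables

`published_metrics()` loads the cohort-level benchmark tables of the
original eight-athlete experiment (mean/SD accuracy for all 108
combinations, recall for the 30 accuracy survivors, precision for the 14
recall survivors) in the exact schema `selection_funnel()` consumes.
Feeding them through the funnel reproduces the reference selection exactly:
30 stage-1 survivors (15 acceleration-only), 14 stage-2 survivors (6
shank, 8 feet), and 7 final survivors, all SVM-based, with `SVMqaSH` the
top performer. One reference table carries an internal inconsistency about
whether the seventh survivor is the cubic-kernel feet model fed with
accelerations or with both signals; the package follows the printed
precision values, which select the acceleration-fed model.

## Problem sizes and numerical choices in the tests

Unit tests run a 2-athlete × 2-repetition × 30-stride cohort; the
synthetic-recovery checks run the full study-scale cohort (8 × 2 × 120,
`delta = 1`, and a `delta = 0` control) with the quadratic SVM on shank
accelerations; the 108-record structural check runs one athlete at 20
strides per condition. These sizes are the package's own trade-off between
coverage and a test suite that runs in minutes. Tolerances: heel strikes
count as recovered within ±3 samples (50 ms at 60 Hz); transitions within
±5; autocorrelation agrees with a brute-force oracle to 1e-10; metric
computations are exact integer arithmetic against a counting oracle.

## Command line

A thin wrapper is installed at `exec/racewalk` with subcommands `simulate`,
`run-all` and `funnel` over the exported functions; the remaining pipeline
stages are the exported stage functions themselves
(`preprocess_session()`, `segment_session()`, `build_datasets()`,
`run_bank()`), composed by `run_pipeline()`.

## Known limitations

* The generator's fault signatures are idealized and additive; real faults
  change coordination patterns nonlinearly, and real inter-athlete
  variability is richer than a multiplicative gain.
* Heel-strike detection assumes the generator's template guarantee (one
  dominant positive peak per cycle); on real shank gyro data the
  mid-swing/heel-strike scheme is standard but needs parameter care.
* Classifiers emit hard labels only; there is no ROC curve over
  thresholds, and no cross-athlete (pooled) training.
* The ANN optimizer is plain conjugate gradient, not scaled conjugate
  gradient; at these problem sizes the difference is speed, not
  expressiveness.
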