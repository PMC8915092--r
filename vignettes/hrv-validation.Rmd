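---
title: "Validating time-domain HRV from gappy wrist heart-rate series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating time-domain HRV from gappy wrist heart-rate series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wrist-worn devices estimate heart rate optically (photoplethysmography,
PPG). Relative to a chest-strap ECG-grade reference, the exported
instantaneous heart-rate (IHR) series is biased, noisy, interrupted by
dropouts, and occasionally corrupted by ectopic-beat-like events. Yet
clinically interesting quantities — the time-domain heart-rate-variability
(HRV) indices SDNN, RMSSD, pNN50, SDNN index and SDANN — are usually
defined on clean beat-to-beat (RR) interval series. `wristhrv` implements
and validates a full correction chain:

1. **resample + impute** the gappy wrist IHR onto a uniform grid and fill
   the gaps (eleven classical methods, benchmarked by masked-slot RMSE);
2. **map** wrist HR toward the reference device with a learned regression
   (eight model families under cross-validated grid search);
3. **reconstruct** a pseudo inter-beat-interval (IBI) series as
   IBI\[ms\] = 60000 / HR\[bpm\], one interval per sample;
4. **correct artifacts** with one of the Malik / Karlsson / Kamath / Acar
   rejection rules, replacing flagged intervals by a cubic spline;
5. **summarise** the time-domain indices and **validate** them against the
   reference with paired t-tests.

Because no public paired wrist/chest dataset accompanies this design, the
package ships a seeded synthetic cohort generator with known ground truth;
every stage is tested against it.

## The pseudo-IBI convention

The IHR-to-interval relation is sometimes printed as HR = 6000/IBI, which
is dimensionally consistent only for centiseconds. The package uses
milliseconds throughout (constant 60000, configurable in `hr_to_ibi()`).
Note the pseudo-IBI series inherits the device's uniform sampling grid: it
is *not* a beat-detection series, and pNN50 computed on it is a convention
of this pipeline family rather than a beat-accurate quantity. All indices
use the sample (n − 1) standard deviation, matching common HRV tooling.

## Imputation

Gaps are explicit `NA` slots on a uniform grid (`resample_uniform()`), so
every method sees a regular index. Conventions the methods need but that
their one-line definitions leave open:

* **ewma** fills a slot with the exponentially weighted mean of *prior*
  observations only (span 5 slots by default) — a forward pass, like the
  failure mode it emulates (a device that can only look backwards).
* **knn_mean** defines neighbours on the time index (the k nearest
  observed slots by |Δt|); `select_k_for_knn()` picks k by masked-slot
  RMSE, ties to the smallest k.
* **spline2** fits a local quadratic through the three nearest anchors
  (the "low-degree polynomial on a small subset" reading); **spline3** is
  the global cubic interpolating spline; **pchip** and **akima** come from
  `pracma`.
* a leading gap cannot be forward-filled and a trailing gap cannot be
  backward-filled; such residual slots fall back to nearest-neighbour so
  the output is always complete, which the downstream stages require.

`inject_missingness()` removes exactly `round(fraction × n)` slots as runs
with geometric lengths (mean 3 slots by default), placed with a one-slot
buffer so that independently drawn runs do not merge and the realised
run-length distribution stays geometric; the first and last slots are
never removed so every interpolant keeps its anchors. The benchmark scores
each method only on the masked slots — untouched observations cannot
dilute the RMSE.

Stationarity is diagnosed with an Augmented Dickey–Fuller test
(`adf_stationarity()`): constant-only regression, AIC-selected lag order,
p-values interpolated from the finite-sample tau distribution for that
regression, clipped to [0.01, 0.99]. The implementation is in-package and
was checked against an independent reference implementation on white-noise
and random-walk fixtures. One honest caveat: with the generator's default
slow drift of 2 bpm per recording the simulated series are usually still
*stationary* at 5% — the drift a 15-minute seated rest plausibly shows is
too small for a unit-root test to notice. Real multi-hour wrist exports
are another matter; the test is provided as a diagnostic, not as a claimed
property of the generator.

## The mapping stage

Paired samples (`align_pair()`) are split per subject into a chronological
75% training prefix and 25% test suffix. Stratifying by subject keeps
every subject in both splits; making the split *chronological* (rather
than random rows) leaves each subject with a contiguous test segment, so
HRV can still be computed per individual downstream, and avoids the
optimistic bias of interleaving train and test samples of a slowly
varying signal.

Tuning is exhaustive grid search under 5-fold cross-validation on the
training rows, scored by negated MSE (larger is better); ties go to the
first grid point in declared order. Default grids: kNN k ∈ {3,5,7,11},
tree depth ∈ {3,5,10,none}, forest size ∈ {50,100,200}, AdaBoost
estimators ∈ {25,50,100}, net hidden units ∈ {4,8}; linear regression has
nothing to tune and reports only its CV score. CV folds are plain random
partitions of the training rows; grouped (per-subject) folds would be the
stricter choice for cross-subject generalisation claims, which this
package does not make.

Model-family conventions:

* **multinomial logistic** treats integer-rounded bpm values of the target
  as categories (via `nnet::multinom`); predictions are the predicted
  category as a number, so they are always values seen in training.
* **AdaBoost** is AdaBoost.R2 with the linear loss over shallow `rpart`
  trees and weighted-median prediction, implemented in-package.
* **rnn / lstm** are implemented in-package as plain-R matrix BPTT:
  a single tanh recurrent layer (RNN) and an LSTM layer followed by two
  sigmoid dense layers with inverted dropout 0.2 (LSTM). Both consume
  sliding windows of the wrist series (length 10, stride 1, built within
  each subject, left-padded with the subject's first value) and are
  trained 15 epochs at batch size 64 with Adam at learning rate 0.1; the
  quoted "momentum 0.5" is read as Adam's first-moment decay β₁ = 0.5,
  since Adam has no classical momentum term. Targets are min–max
  normalized to [0, 1] to match the sigmoid output head and
  inverse-mapped before RMSE is computed, so the report is in bpm.
  Because windows overlap, random CV folds on rows imply some input
  overlap between folds for the nets; this is accepted and noted rather
  than hidden.

Final ranking is by test RMSE in bpm on the held-out rows only.

## Artifact rules and rule selection

All four rules are relative-deviation tests. Malik (20%) and Kamath
(+32.5% / −24.5%, asymmetric) compare each interval against the *last
accepted* interval rather than the raw previous one, so a burst of
ectopics is flagged in full instead of re-anchoring on an artifact; Acar
compares against the mean of up to the last nine accepted intervals (the
window shrinks near the start); Karlsson tests interior intervals against
the mean of their raw previous-and-next neighbours and therefore never
flags the first or last interval. Whether reference implementations anchor
on raw or accepted intervals is genuinely underdetermined; the
accepted-interval convention is the package's documented, configurable
choice (`artifact_rule_config()`).

Flagged intervals are replaced by a cubic spline through the accepted
intervals — the replacement used by standard HRV preprocessing software —
and at least four accepted intervals are required to anchor it.
`select_correction_rule()` scores each rule by R² — the *squared Pearson
correlation*, not 1 − SSE/SST — between per-subject corrected indices and
reference indices, averaged over metrics, with ties broken in the order
malik, karlsson, kamath, acar.

## HRV summary conventions

* pNN50 uses strict `> 50 ms` and denominator n − 1.
* SDANN / SDNN index segments are non-overlapping 5-minute windows by
  cumulative elapsed time (an interval belongs to the segment its start
  falls in); a trailing partial segment is dropped because short-segment
  statistics are unstable, and with fewer than two complete segments both
  indices are `NA` (serialised as JSON `null`).
* Scale equivariance holds for the ms-denominated indices (and for the
  segmented ones once the segment length is scaled with the units); pNN50
  is intentionally *not* scale-invariant — its 50 ms threshold is
  absolute.

## The synthetic cohort

`simulate_reference()` generates HR(t) = baseline + A·sin(2πt/T) + trend
+ AR(1) noise: a respiratory-sinus-arrhythmia-like oscillation (A 2–6
bpm, T 8–15 s across subjects), a slow linear drift (2 bpm per recording)
and autocorrelated noise (AR coefficient 0.7–0.9, innovation SD 0.5–1.5
bpm). Cohort defaults — 10 subjects, 900 s recordings at 1 s, baselines
60–90 bpm — emulate a seated-rest protocol in older adults.
`degrade_to_wrist()` then applies bias, Gaussian measurement noise,
clustered dropouts and ectopic events (one interval shortened by a
fraction, the next lengthened compensatorily — the premature-beat
signature the rejection rules target). With a null degradation the wrist
series equals the reference bit-for-bit, which is what makes exact
ground-truth recovery testable.

What the generator does **not** emulate: PPG waveform morphology, motion
artifact spectra, heteroscedastic noise tied to activity, device-specific
filtering, or true beat-timing jitter. Passing tests therefore demonstrate
the *software chain* is correct and well-calibrated under the stated error
model; they are not evidence about any specific commercial device.

## The identity path and the mapping default

The pipeline's exactness check runs with the mapping stage disabled
(`mapping_model = "none"`): with null degradation there is nothing to
correct, and a trained regression model cannot (and should not) reproduce
its input to 1e-9. When a degradation is configured, the default mapping
family is the LSTM, with the correction model trained on each run's own
training split and applied to the full series before IBI reconstruction.

## Problem sizes and numerical choices

The test suite and the acceptance script use 10-subject, 900-slot cohorts
for end-to-end checks, a 900-slot sinusoidal series (baseline 70 bpm,
amplitude 5 bpm, period 12 s, 10% missing) for the imputation benchmark,
1000 random interval series against brute-force metric oracles (agreement
demanded to 1e-9), and 2000 null replicates for the paired-t type-I
calibration (expected rejection rate 0.05 ± 0.02). All randomness flows
from explicit seeds; reruns with the same configuration are bit-identical
and the pipeline manifest records a checksum of the numeric outputs.

Paired comparisons report two-tailed p-values alongside *one-tailed*
t-table critical values (1.833 at 95% and 2.821 at 99% for df = 9): the
two conventions coexist in practice and the package exposes both, but the
accept/reject decision is always taken from the p-value. A non-significant
paired t-test is reported as "no difference"; as an agreement argument
this is weak by design (absence of evidence), and Bland–Altman limits or
TOST equivalence testing would be the stronger tools — they are outside
this package's scope.

## Known limitations

* The pseudo-IBI series is sampling-grid-based; indices sensitive to true
  beat timing (especially pNN50) are conventions of this pipeline family.
* CV folds are not subject-grouped by default (configurable upstream of
  this package's scope).
* The RNN at learning rate 0.1 is occasionally unstable on hard tasks —
  it is kept at the stated settings rather than silently retuned, and its
  per-epoch losses are exposed for inspection.
* R² rule selection needs at least 3 subjects to be meaningful; fewer
  produce a warning and an unstable ranking.
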