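---
title: "Estimating energy expenditure from wrist accelerometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating energy expenditure from wrist accelerometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristmets)
```

wristmets estimates the metabolic cost of walking and running — in METs,
multiples of resting oxygen uptake — from a raw tri-axial accelerometer worn
on the wrist. This vignette explains the signal model, the predictors, every
tunable that matters, and the reasoning behind the design choices that the
method descriptions leave open. It states no empirical claim that the test
suite and the acceptance script do not themselves recompute.

## The signal path

A wrist device logs acceleration in g at a nominal 100 Hz on three axes. The
pipeline reduces this to a single working signal in three fixed steps:

1. **Kalman smoothing** (`kalman_smooth()`). Each axis is filtered by a
   scalar local-level (random-walk) Kalman filter. The filter has two noise
   variances; neither is dictated by the method description, so we declare
   defaults: process variance $q = 10^{-4}\,\mathrm{g^2}$ per step and
   measurement variance $r = 10^{-2}\,\mathrm{g^2}$. At 100 Hz these give a
   steady-state gain near 0.1 — strong enough to damp sensor noise, gentle
   enough to keep the 1–3 Hz arm-swing oscillation (attenuated, not
   removed). The state is initialised at the first observation so signals
   with a gravity baseline start unbiased. Both variances are overridable
   through `kalman_params()`.

2. **Gravity detrending** (`remove_gravity_trend()`). Gravity projects a
   slowly varying offset onto each axis. We subtract a *trailing* 5-second
   rolling mean, inclusive of the current sample, with an expanding mean
   during the first 5 s. The trailing (causal) reading keeps the output the
   same length as the input and drops no samples; a constant input maps to
   exactly zero. The window length is a parameter (`trend_window_s`,
   seconds).

3. **Vector magnitude** (`vector_magnitude()`).
   $VM = \sqrt{a_x^2 + a_y^2 + a_z^2}$, computed after the two per-axis
   steps. The order — smooth, detrend, then combine — is fixed; VM is
   invariant to axis permutation and sign flips, which the tests assert on
   random streams.

Timing is validated, not repaired: sample intervals may jitter up to 10% of
the nominal interval, and larger gaps are an error. Imputation would
silently manufacture signal, which is the wrong default for a measurement
pipeline.

## Windows and features

The VM series is cut into consecutive, non-overlapping windows of 10, 30 or
60 s (`segment_windows()`); 60 s is the default, the window at which the
Mean–METs correlation is strongest and the network error smallest among the
three. Windows never span two treadmill bouts, and a trailing partial
window is discarded. Overlapping windows would manufacture correlated
training rows; the per-minute summary convention of actigraphy argues for
non-overlap.

Two summaries are taken per window:

* **Mean** — the arithmetic mean of VM in the window, in g. This is the
  sole predictor of the closed-form regressions and the score thresholded
  by the walk/run cut-point. It is computed from the *preprocessed*
  (smoothed, detrended) VM.
* **The nine-feature vector** — mean, SD, max, min and the
  10/25/50/75/90th percentiles of VM, the network inputs. These are
  computed from the *raw* VM (magnitude of the unfiltered axes), which
  retains the gravity level and noise texture that the percentile spread
  encodes. The two sources share one code path and the choice is explicit
  at the call site.

Percentiles interpolate linearly between order statistics
($h = (n-1)p + 1$; `stats::quantile()` type 7) and SD uses the $n-1$
denominator. Neither convention is fixed by the method description; we
declare these for reproducibility and test them against a hand-written
sort-based oracle.

Network inputs are min–max normalized, $x_{std} = (x - x_{min}) /
(x_{max} - x_{min})$, with bounds fitted on training rows only and frozen
(`fit_normalizer()` / `apply_normalizer()`). Validation values outside the
training range are *not* clipped — they map outside $[0,1]$ and warn —
because clipping would silently truncate exactly the extrapolation cases a
user should see. A constant training feature maps to 0.

## The predictors

**Closed-form regressions** (`ee_model()`, `fit_ee_regression()`). Three
reference equations with published coefficients ship frozen
(`ee_reference_model()`):

$$\mathrm{METs} = 8.33\,\mathrm{Mean} + 3.36$$
$$\mathrm{METs} = 2.56\,\ln(\mathrm{Mean}) + 10.04$$
$$\mathrm{METs} = 29.65\,\mathrm{Mean}^3 - 52.67\,\mathrm{Mean}^2 +
33.46\,\mathrm{Mean} + 1.22$$

Refitting uses pooled ordinary least squares (windows from all subjects
pooled; repeated measures are not modelled, matching how the reference
coefficients were obtained), with $R^2 = 1 - SSE/SST$ and standard error of
estimate $\sqrt{SSE/(n-p)}$. The logarithm is natural. Predictions are
never clamped to a physiological range: the cubic rises again beyond the
inflection of its second derivative at $-c_2/(3c_3) \approx 0.59$
(`cubic_inflection()`), and surfacing that diagnostic beats hiding it.

**The network** (`train_ann()`). One sigmoid hidden layer, linear output,
trained by full-batch gradient descent on
$\frac{1}{n}\sum e_i^2 + \frac{\lambda}{n}\sum w^2$ — the conventional
"weight attenuation" penalty of small single-hidden-layer regressors
(biases unpenalized). Choices the method description leaves open, declared
here:

* activation: logistic sigmoid (bounded inputs, small net — the standard
  choice);
* initialization: uniform $(-0.5, 0.5)$ scaled by $1/\sqrt{\text{fan-in}}$,
  seeded; training is bit-reproducible given data, config and seed;
* step size: starts at 0.05, halves until a step no longer increases the
  penalized loss and grows 10% after every accepted step — deterministic,
  and it makes the loss trace provably non-increasing;
* stopping: 2000 iterations (the convergence point of the reference
  models) or a loss improvement below `tol`.

Analytic gradients are verified against central finite differences in the
tests. `tune_ann()` grid-searches decay (0.1–0.9) by hidden-layer size
(1–30) with k-fold cross-validated RMSE, ties broken toward fewer neurons
then larger decay; tuning never touches the validation split. Because the
exact optimizer, activation and initialization behind the published error
figures are unknown, those figures are approximable, not bit-reproducible.
The canonical input is the nine-feature vector, but any input dimension is
accepted — the coefficient-recovery tests train on a single feature.

**The two-stage model** (`train_two_stage()`). Walking and running follow
different Mean–METs relationships, so the composite model first classifies
each window by its Mean and then applies a gait-specific network (walking:
9 hidden neurons, decay 0.8; running: 4 and 0.7). The cut-point comes from
ROC analysis (`roc_analysis()`): candidate thresholds are midpoints between
consecutive sorted unique Means plus infinite sentinels, sensitivity and
false-positive rate are exceedance probabilities, and AUC is the trapezoidal
integral — identical to the Mann–Whitney statistic with ties counted one
half, which the tests verify pairwise. The Youden index $J = tpr - fpr$
picks the threshold (`youden_cutoff()`); with separable classes the
midpoint grid makes the maximizer unique and equal to the midpoint of the
separating gap — the maximum-margin cut, the form consistent with a
reported cut-point of 0.23375 at AUC 1. Among tied maxima the largest
threshold is returned (favouring specificity). Classification is strict
(`Mean > threshold` is running); the boundary value itself is walking.

## Evaluation

`evaluate_predictions()` reports RMSE, Bias, a Bland–Altman analysis and
per-gait/per-speed breakdowns. Two Bias conventions circulate: the printed
formula is relative ($\frac{1}{N}\sum (pred - meas)/meas$), while error
tables are often quoted in METs. Both are implemented; `relative` is the
default because the formula wins over the unit annotation, and every report
labels its mode. Per-speed rows carry the SD of the per-window bias terms,
labelled as an SD. Bland–Altman limits use the fixed 1.96 normal quantile
(not a small-sample t), points exactly on a limit count as inside, and the
window — not the subject — is the unit of analysis. The per-speed table
pools exactly: the count-weighted mean of squared per-speed RMSEs equals
the overall squared RMSE, asserted to $10^{-12}$.

## What the synthetic cohort emulates — and what it does not

`generate_dataset()` builds a 100-subject cohort on the 8-speed treadmill
protocol (walk 2–6 km/h, run 7–9 km/h, 4-minute bouts at 100 Hz), split
70/30 into modeling and validation groups *by subject* — never by window.
Each axis is a constant gravity projection (a random wrist orientation held
for the whole protocol) plus an arm-swing sinusoid plus Gaussian sensor
noise (sd 0.02 g). Declared parameter choices:

* step frequency $f(v) = 0.8 + 0.25 v$ Hz — walking cadence ~1.3–2.3 Hz,
  running ~2.5–3.1 Hz;
* per-axis amplitude $A(v) = s \cdot 0.03 v$ g walking, $s \cdot 0.05 v$ g
  running, with the subject factor $s \sim U(0.85, 1.2)$. The walk/run
  amplitude jump mirrors the qualitative discontinuity in wrist motion
  between gaits and keeps the pooled walking and running Mean
  distributions separated — the regime in which the published cut-point
  analysis operates (AUC = 1). The narrow $s$ range is what guarantees
  this across subjects;
* the three axes share one random phase offset 120° apart, so the sum of
  squared sinusoids is exactly 3/2 and the VM envelope is constant — the
  window Mean then reflects amplitude, not phase luck;
* ground-truth METs follow ACSM-style walking/running oxygen-cost curves
  ($(0.1 v + 3.5)/3.5$ and $(0.2 v + 3.5)/3.5$ METs at $v$ m/min), a
  subject offset $\sim N(0, 0.3^2)$ METs, and per-window measurement noise
  $\sim N(0, 0.4^2)$ METs — spanning roughly 2–11 METs across the
  protocol, with model RMSEs landing in the 0.4–1.4 METs range typical of
  wrist devices.

Everything derives from one master seed: per-subject seeds are drawn once
from it, so datasets are reproducible and subjects independent.

The generator does **not** emulate biomechanically realistic gait
waveforms, device-specific noise spectra, rest periods between bouts, or
free-living movement. Consequently, a perfect AUC and 100% held-out gait
accuracy on synthetic data demonstrate that the ROC/Youden machinery and
the pipeline around it are correct *in the separable regime the treadmill
protocol produces* — they are not evidence about messy free-living wrists,
where the Mean distributions overlap and no cut-point is perfect.

## Problem sizes and numerical tolerances

The test suite exercises the full 100-subject cohort once (about half a
minute) and otherwise uses a 6-subject cohort; exact identities (metric
oracles, AUC–Mann–Whitney equivalence, normalizer inversion, Kalman vs the
literal recursion) are asserted at $10^{-12}$, gradient checks at $10^{-6}$
relative, and stochastic checks (Bland–Altman coverage at $n = 10{,}000$,
slope recovery at $n = 560$) at the tolerances their sampling noise
implies. `scripts/acceptance.R` regenerates the default cohort from
scratch at whatever seed it is given.

## Known limitations

* Pooled OLS ignores within-subject correlation; coefficient standard
  errors on repeated-measures data are optimistic.
* The network optimizer is plain gradient descent; it is deterministic and
  sufficient at these problem sizes but slower than quasi-Newton methods
  for large feature tables.
* The cut-point value itself is data-dependent: on synthetic cohorts only
  its properties (AUC 1, perfect held-out accuracy, gap-midpoint location)
  are reproducible, not the numeric threshold obtained on any particular
  human cohort.
* Rest/sedentary windows and activity types beyond treadmill walking and
  running are out of scope.
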