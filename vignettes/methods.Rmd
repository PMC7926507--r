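---
title: "Methods: accelerometry features, model selection, and the synthetic protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometry features, model selection, and the synthetic protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelchairEE)
```

## The estimation problem

Manual wheelchair users expend energy almost exclusively through the
upper limbs, so the standard consumer and research equations that map
hip- or wrist-worn accelerometry to energy expenditure in ambulatory
populations do not transfer. The pipeline in this package estimates
active energy expenditure — expressed as weight-normalized oxygen
uptake, VO₂ in mL·kg⁻¹·min⁻¹ — from a single triaxial accelerometer
worn on the upper arm, using per-minute signal statistics as predictors
in multiple linear regression.

The units and conventions are fixed throughout: acceleration in g with
gravity *included* (no high-pass filtering anywhere — the per-minute
dispersion statistics are location-free, and the percentile statistics
deliberately retain orientation information); time in seconds relative
to the session start; VO₂ per minute as the arithmetic mean of all
measurements in the half-open window interval, with no interpolation.

## Windowing

Windows are *annotation-anchored*: for each annotated activity,
consecutive non-overlapping 60-s windows start at the activity's start,
and a trailing partial window is discarded. Rest periods between
activities are never windowed. This matches a protocol in which each
activity is performed for a multiple of one minute and per-task errors
are reported; session-anchored windows would straddle rests and blur
task boundaries. A window with no VO₂ measurement in its interval is
dropped (with a warning) rather than interpolated.

Irregular sampling is tolerated: features operate on the recorded
sample sequence, and the reader only rejects a file whose median
inter-sample gap is inconsistent (±20%) with the declared rate. No
resampling is performed, and no re-synchronization beyond anchoring
both streams to the session start is attempted — the recordings are
assumed synchronously started.

## The 55 per-window variables

Thirteen statistics per channel (axes X, Y, Z, and the resultant vector
RV) plus three inter-axis correlations; `feature_names()` gives the
canonical order. Numerical conventions that the data do not dictate are
fixed as follows:

* **Dispersion** — sample (n−1) variance and standard deviation.
* **Percentiles** — linear interpolation between order statistics
  (`quantile()` type 7). With 3000 samples per window the convention is
  numerically negligible, but it must be pinned for reproducible
  outputs.
* **Lag-one autocorrelation (`DYN`)** — Pearson correlation of the
  window against itself shifted by one sample; the degenerate constant
  window returns 0 with a warning.
* **Wavelet norms (`ND1`, `ND2`, `NA2`)** — two-level discrete wavelet
  transform, Daubechies-2 mother wavelet, *periodized* boundary
  handling. Periodization keeps the filter bank orthonormal, so
  ND1² + ND2² + NA2² equals the window's energy exactly — an invariant
  the test suite asserts. Odd lengths are right-padded with the final
  sample before wrapping. For a constant signal c of length n the
  closed form NA2 = 2c√(n/4) serves as a second oracle.
* **Sample entropy (`SAMPEN`)** — SampEn(m = 2, r = 0.3·SD), Chebyshev
  (max-norm) template distance, self-matches excluded. The tolerance is
  proportional to the *window's own* SD (the plausible alternative —
  the SD of the whole recording — would make the statistic depend on
  context outside the window and break amplitude-scale invariance).
  Conventions for degenerate windows: a constant window returns 0; if
  no extended template matches (A = 0), the standard cap
  −ln(2/((n−m−1)(n−m))) is returned. The O(n²) template count is
  compiled C++; the test suite checks it against an independent pure-R
  double-loop counter.
* **Cross-correlations** — zero-lag Pearson correlation between axis
  pairs within the window (not a maximum over lags; "cross-correlation"
  is otherwise ambiguous).

Under rescaling of all channels by c > 0: SD, 75-25, ND1, ND2, NA2
scale by c, VAR by c², and DYN, XCORR, SAMPEN are invariant (SAMPEN
because r tracks SD). These scale laws are property-tested.

The 55 variables partition into 32 "linear" (dispersion + percentiles
per channel) and 23 "non-linear" (DYN, wavelet norms, SAMPEN per
channel, plus the three XCORR) variables, the three candidate sets of
the modelling stage being all/linear/non-linear.

## Model selection under cross-validation

`run_cv_experiment()` assigns windows to 10 folds at random (seeded;
fold sizes differ by at most one). Within each fold the training 90%
drives a greedy forward selection: at each step the candidate whose
inclusion minimizes training MSE is added, ties broken by canonical
feature-name order. Nested OLS fits guarantee the training MSE is
non-increasing in the number of predictors, which is asserted per fold.

Choices the procedure itself does not dictate, fixed here:

* **Selection criterion** — training MSE (equivalent to R² at each
  step).
* **Aggregation** — metrics are computed once on *pooled* predictions
  (all held-out predictions concatenated), not averaged per fold;
  pooling is less noisy at 100-window folds and treats every window
  equally.
* **Final model** — the 3-predictor set chosen most frequently across
  the 10 folds (ties by canonical order), refit on all windows. The
  default of three predictors reflects the inflection of the
  performance curve: beyond three, gains are marginal for every
  variable set.
* **Fold unit** — the window. Because windows of one participant are
  correlated, window-level folding leaks information between training
  and validation; `group_by_participant = TRUE` switches to
  participant-level folds for a stricter generalization estimate. The
  default mirrors the pooled-window experimental design the published
  equations come from.

Coefficient standard errors (σ̂²(XᵀX)⁻¹) are attached to every fit so
that recovery of a known generating equation can be judged in SE units.

Per-task errors are summarized as the relative normalized MSE,
100·MSE/mean(obs²), and the relative MAE, 100·MAE/mean(obs), per
activity label; these normalizations are declared conventions (the
quantities are elsewhere reported without a definition), so table
*layout* is reproduced but numeric agreement with external tables is
not claimed. Tasks with fewer than two validation windows are flagged,
not computed.

## The synthetic protocol generator

`generate_dataset()` emulates the study design the analysis assumes: 20
participants × 10 five-minute activities (3 sedentary, 4 housework, 3
locomotion), 60-s rests between activities, accelerometer at a nominal
50 Hz, VO₂ measurements every 5 s. Sample times are integer sample
indices divided by the rate, so a one-minute window holds exactly
60·rate samples.

The triaxial signal of an activity is built from components chosen so
that every feature family the pipeline computes has a driver that can
vary independently:

* a unit-norm, slowly drifting gravity orientation;
* an oscillation at the activity's cadence (0.25–1 Hz) along a
  dominant stroke direction biased toward the gravity axis, wobbling
  minute to minute;
* per-minute log-normal amplitude (vigor), waveform shape
  sign(sin)|sin|^q (impulsive for q > 1, sustained for q < 1), and
  duty cycle (bursts of movement separated by within-cycle pauses);
* motor "tremor" noise proportional to the minute's amplitude with a
  per-minute fraction, plus a small constant sensor floor (0.005 g)
  and a per-minute DC bias drift (0.02 g);
* occasional impact spikes (pushrim/caster bumps) of environmental —
  not vigor-graded — magnitude (0.15–0.5 g) in random directions.

These ingredients are not decorative. Duty cycle and shape move the
quantile-to-moment ratio of a window, so `75-25` is not a rescaled
`SD`; direction wobble separates per-axis from resultant-vector
statistics; the bias drift gives percentile *locations* variance that
dispersion features do not share; amplitude-proportional tremor keeps
the signal-to-noise ratio, and hence sample entropy, governed by
waveform rather than intensity; and spikes load moment statistics but
barely move quantiles. Without this variability the 55 features
collapse onto a one-dimensional "intensity" axis and any dispersion
statistic is an equally good predictor — forward selection would then
be a coin flip among proxies and parameter recovery meaningless.

Minute VO₂ is produced by applying a known generating equation — by
default the published all-variables model, so the packaged equations
and the generator are mutually consistent — to the features of that
minute's generated signal, adding Gaussian noise (default SD
1 mL·kg⁻¹·min⁻¹), flooring at 0, and emitting the value at the 5-s
cadence within the minute. The linear-model assumption therefore holds
*exactly*, which is what makes recovery of the generating predictors
and coefficients a meaningful end-to-end check. A
`quadratic_coeff` option adds a quadratic term in the first predictor
to probe robustness under deliberate misspecification. Per-participant
variation perturbs amplitudes (log-normal, SD 0.2) and body mass
(74.8 ± 18.05 kg, truncated at 40), and all randomness flows from one
master seed through per-participant sub-seeds.

What the generator does **not** emulate: biomechanically realistic
propulsion kinematics, metabolic lag/on-kinetics of VO₂ (the minute
value is coupled instantaneously to the minute's signal),
breath-by-breath gas-exchange noise structure, device clock drift, and
real between-feature correlation structure of human movement. Passing
the recovery tests therefore shows the *pipeline* is correct and the
experiment identifiable under its own assumptions — it does not certify
accuracy on real recordings, whose VO₂ is not an exact linear function
of any feature set.

## Problem sizes and runtime choices

Sample entropy is quadratic in window length, so the test suite and the
acceptance script run full-protocol simulations at 10 Hz (600-sample
minutes) — the replicated end-to-end recovery uses 20 replicates of 20
participants × 50 windows — while structural checks of the protocol
(window counts, 3000-sample minutes) run at the nominal 50 Hz. The
amplitudes were chosen once so that the generated VO₂ spans a
physiologically sensible range (roughly 3–15 mL·kg⁻¹·min⁻¹, sedentary
< housework < locomotion) with a between-window SD near
2.3 mL·kg⁻¹·min⁻¹ against the 1 mL·kg⁻¹·min⁻¹ observation noise.

## Known limitations

* Greedy forward selection is not guaranteed to find the best subset;
  with strongly collinear candidate features the selected set can vary
  between folds (the modal-set rule makes the final model
  deterministic, and the per-fold selections are retained for
  inspection).
* Window-level folding (the default) over-estimates out-of-sample
  performance on real multi-participant data; use
  `group_by_participant = TRUE` for deployment-oriented estimates.
* The published non-linear equation's large intercept (−343.09) means
  it is only sensible near the feature ranges it was fit on
  (`RV_DYN` ≈ 0.7, `Y_DYN` ≈ 0.7 for arm-movement signals at 50 Hz);
  extrapolating it to all-zero features is a worked identity, not a
  physiological prediction.
* The readers accept two delimited-text dialects (`time,gFx,gFy,gFz`
  and `t,ax,ay,az`); other exports must be converted upstream.
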