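# wheelchairEE

Estimating the active energy expenditure of full-time manual wheelchair
users from a single arm-worn triaxial accelerometer.

For wheelchair users with spinal cord injury, the usual step-count and
hip-worn activity-monitor equations do not apply: energy is spent by the
upper limbs. This package implements an accelerometry-to-oxygen-uptake
pipeline for that population. It is aimed at researchers in wearable
sensing and rehabilitation physiology who want to (a) apply published
arm-accelerometry prediction equations to their own recordings, or (b)
re-run the whole feature-engineering and model-selection experiment —
including on synthetic data with a known ground truth, so every stage is
testable without access to participant data.

## The method

A session pairs a triaxial acceleration log (nominal 50 Hz, units of g,
gravity included) with indirect-calorimetry oxygen uptake
(VO₂, mL·kg⁻¹·min⁻¹) and activity annotations. Each annotated activity
is cut into one-minute windows. Per window, 55 variables are computed
over the four channels *X*, *Y*, *Z* and the resultant vector
*RV* = √(x² + y² + z²):

* per channel (13): standard deviation `SD`, variance `VAR`, percentiles
  `P10`–`P90`, interquartile range `75-25`, lag-one autocorrelation
  `DYN`, the Euclidean norms `ND1`, `ND2`, `NA2` of the level-1/2
  detail and level-2 approximation coefficients of a Daubechies-2
  discrete wavelet transform (periodized), and the sample entropy
  `SAMPEN` (pattern length m = 2, tolerance r = 0.3·SD);
* between axes (3): zero-lag Pearson cross-correlations `XCORR_XY`,
  `XCORR_YZ`, `XCORR_XZ`.

VO₂ models are multiple linear regressions chosen by greedy forward
selection (training-MSE criterion) under 10-fold cross-validation, for
three candidate sets: all 55 variables, the 32 linear
(dispersion/percentile) variables, and the 23 non-linear variables. The
performance curve over 1–10 predictors is reported as pooled
correlation, mean squared error and mean absolute error; final models
use 3 predictors. The three published equations are packaged verbatim,
e.g. the all-variables model

    VO₂ = 3.4921 + 10.784·RV_75-25 − 25.4524·Y_VAR + 21.0447·Y_SD .

## Worked example

```r
library(wheelchairEE)

# simulate one participant's 10-activity protocol and segment it
s <- generate_session("P01", rate = 10, seed = 7)
w <- segment_minutes(s)
length(w)
#> [1] 50

# 55 variables for the first minute of "Lying down"
fv <- extract_features(w[[1]])
round(fv[c("Y_SD", "Y_VAR", "RV_75-25", "RV_DYN", "Y_SAMPEN")], 4)
#>     Y_SD    Y_VAR RV_75-25   RV_DYN Y_SAMPEN
#>   0.0289   0.0008   0.0163   0.6373   0.7115

# apply the published all-variables equation
predict(published_models()$all, fv)
#> [1] 4.253929

# the full experiment on a 20-participant synthetic dataset
ds  <- generate_dataset(20, seed = 7, rate = 10)
tab <- extract_feature_table(unlist(lapply(ds, segment_minutes),
                                    recursive = FALSE))
cv  <- run_cv_experiment(tab, variable_set = "all", seed = 7)
cv
#> <ee_cv_experiment [all]> 10 folds, seed 7
#>   final predictors: Y_SD, Y_VAR, RV_75-25
#>   pooled validation (k = 3): r = 0.903, MSE = 1.087, MAE = 0.828
```

The printed `fv` values are window statistics in g (dimensionless for
`DYN`/`SAMPEN`); the prediction and the error metrics are in
mL·kg⁻¹·min⁻¹ (MSE in its square). In the synthetic data the generating
equation is the published all-variables model, which is why the
experiment recovers `Y_SD`, `Y_VAR`, `RV_75-25`.

A file-based variant of the same flow (`simulate_dataset()` →
`run_pipeline()`, or `Rscript inst/scripts/run_pipeline.R --out results/`)
reads Physics-Toolbox-dialect CSV exports and writes feature tables,
model JSON files and an experiment report with embedded provenance.

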