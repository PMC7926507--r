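Package: wheelchairEE
Title: Energy Expenditure Estimation for Manual Wheelchair Users from
    Arm-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates active energy expenditure (oxygen uptake, VO2, in
    mL/kg/min) of manual wheelchair users from a single arm-worn triaxial
    accelerometer. Provides readers for accelerometer logs, gas-analyzer
    VO2 exports and activity annotations; a per-minute feature extractor
    computing 55 named variables (dispersion and percentile statistics,
    lag-one correlation, Daubechies-2 wavelet coefficient norms, sample
    entropy, and inter-axis cross-correlations); forward stepwise linear
    modelling under 10-fold cross-validation over three variable sets;
    the published predictive equations; and a synthetic-protocol
    generator emulating a 20-participant, 10-activity study design so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
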