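Package: cardiovar
Title: Beat-to-Beat Cardiovascular Analysis for Acute Exercise Crossover Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of beat-to-beat cardiovascular recordings from
    acute exercise crossover studies: artifact editing and cubic-spline
    resampling of RR tachograms, time-domain heart rate variability indices,
    wavelet (maximal-overlap Daubechies) low/high-frequency band powers with a
    Welch periodogram cross-check, spontaneous-sequence baroreflex sensitivity,
    foot-to-foot pulse wave velocity with carotid pressure calibration,
    indirect-calorimetry energy expenditure (Weir equation, steady-state
    detection, VO2peak adjudication), and the crossover mixed-model statistical
    stage (REML random-intercept models with Satterthwaite F-tests, omega- and
    partial-eta-squared effect sizes, Tukey post hocs). Ships synthetic signal
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
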