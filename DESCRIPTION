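Package: respicard
Title: Intermittent-Flow Respirometry and Cardiovascular Time-Series Analysis for Fish Cardiorespiratory Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combined intermittent-flow respirometry and
    pulsatile blood-flow recordings in fish, as used in salinity-acclimation and
    coronary-ligation experiments on rainbow trout. Converts raw air-saturation
    traces into quality-filtered oxygen-consumption rates with background
    correction; derives standard and maximum metabolic rate, aerobic scope and
    excess post-exercise oxygen consumption (EPOC) with activity smoothing and
    recovery-time rules; extracts cardiac output, heart rate and stroke volume
    from ventral-aortic flow traces with gravimetric probe calibration and beat
    detection (including atrioventricular-block bradycardia); computes biometric
    and haematological indices with anaemia exclusions; and analyses 2x2
    factorial (salinity x surgery) designs with Type II two-way ANOVA and
    Bonferroni-corrected simple main effects. A synthetic-study generator with
    known ground truth provides an oracle for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
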