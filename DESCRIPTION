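Package: rtstress
Title: Stress Quantification from Biosignals During Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying physiological stress in
    radiotherapy patients from photoplethysmogram (PPG) and breathing traces.
    Detects heartbeats from the second derivative of the PPG, computes the
    seven heart-rate-variability features commonly linked to acute stress
    (HR, SDNN, RMSSD, pNN50, HF, LF/HF, TP), converts before- versus
    during-treatment feature shifts into a directional stress score quantized
    to sevenths, trains baseline multi-label predictors of during-treatment
    shifts from waiting-room data with 10-fold cross-validation, and relates
    stress to breathing-cycle irregularity with a clustered
    repeated-measures (GEE) regression. Includes a synthetic cohort
    generator so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    sandwich,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
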