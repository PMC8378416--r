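Package: evtbenefit
Title: Ordinal Outcome and Treatment-Benefit Prediction for Endovascular
    Stroke Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits cumulative-logit (proportional-odds) models of the 90-day
    modified Rankin Scale after large-vessel-occlusion stroke, with
    endovascular-treatment interaction terms and an optionally nonlinear
    glucose effect; derives per-patient probabilities of functional
    independence and individualized treatment benefit; externally validates
    models (Harrell's C for binary and ordinal outcomes, calibration
    intercept and slope, bootstrap percentile confidence intervals);
    quantifies benefit prediction with matched-pair c-for-benefit and
    benefit-group calibration, including a reperfusion-surrogate contrast
    for single-arm registries; and generates synthetic trial and registry
    cohorts with configurable covariate laws, missingness and imputation so
    the whole derive-validate-update-revalidate workflow is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nnet
Suggests:
    testthat (>= 3.0.0),
    MASS,
    survival
Config/testthat/edition: 3
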