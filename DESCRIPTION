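Package: stabsize
Title: Sample Size for Precise and Fair Time-to-Event Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design-stage sample size assessment for clinical prediction
    models with time-to-event outcomes, targeting stable individual-level
    risk estimates rather than only population-level calibration. An
    assumed exponential proportional-hazards "core model" is specified
    directly or calibrated to a target concordance and overall risk;
    Fisher's information is decomposed into a unit information matrix and
    the sample size, giving closed-form per-individual variances of the
    linear predictor, 95% uncertainty intervals on the risk scale,
    misclassification probabilities against clinical risk thresholds, and
    the sample size required to meet interval-width targets. Includes
    follow-up simulation under declared censoring schemes, a synthetic
    cohort generator, subgroup (fairness) summaries, instability plots and
    a Newton-Raphson exponential regression fitter used for validation and
    post-fit intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
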