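Package: hypoalert
Title: Predictive Alerts for Sustained Hypoglycemia from Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects and classifies hypoglycemic events (transient versus
    sustained) in continuous glucose monitoring (CGM) traces on a 5-minute grid,
    predicts impending sustained hypoglycemia either by random-forest
    classification or by multistep quantile-regression-forest glucose
    forecasting with a consecutive-prediction inference rule, and evaluates
    predictive alerts with event-class-aware sensitivity, specificity and
    false-alert-rate metrics under patient-based and chronological (time-based)
    validation. Ships a synthetic multi-patient CGM cohort simulator with
    configurable hypoglycemia structure so the full pipeline is testable
    without patient data, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
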