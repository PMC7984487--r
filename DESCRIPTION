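Package: dvhqa
Title: Model-Independent Validation of Knowledge-Based DVH Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the accuracy of knowledge-based dose-volume histogram
    (DVH) predictions for organs at risk against a reference cohort of
    clinically accepted treatment plans. Computes dosewise prediction bias,
    error variation and RMSE with their quadrature relation, constructs
    competing prediction error bands (empirical RMSE, interquartile-range,
    median-split, and model-provided symmetric bands), and measures each
    band's empirical coverage (prediction success rate) as a function of dose
    with a clinical volume tolerance and boxcar smoothing. Includes a
    synthetic-cohort generator with known injected bias and spread so that
    every statistic and the closed-form coverage calibrations (68 percent for
    a one-sigma band, 50 percent for an IQR band) are testable without
    institutional data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
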