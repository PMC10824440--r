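Package: cidyn
Title: Dynamic Criticality Index Modeling for Pediatric Inpatient Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for dynamic prediction of future care location
    (intensive care versus routine ward) in hospitalized children. Generates
    seeded synthetic inpatient cohorts with a latent severity process,
    discretizes encounters into 6-hour periods with lookback features and
    leakage-free imputation, trains one calibrated neural-network classifier
    per prediction horizon (>6-12 h through >24-30 h) under an
    architecture-growth protocol guided by the Matthews correlation
    coefficient, recalibrates raw scores with a B-spline logistic map, and
    runs a full evaluation suite: discrimination with confidence intervals,
    fixed-sensitivity and fixed-specificity operating points, number needed
    to evaluate, a risk-interval calibration audit with Cohen's h, transfer
    cohort accuracy, and LIME-style local covariate-importance frequency
    comparison between model sets trained at different sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
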