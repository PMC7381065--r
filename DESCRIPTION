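Package: telecua
Title: Trial-Based Cost-Utility Analysis for Telerehabilitation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based cost-utility analysis of telerehabilitation
    versus clinic-based physiotherapy in chronic low back pain: two-proportion
    sample-size and attrition arithmetic, permuted-block allocation sequences,
    Oswestry Disability Index (ODI) scoring, linear ODI to SF-6D utility
    mapping, quality-adjusted life year (QALY) construction, protocol-driven
    resource costing with currency conversion, incremental cost-effectiveness
    ratios with dominance classification, nonparametric bootstrap
    cost-effectiveness planes with quadrant summaries and acceptability
    curves, and a calibrated synthetic cohort generator so every pipeline
    stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
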