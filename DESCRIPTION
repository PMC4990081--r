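Package: rxsafetrial
Title: Simulation and Analysis of Cluster Randomised Prescribing Safety Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing cluster randomised
    trials of prescribing-safety feedback in primary care. Implements six
    high-risk prescribing indicators and their patient-level composite on
    quarterly dispensing cross-sections; a synthetic dispensing-data generator
    with practice-level clustering calibrated to a target intraclass
    correlation; stratified cluster randomisation with a blinded group-to-arm
    step; design-effect power calculations for comparing two proportions with
    a simulation check; a random-intercept logistic regression fitted by
    adaptive Gauss-Hermite quadrature; and a binomial generalised estimating
    equations change-point (segmented) model with robust sandwich variances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
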