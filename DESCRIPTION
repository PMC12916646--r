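Package: pvsignal
Title: Disproportionality Signal Detection and Time-to-Onset Modelling for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for post-marketing pharmacovigilance analysis of
    spontaneous reporting system (SRS) data in the FAERS quarterly-file
    dialect: ingestion and case-version deduplication, primary-suspect
    cohort selection, 2x2 contingency tables at MedDRA Preferred Term and
    System Organ Class level, four disproportionality algorithms (reporting
    odds ratio, proportional reporting ratio with Pearson chi-square,
    Bayesian confidence propagation information component, and the
    DuMouchel gamma-Poisson shrinker with empirical Bayes geometric mean),
    multi-algorithm consensus classification, subgroup and co-medication
    sensitivity re-analysis, and parametric time-to-onset modelling
    (Weibull, log-logistic, log-normal) with AIC selection and hazard
    pattern labelling. Includes a synthetic spontaneous-report generator
    with known ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    flexsurv
Config/testthat/edition: 3
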