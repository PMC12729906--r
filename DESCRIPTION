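Package: aspcost
Title: Cost and Resource-Use Analysis for Antimicrobial Stewardship Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the monetary value of resource use between two
    phases of a hospital antimicrobial stewardship program (ASP). Implements
    eligibility filtering of patient episodes, antimicrobial consumption
    costing by defined daily dose (DDD), micro-costing of diagnostic and
    laboratory resources, rule-based cost avoidance (hospitalization bed-days,
    Clostridioides difficile infection treatment, readmission, and
    adverse-drug-event extra stay), annualized stewardship staffing cost,
    total and per-patient cost-benefit aggregation with currency handling,
    normality-gated two-sample and contingency comparisons of cohorts, and
    one-way and multivariate Monte Carlo sensitivity analysis with triangular
    input uncertainty and standardized-regression tornado ranking. A seeded
    synthetic-cohort generator reproduces the statistical structure of a
    two-period oncology ASP study so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
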