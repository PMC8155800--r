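Package: prepostCE
Title: Pre-Post Cost-Effectiveness and Cost-Utility Analysis for Severe
    Asthma Biologics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patient-level pre-post (one baseline year versus one
    treatment year) pharmacoeconomic pipeline for add-on biologic therapy
    in refractory eosinophilic asthma. Provides a calibrated synthetic
    cohort generator (Gaussian copula over negative-binomial, gamma and
    discretised truncated-normal marginals), direct-cost accounting
    against a euro unit-cost schedule, three effectiveness measures
    (exacerbations avoided, Asthma Control Test points, health-state
    utility), response classification per the Spanish severe-asthma
    consensus, incremental cost-effectiveness and cost-utility ratios with
    net monetary and net health benefit, percentile-bootstrap confidence
    intervals for ratio statistics, and first-order Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness planes and
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
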