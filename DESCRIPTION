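Package: qiprofile
Title: Between-Provider Variability and Reliability of Long-Term Care Quality Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Provider-profiling toolkit for nursing-home quality indicators.
    Computes six resident-level quality indicators (polypharmacy, self-reported
    and observed pain, trunk-fixation and bedrail restraints, weight loss) from
    resident records with the indicators' exclusion rules and listwise deletion,
    fits risk-adjusted random-intercept logistic models by adaptive
    Gauss-Hermite quadrature, and quantifies between-provider variability
    (latent-scale intraclass correlation ICC1, empirical-Bayes caterpillar
    profiles, rankability) and group-mean reliability (ICC2) with parametric
    bootstrap confidence intervals. Includes a synthetic resident-population
    generator with known facility-level variance for validation studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
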