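Package: triomr
Title: Assortative-Mating Simulation and Trio-Based Mendelian Randomization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of mother-father-offspring trios under
    configurable single-trait and cross-trait assortative mating, and
    instrumental-variable estimators of a causal exposure-outcome effect that
    use trio genotype data to detect and correct the bias assortment induces.
    Provides plain two-stage least squares with a weighted allele-score
    instrument, a variant adjusting for parental allele scores, and a variant
    instrumenting parental exposure phenotypes with nontransmitted allele
    scores; summary-data estimators (inverse-variance weighting, Egger
    regression, weighted median, mode-based estimate) and heterogeneity
    diagnostics; and a Monte-Carlo harness that measures bias, false-rejection
    rate and power of each estimator over replicated scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
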