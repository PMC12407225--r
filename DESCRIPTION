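Package: panelbn
Title: Subpopulation Bayesian Network Analysis of Longitudinal Intervention Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns temporal hybrid (conditional linear Gaussian) Bayesian
    networks from longitudinal intervention panel data with missing values,
    and compares intervention-to-outcome pathways across demographic
    subpopulations. Provides BIC hill climbing under temporal tier
    constraints, structural expectation-maximization for incomplete records,
    Efron-bootstrap arc-confidence averaging with stability selection of the
    bootstrap count via the structural Hamming distance, jackknife
    bias-corrected mutual-information arc grading, extraction of
    intervention-to-outcome path fragments, and a synthetic panel generator
    with a known ground-truth network for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
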