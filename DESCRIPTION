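Package: pansig
Title: Consensus Random-Forest Signatures for Target-Defined Tumor
    Microenvironments
Version: 0.1.0
Authors@R: person("pansig", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Target-agnostic workflow for characterizing the
    microenvironment associated with overexpression of a query gene in a
    multi-entity bulk expression cohort.  Samples are dichotomized into
    target-high versus rest by per-entity z-scores, an entity-independent
    consensus gene (or microRNA) signature is extracted by aggregating
    feature importances over repeated random-forest classifiers, and the
    signature is validated (leave-target-out overlap, aggregated
    confusion-matrix F1 and Matthews correlation coefficient) and
    characterized (per-entity correlation panels, direction splitting,
    hypergeometric over-representation analysis).  Ships a synthetic
    multi-entity cohort generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
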