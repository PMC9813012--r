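Package: comodal
Title: Collaborative Multimodal Reservoir Computing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulator for a pair of echo-state reservoir modules that learn
    to segment co-occurring multimodal stimulus patterns (chunks) from
    continuous two-channel input streams without labels. Each module's linear
    readouts are trained online by FORCE (recursive least squares) against a
    soft winner-take-all teaching signal derived from the partner module's
    normalized readouts, so chunk selectivity self-organizes from stimulus
    co-occurrence alone. Includes generators for paired text-tone and
    procedural-image stimulus streams with co-occurrence (pair replacement)
    and inter-modal delay manipulations, alternative inter-module coupling
    architectures with a Hebbian association layer, confusion-matrix accuracy
    scoring with optimal label assignment, and population-dynamics metrics
    (PCA trajectory separation, activation phase, effective dimensionality).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
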