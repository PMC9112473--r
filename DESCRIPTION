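Package: corgnet
Title: Knowledge-Guided Feature Selection for Pathways Driving Cancer Drug
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nominates biological pathways that drive drug response in cancer
    cell line panels by combining condition-responsive-gene (CORG) pathway
    activity scoring, protein-protein interaction network modules derived
    from the topological overlap measure, per-module shadow-feature (Boruta
    style) selection backed by a random-forest importance engine, support
    vector machine recursive feature elimination with cross-validation
    averaged ranks, and module-level hypergeometric enrichment with
    Holm-Bonferroni correction. Includes a synthetic data generator with
    planted driver pathways for calibration and recovery testing, and a
    command line entry point for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
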