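Package: gislasso
Title: Knowledge-Guided Feature Selection with GIS-Weighted LASSO
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns prior biological knowledge stored in ontologies into
    per-gene relevance scores and uses them as feature-specific L1
    penalties in a weighted-LASSO generalized linear model, so that
    feature selection on gene expression data trades off predictive
    power against known biological relevance. Parses OBO ontologies and
    GAF/TSV gene annotations, unfolds annotations over the ontology DAG,
    computes a structure-based information content for every term and a
    Gene Information Score (GIS) for every gene, fits gaussian and
    logistic models with per-feature L1 penalties by coordinate descent
    (cross-validated lambda selection, one-vs-rest multiclass), and ships
    a simulation suite for multicollinearity and predictive-power
    sensitivity analyses on synthetic ontologies, annotations and
    expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
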