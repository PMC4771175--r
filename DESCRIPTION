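Package: ppinet
Title: Proteomic Network Inference, Benchmarking and Consensus Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protein-protein interaction networks from reverse phase
    protein array (RPPA) expression matrices with thirteen established
    estimators spanning correlation, inverse-covariance and regression-based
    partial correlation, and k-nearest-neighbour mutual information families.
    Benchmarks the estimators against a gold-standard edge set with
    limited-recall precision-recall analysis and per-method grid search,
    aggregates high-performing methods into per-cohort consensus networks,
    detects robust modules by five-algorithm community-detection consensus,
    classifies edge groups, and maps consensus interactions onto hierarchical
    gene-list collections. A synthetic-data generator produces Gaussian
    graphical model cohorts, antibody annotations and gene-list hierarchies
    with the statistical structure the analysis assumes, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    corpcor,
    glmnet,
    igraph,
    yaml,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
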