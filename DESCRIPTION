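Package: psychspace
Title: Data-Driven Ontology Discovery for Behavioral Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving quantitative psychological ontologies from
    large individual-differences batteries of behavioral tasks and self-report
    surveys. Implements maximum-likelihood exploratory factor analysis with
    direct oblimin rotation and BIC dimensionality selection, ten Berge
    correlation-preserving factor scores, test-retest reliability analysis with
    attenuation correction, hierarchical clustering of variables in
    factor-loading space with a dynamic hybrid tree cut and consensus
    robustness analysis, sparse partial-correlation networks via the graphical
    lasso with extended-BIC model selection, and permutation-nulled
    cross-validated prediction of real-world outcomes from factor scores.
    A synthetic battery generator with planted factor, reliability, and outcome
    structure supports end-to-end validation of every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    cluster,
    MASS,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ranger,
    e1071,
    optparse
Config/testthat/edition: 3
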