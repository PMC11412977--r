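Package: prioconn
Title: Conservation Prioritization and Corridor Planning from Ensemble
    Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for landscape-scale conservation planning in fragmented
    forest systems: occurrence-record cleaning and spatial thinning,
    collinearity screening of environmental predictors, TSS-weighted
    ensembles of species distribution models with pseudo-absence sampling,
    core-area zonation priority ranking with condition layers and
    hierarchical protected-area masks, extraction of conservation-priority
    fragments, and least-cost ecological corridors on composite resistance
    surfaces with cost-weighted-distance statistics. Includes a synthetic
    landscape and virtual-taxon generator so the full pipeline runs and is
    testable without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    withr,
    glmnet,
    xgboost,
    rpart,
    nnet,
    pROC,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
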