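Package: lymphCODA
Title: Compositional Analysis of Lymphocyte Subset Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing T- and B-lymphocyte subset panels as
    compositional data. Converts hierarchical percent-of-parent flow
    cytometry panels into closed 16-part compositions, performs stepwise
    redundancy analysis over all pairwise logratios, infers sparse
    conditional-dependence networks on centred-logratio data (graphical
    lasso and Meinshausen-Buhlmann neighbourhood selection with StARS
    stability selection), and fits L1-penalised log-contrast regressions
    of health outcomes with a sum-to-zero constraint, BIC tuning and
    bootstrap confidence intervals. Includes a synthetic cohort generator
    with known ground truth (planted conditional-dependence edges, sparse
    sum-to-zero outcome model, zero inflation) so the whole pipeline is
    testable without restricted survey microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
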