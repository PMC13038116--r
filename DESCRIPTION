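Package: graftdl
Title: Graph-Filtered Temporal Dictionary Learning for Functional Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Morphology-free extraction of fluorescing components and their time
    traces from functional imaging videos (two-photon and widefield calcium
    imaging, vascular and axonal recordings) by graph-regularized dictionary
    learning. A k-nearest-neighbour graph over pixel time traces replaces
    spatial shape priors; sparse nonnegative spatial maps are estimated by
    re-weighted l1 graph filtering, with the weighted nonnegative LASSO solved
    as a quadratic program by interchangeable interior-point and active-set
    solvers. Temporal random-projection sketching runs the learning loop in a
    compressed time dimension with full-length traces recovered at the end.
    Includes a ground-truth-bearing synthetic video generator and trace-matching
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tiff,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
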