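Package: trajdiff
Title: Differential Pseudotime Analysis Across Multiple Single-Cell Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for comparing pseudotemporal trajectories
    across multiple single-cell RNA-seq samples. Builds cluster-based
    minimum-spanning-tree trajectories on a harmonized embedding, quantifies
    branch uncertainty by bootstrap detection rates, tests differential tree
    topology with binomial or multinomial logistic regression, and models
    gene expression along pseudotime with a functional mixed-effects B-spline
    model (sample-level random effects, inverse-gamma cell noise) fitted by
    EM. Permutation likelihood-ratio tests detect differential expression
    along pseudotime (TDE), differential expression associated with
    sample-level covariates (XDE, decomposed into mean shift and trend
    difference), and the analogous cell-density tests (TCD/XCD). Includes
    simulation generators for benchmark construction (median-matching nulls,
    signal spike-ins, branch subsampling) and FDR-calibration metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    Matrix,
    igraph,
    rhdf5,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
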