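Package: gkpareto
Title: Parallel Pareto-Optimal Gamma Knife Radiosurgery Plan Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batched generation of Pareto-optimal Gamma Knife radiosurgery
    treatment plans. The weighted-sum inverse planning problem is solved in
    its dual linear-program form with an alternating direction method of
    multipliers (ADMM) whose Schur-complement operator is cached once and
    shared across all objective-weight vectors, so hundreds of plans are
    optimized simultaneously. Includes a two-pass low-dose refinement with
    non-redundant sampling of overlapping low-dose volumes, a synthetic
    voxel-phantom generator with Gaussian sector/collimator dose-rate
    kernels, clinical plan metrics (coverage, selectivity, gradient index,
    beam-on time), and an exact linear-programming oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
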