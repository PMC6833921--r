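Package: scgnmf
Title: Nonnegative Matrix Factorization Classification of Small-Sample
    Transcriptomes via a Spectral Conjugate Gradient Solver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies small-sample, high-dimensional expression profiles
    (tens of thousands of genes, a handful of samples) by nonnegative matrix
    factorization A ~ WH. The factorization is solved by alternating
    nonnegative least squares in which each convex subproblem is minimized
    by a modified spectral conjugate gradient method with Armijo-type
    backtracking, followed by projection onto the nonnegative orthant and a
    relative KKT stopping rule. On top of the factorization the package
    provides soft-membership sample classification, trial-rank selection,
    sample correlation diagnostics, extraction of highly expressed genes per
    class from the basis matrix, shared-gene intersection analysis, a
    synthetic-data generator with planted class structure and replicate
    groups, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
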