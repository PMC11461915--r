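Package: jivebatch
Title: Batch-Effect Correction for Single-Cell RNA-Seq Using Joint and
    Individual Variation Explained
Version: 0.1.0
Authors@R:
    person("Miami", "Statistics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes multi-batch single-cell RNA-seq expression matrices
    into a low-rank joint structure shared across batches (interpreted as
    biology), per-batch individual structures (interpreted as technical batch
    effects), and residual noise, by alternating least squares with an
    orthogonality constraint between joint and individual loadings. The joint
    structure provides batch-corrected expression values and a low-dimensional
    cell embedding. Includes permutation-test rank selection, a quantitative
    evaluation suite for batch integration (kBET acceptance, average
    silhouette width, local inverse Simpson's index, principal variance
    component analysis), a Gamma-Poisson multi-batch count simulator with
    configurable cell-type and batch effects, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    lme4,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
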