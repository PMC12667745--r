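Package: rqpca
Title: Contrastive Dimension Reduction by Rayleigh Quotient Maximization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrastive principal component analysis formulated as exact
    maximization of the Rayleigh quotient of a target covariance against a
    background covariance, solved as a symmetric-definite generalized
    eigenproblem with optional Tikhonov regularization of the background
    (rho-PCA). Includes a faithful contrastive PCA (cPCA) baseline and the
    Taylor-expansion bridge showing cPCA is a first-order approximation of
    the Rayleigh quotient objective, a single-cell style preprocessing chain
    (high-expression filtering, depth normalization, log1p, binned-dispersion
    highly variable gene selection, per-group standard scaling), projection
    and per-group variance-ratio reporting, and seeded simulators for
    planted-axis Gaussian scenarios and overdispersed count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
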