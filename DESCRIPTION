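Package: ctrecon
Title: Sparse-View Parallel-Beam CT Reconstruction with Joint TV and
    Wavelet Regularization
Version: 0.1.0
Authors@R:
    person("CT", "Recon Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for two-dimensional parallel-beam computed tomography
    reconstruction from sparse (few-view) projection data.  Provides an
    exact ray-driven sparse system matrix, filtered backprojection with
    Ram-Lak and Shepp-Logan filters, algebraic solvers (Kaczmarz ART and
    SART), and a compressed-sensing solver that minimizes a joint total
    variation + wavelet l1 + least-squares objective by nonlinear
    conjugate gradient with backtracking line search.  Includes a
    synthetic phantom generator with low-contrast inserts and fine
    structure, a Gaussian sinogram noise model, uniform view decimation,
    and image quality metrics (relative RMSE, streak indicator, SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
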