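Package: gliomatwin
Title: Predictive Digital Twins for Glioma Growth with Quantified Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale predictive digital twins for high-grade glioma. Implements a
    reaction-diffusion model of tumor volume fraction with chemoradiation source
    terms, discretized by first-order Lagrange finite elements in space and implicit
    Euler in time; Gaussian random-field (Matern/SPDE) priors on spatially varying
    log-diffusion and log-proliferation fields; adjoint-based inexact Newton-CG
    maximum a posteriori estimation; a low-rank Laplace approximation of the Bayesian
    posterior built from a randomized generalized eigensolve of the prior-preconditioned
    data-misfit Hessian; and Monte Carlo pushforward of parameter uncertainty to
    clinical quantities of interest (total tumor cellularity, tumor volume, concordance
    correlation, Dice overlap). Ships a synthetic virtual-patient generator emulating
    longitudinal voxel imaging of tumor cellularity under a Stupp-like chemoradiation
    schedule, with an inverse-crime-avoiding fine/coarse mesh pairing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    car,
    generics,
    ggplot2,
    methods,
    rlang,
    stats,
    utils
Suggests:
    RNifti,
    jsonlite,
    testthat (>= 3.0.0),
    tibble
Config/testthat/edition: 3
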