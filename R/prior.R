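# Matern-type Gaussian random-field priors defined through the squared
# inverse of an elliptic operator, with Robin boundary treatment.

#' Elliptic-operator hyperparameters from marginal variance and correlation length
#'
#' For the covariance operator `C = (-gamma Laplacian + delta I)^(-2)` the
#' SPDE/Matern correspondence (operator order 2, smoothness
#' `nu = 2 - d/2`) gives, with `kappa_m = sqrt(delta/gamma)`:
#' `rho = sqrt(8 nu) / kappa_m` and marginal variance
#' `sigma^2 = Gamma(nu) / (Gamma(2) (4 pi)^(d/2) kappa_m^(2 nu) gamma^2)`.
#' Inverting these for the user-facing statistics yields `(gamma, delta)`.
#' In 2-D this reduces to `gamma = rho / (4 sigma sqrt(2 pi))` and
#' `delta = 2 / (sigma rho sqrt(2 pi))`.
#'
#' @param sigma2 Target pointwise marginal variance of the field.
#' @param rho_mm Target correlation length in mm.
#' @param dim Spatial dimension (2 or 3).
#' @return Named numeric vector `c(gamma, delta)`.
#' @export
hyperparams_from_stats <- function(sigma2, rho_mm, dim = 2) {
  stopifnot_scalar(sigma2, "sigma2", positive = TRUE)
  stopifnot_scalar(rho_mm, "rho_mm", positive = TRUE)
  if (!dim %in% c(2, 3)) stop("dim must be 2 or 3")
  nu <- 2 - dim / 2
  kap <- sqrt(8 * nu) / rho_mm
  gamma_ <- sqrt(gamma(nu) / (gamma(2) * (4 * pi)^(dim / 2) * kap^(2 * nu) * sigma2))
  c(gamma = gamma_, delta = kap^2 * gamma_)
}

#' Gaussian random-field prior for one log-parameter block
#'
#' Defines `m ~ N(mean, C)` with `C = A^(-2)` and
#' `A = -gamma Laplacian + delta I`, discretized with P1 elements in the
#' mass-weighted convention (discrete covariance `A^-1 M A^-1`, precision
#' `A M^-1 A`), so that statistics are stable under mesh refinement. A Robin
#' boundary term `beta <u, v>_boundary` with `beta = sqrt(gamma delta)/1.42`
#' is added to `A` by default to reduce boundary variance inflation.
#'
#' @param domain A `tissue_domain`.
#' @param mean Prior mean: scalar or nodal vector.
#' @param sigma2 Pointwise marginal variance.
#' @param rho_mm Correlation length in mm.
#' @param robin If `TRUE` (default) apply the Robin boundary treatment.
#' @param robin_scale Multiplier on the default Robin coefficient.
#' @return A `matern_prior` object.
#' @export
matern_prior <- function(domain, mean = 0, sigma2, rho_mm,
                         robin = TRUE, robin_scale = 1) {
  stopifnot(inherits(domain, "tissue_domain"))
  hp <- hyperparams_from_stats(sigma2, rho_mm, domain$dim)
  n <- nrow(domain$vertices)
  robin_coeff <- if (robin) sqrt(hp["gamma"] * hp["delta"]) / 1.42 * robin_scale else 0
  A <- hp["gamma"] * domain$fem$stiff_unit + hp["delta"] * domain$fem$mass +
    robin_coeff * domain$fem$boundary_mass
  A <- as_dgc(A)
  p <- structure(list(
    domain = domain, mean = rep_len(as.numeric(mean), n),
    sigma2 = sigma2, rho_mm = rho_mm,
    gamma = unname(hp["gamma"]), delta = unname(hp["delta"]),
    robin_coeff = unname(robin_coeff),
    A = A, cache = new.env(parent = emptyenv())
  ), class = "matern_prior")
  p
}

prior_factor <- function(prior, what = c("A", "M", "sqrtM")) {
  what <- match.arg(what)
  cache <- prior$cache
  if (is.null(cache[[what]])) {
    if (what == "A") {
      cache$A <- Matrix::Cholesky(Matrix::forceSymmetric(prior$A), perm = TRUE, LDL = FALSE)
    } else if (what == "M") {
      cache$M <- Matrix::Cholesky(Matrix::forceSymmetric(prior$domain$fem$mass),
                                  perm = TRUE, LDL = FALSE)
    } else {
      ex <- Matrix::expand(prior_factor(prior, "M"))
      cache$sqrtM <- list(L = ex$L, P = ex$P)   # M = P' L L' P
    }
  }
  cache[[what]]
}

solve_A <- function(prior, b) as.numeric(Matrix::solve(prior_factor(prior, "A"), b))
solve_M <- function(prior, b) as.numeric(Matrix::solve(prior_factor(prior, "M"), b))

# F z with F F' = M (sparse Cholesky square root of the mass matrix)
mass_sqrt_mult <- function(prior, z) {
  f <- prior_factor(prior, "sqrtM")
  as.matrix(Matrix::t(f$P) %*% (f$L %*% z))
}
mass_sqrt_tmult <- function(prior, v) {
  f <- prior_factor(prior, "sqrtM")
  as.matrix(Matrix::t(f$L) %*% (f$P %*% v))
}

# Whitening map G = A^-1 F with G G' = A^-1 M A^-1 = covariance.
prior_G <- function(prior, z) {
  apply(mass_sqrt_mult(prior, as.matrix(z)), 2, function(col) solve_A(prior, col))
}
prior_Gt <- function(prior, v) {
  v <- as.matrix(v)
  mass_sqrt_tmult(prior, apply(v, 2, function(col) solve_A(prior, col)))
}

#' Apply the prior covariance operator
#'
#' Computes `C v = A^-1 M A^-1 v` (two elliptic solves around a mass
#' application). The action is symmetric and positive definite.
#'
#' @param prior A [matern_prior()].
#' @param v Nodal vector (or matrix of columns).
#' @export
apply_prior_covariance <- function(prior, v) {
  v <- as.matrix(v)
  out <- apply(v, 2, function(col) {
    solve_A(prior, as.numeric(prior$domain$fem$mass %*% solve_A(prior, col)))
  })
  if (ncol(v) == 1L) as.numeric(out) else out
}

#' Apply the prior precision operator
#'
#' Computes `C^-1 v = A M^-1 A v` in the mass-weighted discrete convention.
#'
#' @inheritParams apply_prior_covariance
#' @export
apply_prior_precision <- function(prior, v) {
  v <- as.matrix(v)
  out <- apply(v, 2, function(col) {
    as.numeric(prior$A %*% solve_M(prior, as.numeric(prior$A %*% col)))
  })
  if (ncol(v) == 1L) as.numeric(out) else out
}

#' Draw samples from a Matern-type field prior
#'
#' Samples `mean + A^-1 F z` with `F F' = M` and `z` standard normal, whose
#' covariance is exactly the discrete prior covariance `A^-1 M A^-1`.
#'
#' @param prior A [matern_prior()].
#' @param n Number of samples.
#' @param seed Integer seed (same seed, same samples).
#' @return Matrix with one column per sample.
#' @export
sample_prior <- function(prior, n = 1L, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  nverts <- length(prior$mean)
  z <- with_seed(seed, matrix(stats::rnorm(nverts * n), nverts, n))
  prior$mean + prior_G(prior, z)
}

# --- block prior over (mD, mkappa) ---------------------------------------

#' Block-diagonal prior over the log-parameter pair
#'
#' Mutually independent Matern-type field priors per parameter block. The
#' default two blocks are `mD` and `mkappa`; an optional linear `field_map`
#' (sparse, fields-by-parameters) maps the parameter blocks to the
#' `(mD, mkappa)` fields seen by the PDE, which supports the tissue-split
#' mode where gray- and white-matter log-diffusivity are independent fields
#' combined through the gray-matter indicator.
#'
#' @param blocks Named list of [matern_prior()] objects.
#' @param field_map Optional sparse matrix mapping the concatenated parameter
#'   vector to the concatenated `(mD, mkappa)` field vector; identity if `NULL`.
#' @export
block_prior <- function(blocks, field_map = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  sizes <- vapply(blocks, function(b) length(b$mean), integer(1))
  offsets <- cumsum(c(0L, sizes))
  structure(list(blocks = blocks, sizes = sizes, offsets = offsets,
                 npar = sum(sizes), field_map = field_map),
            class = "block_prior")
}

#' Prior for the virtual-patient calibration
#'
#' The default hyperparameters for the synthetic study: log-diffusivity mean
#' -1.30 with variance 0.05, log-proliferation mean -1.00 with variance
#' 0.02, correlation length 180 mm for both blocks.
#'
#' @param domain A `tissue_domain`.
#' @param mean_mD,var_mD,mean_mkappa,var_mkappa,rho_mm Block hyperparameters.
#' @param ... Passed to [matern_prior()].
#' @export
default_block_prior <- function(domain, mean_mD = -1.30, var_mD = 0.05,
                                mean_mkappa = -1.00, var_mkappa = 0.02,
                                rho_mm = 180, ...) {
  block_prior(list(
    mD = matern_prior(domain, mean_mD, var_mD, rho_mm, ...),
    mkappa = matern_prior(domain, mean_mkappa, var_mkappa, rho_mm, ...)
  ))
}

#' Tissue-split prior on the log-diffusivity
#'
#' Cohort-style configuration in which the log-diffusivity is modeled as two
#' independent random fields on gray and white matter, combined through the
#' gray-matter indicator, each with its own mean/variance/correlation length.
#'
#' @param domain A `tissue_domain`.
#' @param mean_gm,var_gm,rho_gm Gray-matter block hyperparameters.
#' @param mean_wm,var_wm,rho_wm White-matter block hyperparameters.
#' @param mean_mkappa,var_mkappa,rho_mkappa Log-proliferation hyperparameters.
#' @param ... Passed to [matern_prior()].
#' @export
tissue_split_prior <- function(domain,
                               mean_gm = -1.467, var_gm = 0.115, rho_gm = 180,
                               mean_wm = -0.991, var_wm = 0.115, rho_wm = 360,
                               mean_mkappa = -1.230, var_mkappa = 0.040,
                               rho_mkappa = 180, ...) {
  n <- nrow(domain$vertices)
  chi <- as.numeric(domain$tissue)
  blocks <- list(
    mD_gm = matern_prior(domain, mean_gm, var_gm, rho_gm, ...),
    mD_wm = matern_prior(domain, mean_wm, var_wm, rho_wm, ...),
    mkappa = matern_prior(domain, mean_mkappa, var_mkappa, rho_mkappa, ...)
  )
  iD <- seq_len(n)
  fm <- Matrix::sparseMatrix(
    i = c(iD, iD, n + iD),
    j = c(iD, n + iD, 2L * n + iD),
    x = c(chi, 1 - chi, rep(1, n)),
    dims = c(2L * n, 3L * n)
  )
  block_prior(blocks, field_map = as_dgc(fm))
}

bp_block_apply <- function(bp, v, fun) {
  out <- numeric(bp$npar)
  for (k in seq_along(bp$blocks)) {
    idx <- bp$offsets[k] + seq_len(bp$sizes[k])
    out[idx] <- fun(bp$blocks[[k]], v[idx])
  }
  out
}

bp_mean <- function(bp) unlist(lapply(bp$blocks, function(b) b$mean), use.names = FALSE)
bp_precision <- function(bp, v) bp_block_apply(bp, v, apply_prior_precision)
bp_covariance <- function(bp, v) bp_block_apply(bp, v, apply_prior_covariance)
bp_Gt_vec <- function(bp, v) bp_block_apply(bp, v, function(b, x) as.numeric(prior_Gt(b, x)))
bp_G_vec <- function(bp, z) bp_block_apply(bp, z, function(b, x) as.numeric(prior_G(b, x)))

# parameters -> (mD, mkappa) field vector and its transpose
bp_to_fields <- function(bp, v) {
  if (is.null(bp$field_map)) v else as.numeric(bp$field_map %*% v)
}
bp_fields_adjoint <- function(bp, g) {
  if (is.null(bp$field_map)) g else as.numeric(Matrix::t(bp$field_map) %*% g)
}

bp_sample <- function(bp, n = 1L, seed = NULL) {
  zs <- with_seed(seed, matrix(stats::rnorm(bp$npar * n), bp$npar, n))
  out <- matrix(0, bp$npar, n)
  for (k in seq_along(bp$blocks)) {
    idx <- bp$offsets[k] + seq_len(bp$sizes[k])
    out[idx, ] <- bp$blocks[[k]]$mean + prior_G(bp$blocks[[k]], zs[idx, , drop = FALSE])
  }
  out
}

#' Prior negative log-density (cost) and its gradient
#'
#' `cost(m) = 1/2 (m - m_pr)' C^-1 (m - m_pr)` in the mass-weighted discrete
#' convention, summed over blocks, with its gradient.
#'
#' @param prior A [block_prior()] (or a single [matern_prior()]).
#' @param m Parameter vector (concatenated blocks), a [parameter_field()],
#'   or a single-block nodal vector.
#' @return List with elements `cost` and `grad`.
#' @export
prior_cost_and_grad <- function(prior, m) {
  if (inherits(prior, "matern_prior")) {
    prior <- block_prior(list(m = prior))
  }
  v <- if (inherits(m, "parameter_field")) pf_concat(m) else as.numeric(m)
  dm <- v - bp_mean(prior)
  g <- bp_precision(prior, dm)
  list(cost = 0.5 * sum(dm * g), grad = g)
}
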