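# Low-rank Laplace approximation of the posterior: randomized solution of
# the prior-preconditioned generalized eigenproblem for the data-misfit
# Hessian, Sherman-Morrison-Woodbury posterior covariance action, and a
# low-rank posterior sampler.

#' Leading eigenpairs of the prior-preconditioned misfit Hessian
#'
#' Solves the generalized eigenvalue problem
#' `H_misfit v_j = lambda_j C_pr^-1 v_j` at the MAP point for the leading
#' `k` pairs with a double-pass randomized eigensolver using `k + p`
#' Gaussian probes. Internally the problem is whitened with the prior factor
#' `G` (`G G' = C_pr`): the symmetric operator `G' H G` is compressed and
#' diagonalized, so the returned eigenvectors are exactly
#' `C_pr^-1`-orthonormal. The eigenvalues measure how strongly the data
#' inform the corresponding parameter directions; negative estimates are
#' truncated to zero.
#'
#' @param ip Inverse problem (from [calibration_problem()]) or linear fixture.
#' @param prior A [block_prior()].
#' @param m_map MAP parameter vector (e.g. `solve_map(...)$m_map`).
#' @param k Number of eigenpairs to retain (default 50).
#' @param p Oversampling count (default 10).
#' @param seed Integer seed for the Gaussian probes.
#' @param mode Hessian mode; the Gauss-Newton (PSD) Hessian is the default
#'   so that all eigenvalues are nonnegative and the low-rank posterior
#'   update is well defined.
#' @return An `eigen_pair_set` with `values`, `vectors` (parameter-space,
#'   `C_pr^-1`-orthonormal columns), `whitened` (the whitened eigenvectors),
#'   `k`, and `oversampling`.
#' @export
misfit_hessian_gevp <- function(ip, prior, m_map, k = 50L, p = 10L, seed = 1L,
                                mode = "gauss_newton") {
  if (k < 1) stop("k must be at least 1")
  npar <- prior$npar
  kp <- min(k + p, npar)
  pl <- par_linearize(ip, prior, m_map)
  Tfun <- function(w) bp_Gt_vec(prior, pl$hess(bp_G_vec(prior, w), mode))
  Omega <- with_seed(seed, matrix(stats::rnorm(npar * kp), npar, kp))
  Y <- matrix(0, npar, kp)
  for (j in seq_len(kp)) Y[, j] <- Tfun(Omega[, j])
  Q <- qr.Q(qr(Y))
  TQ <- matrix(0, npar, ncol(Q))
  for (j in seq_len(ncol(Q))) TQ[, j] <- Tfun(Q[, j])
  T2 <- crossprod(Q, TQ)
  T2 <- (T2 + t(T2)) / 2
  es <- eigen(T2, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  keep <- seq_len(min(k, length(ord)))
  vals <- es$values[ord][keep]
  truncated_rank <- sum(vals < 0)
  vals <- pmax(vals, 0)
  W <- Q %*% es$vectors[, ord[keep], drop = FALSE]
  V <- matrix(0, npar, length(keep))
  for (j in seq_along(keep)) V[, j] <- bp_G_vec(prior, W[, j])
  structure(list(values = vals, vectors = V, whitened = W,
                 k = length(keep), oversampling = p,
                 rank_deficient = truncated_rank > 0),
            class = "eigen_pair_set")
}

#' @export
print.eigen_pair_set <- function(x, ...) {
  cat(sprintf("<eigen_pair_set> %d retained pairs (oversampling %d); lambda_1 = %.4g, lambda_k = %.4g\n",
              x$k, x$oversampling, x$values[1], x$values[x$k]))
  invisible(x)
}

#' @method tidy eigen_pair_set
#' @export
tidy.eigen_pair_set <- function(x, ...) {
  out <- data.frame(index = seq_len(x$k), eigenvalue = x$values)
  if (requireNamespace("tibble", quietly = TRUE)) tibble::as_tibble(out) else out
}

#' Low-rank Laplace approximation to the posterior
#'
#' Gaussian `N(m_MAP, C_post)` with
#' `C_post = C_pr - sum_j lambda_j/(1+lambda_j) v_j v_j'` (Sherman-Morrison-
#' Woodbury form of `(H_misfit + C_pr^-1)^-1` truncated at rank `k`).
#'
#' @param m_map MAP parameter vector.
#' @param pairs An `eigen_pair_set` from [misfit_hessian_gevp()], or `NULL`
#'   for the rank-0 (prior-covariance) approximation.
#' @param prior The [block_prior()].
#' @export
laplace_posterior <- function(m_map, pairs, prior) {
  if (!is.null(pairs) && any(pairs$values < 0)) stop("eigenvalues must be nonnegative")
  structure(list(m_map = as.numeric(m_map), pairs = pairs, prior = prior),
            class = "laplace_posterior")
}

#' Apply the Laplace posterior covariance
#'
#' `C_post v = C_pr v - sum_j [lambda_j/(1+lambda_j)] v_j (v_j' v)`; reduces
#' to the prior covariance for rank 0, and the correction is positive
#' semidefinite so posterior variances never exceed prior variances.
#'
#' @param post A [laplace_posterior()].
#' @param v Parameter-space vector.
#' @export
posterior_cov_action <- function(post, v) {
  out <- bp_covariance(post$prior, v)
  if (!is.null(post$pairs) && post$pairs$k > 0) {
    lam <- post$pairs$values
    V <- post$pairs$vectors
    out <- out - as.numeric(V %*% ((lam / (1 + lam)) * crossprod(V, v)))
  }
  out
}

#' Sample from the low-rank Laplace posterior
#'
#' Draws prior-whitened Gaussian noise `z` and applies the low-rank
#' transformation `m = m_MAP + G (z - sum_j (1 - (1+lambda_j)^{-1/2}) w_j (w_j' z))`,
#' whose covariance is exactly the rank-k posterior covariance.
#'
#' @param post A [laplace_posterior()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Matrix with one parameter-space sample per column.
#' @export
sample_laplace <- function(post, n = 1L, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  npar <- post$prior$npar
  z <- with_seed(seed, matrix(stats::rnorm(npar * n), npar, n))
  if (!is.null(post$pairs) && post$pairs$k > 0) {
    W <- post$pairs$whitened
    shrink <- 1 - 1 / sqrt(1 + post$pairs$values)
    z <- z - W %*% (shrink * crossprod(W, z))
  }
  out <- matrix(0, npar, n)
  for (j in seq_len(n)) out[, j] <- bp_G_vec(post$prior, z[, j])
  post$m_map + out
}

#' Pointwise posterior standard deviation (diagonal of the covariance)
#'
#' Computes the marginal posterior variance at each parameter degree of
#' freedom from the prior marginal variance minus the low-rank correction.
#' Exact for the low-rank representation; the prior diagonal is evaluated
#' by applying the covariance to unit vectors, so use on small meshes only.
#'
#' @param post A [laplace_posterior()].
#' @keywords internal
posterior_pointwise_variance <- function(post) {
  npar <- post$prior$npar
  pri <- vapply(seq_len(npar), function(i) {
    e <- numeric(npar); e[i] <- 1
    bp_covariance(post$prior, e)[i]
  }, numeric(1))
  corr <- if (!is.null(post$pairs) && post$pairs$k > 0) {
    lam <- post$pairs$values
    rowSums(sweep(post$pairs$vectors^2, 2, lam / (1 + lam), `*`))
  } else 0
  pri - corr
}

#' @export
print.laplace_posterior <- function(x, ...) {
  k <- if (is.null(x$pairs)) 0L else x$pairs$k
  cat(sprintf("<laplace_posterior> rank-%d update of the prior around the MAP (npar = %d)\n",
              k, x$prior$npar))
  invisible(x)
}
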