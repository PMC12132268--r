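# Low-rank Laplace posterior: randomized GEVP vs dense oracles, posterior
# covariance action, sampling, and exactness on linear problems.

# Small linear fixture with a prior on a coarse mesh, used throughout.
linear_fixture <- function(nobs = 40, seed = 51) {
  dom <- small_domain()
  bp <- block_prior(list(mD = matern_prior(dom, -1, 0.05, 10),
                         mkappa = matern_prior(dom, -2, 0.02, 10)))
  npar <- bp$npar
  set.seed(seed)
  J <- matrix(rnorm(nobs * npar), nobs, npar) / sqrt(npar)
  m_star <- gliomatwin:::bp_mean(bp) + 0.3 * rnorm(npar)
  d <- as.numeric(J %*% m_star) + 0.05 * rnorm(nobs)
  sig2 <- 0.05^2
  list(dom = dom, bp = bp, npar = npar, J = J, d = d, sig2 = sig2,
       ip = gliomatwin:::linear_inverse_problem(J, d, sig2))
}

test_that("randomized GEVP matches a dense generalized eigensolve", {
  fx <- linear_fixture()
  # MAP of the quadratic problem
  res <- solve_map(fx$ip, fx$bp,
                   settings = newtoncg_settings(ew_eta_max = 1e-10, max_cg = 3000,
                                                gn_iters = 0, grad_rtol = 1e-9))
  # probes cover the full misfit rank (40), so the double-pass solve is exact
  pairs <- misfit_hessian_gevp(fx$ip, fx$bp, res$m_map, k = 10, p = 45, seed = 3)
  H <- crossprod(fx$J) / fx$sig2
  Gpr <- dense_operator(function(v) gliomatwin:::bp_covariance(fx$bp, v), fx$npar)
  oracle <- sort(Re(eigen(Gpr %*% H)$values), decreasing = TRUE)[1:10]
  expect_lt(max(abs(pairs$values[1:10] - oracle) / oracle), 1e-6)
  # eigenvectors are prior-precision orthonormal
  VtPV <- crossprod(pairs$vectors,
                    dense_operator(function(v) gliomatwin:::bp_precision(fx$bp, v),
                                   fx$npar) %*% pairs$vectors)
  expect_lt(max(abs(VtPV - diag(10))), 1e-8)
})

test_that("a zero-information problem yields a flat spectrum and prior-equal posterior", {
  fx <- linear_fixture()
  # data carry no information: J = 0
  ip0 <- gliomatwin:::linear_inverse_problem(matrix(0, 5, fx$npar), rep(0, 5), 1)
  pairs <- misfit_hessian_gevp(ip0, fx$bp, gliomatwin:::bp_mean(fx$bp), k = 5, p = 5, seed = 9)
  expect_lt(max(pairs$values), 1e-10)
  post0 <- laplace_posterior(gliomatwin:::bp_mean(fx$bp), NULL, fx$bp)
  set.seed(12)
  v <- rnorm(fx$npar)
  expect_equal(posterior_cov_action(post0, v),
               gliomatwin:::bp_covariance(fx$bp, v), tolerance = 1e-12)
})

test_that("posterior covariance matches the dense (H + C^-1)^-1 and never exceeds the prior", {
  fx <- linear_fixture()
  res <- solve_map(fx$ip, fx$bp,
                   settings = newtoncg_settings(ew_eta_max = 1e-10, max_cg = 3000,
                                                gn_iters = 0, grad_rtol = 1e-9))
  pairs <- misfit_hessian_gevp(fx$ip, fx$bp, res$m_map, k = 40, p = 15, seed = 5)
  post <- laplace_posterior(res$m_map, pairs, fx$bp)
  H <- crossprod(fx$J) / fx$sig2
  Prec <- dense_operator(function(v) gliomatwin:::bp_precision(fx$bp, v), fx$npar)
  dense_post <- solve(H + Prec)
  set.seed(7)
  for (trial in 1:3) {
    v <- rnorm(fx$npar)
    got <- posterior_cov_action(post, v)
    want <- as.numeric(dense_post %*% v)
    expect_lt(sqrt(sum((got - want)^2)) / sqrt(sum(want^2)), 1e-5)
    expect_lte(sum(v * got), sum(v * gliomatwin:::bp_covariance(fx$bp, v)) + 1e-10)
  }
})

test_that("rank truncation error is bounded by the first discarded eigenvalue", {
  fx <- linear_fixture()
  res <- solve_map(fx$ip, fx$bp,
                   settings = newtoncg_settings(ew_eta_max = 1e-10, max_cg = 3000,
                                                gn_iters = 0, grad_rtol = 1e-9))
  all_pairs <- misfit_hessian_gevp(fx$ip, fx$bp, res$m_map, k = 40, p = 15, seed = 5)
  kk <- 8L
  trunc <- all_pairs
  trunc$values <- trunc$values[seq_len(kk)]
  trunc$vectors <- trunc$vectors[, seq_len(kk), drop = FALSE]
  trunc$whitened <- trunc$whitened[, seq_len(kk), drop = FALSE]
  trunc$k <- kk
  post_full <- laplace_posterior(res$m_map, all_pairs, fx$bp)
  post_k <- laplace_posterior(res$m_map, trunc, fx$bp)
  lam_next <- all_pairs$values[kk + 1L]
  D <- dense_operator(function(v) posterior_cov_action(post_k, v), fx$npar) -
    dense_operator(function(v) posterior_cov_action(post_full, v), fx$npar)
  Gpr <- dense_operator(function(v) gliomatwin:::bp_covariance(fx$bp, v), fx$npar)
  nrm <- function(M) max(abs(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values))
  # || C_k - C_full ||_2 <= lam_{k+1}/(1+lam_{k+1}) * || C_pr ||_2
  expect_lte(nrm(D), lam_next / (1 + lam_next) * nrm(Gpr) * (1 + 1e-8))
})

test_that("the low-rank sampler reproduces the dense posterior covariance", {
  fx <- linear_fixture()
  res <- solve_map(fx$ip, fx$bp,
                   settings = newtoncg_settings(ew_eta_max = 1e-10, max_cg = 3000,
                                                gn_iters = 0, grad_rtol = 1e-9))
  pairs <- misfit_hessian_gevp(fx$ip, fx$bp, res$m_map, k = 40, p = 15, seed = 5)
  post <- laplace_posterior(res$m_map, pairs, fx$bp)
  s1 <- sample_laplace(post, 50, seed = 77)
  expect_identical(s1, sample_laplace(post, 50, seed = 77))
  n <- 20000
  s <- sample_laplace(post, n, seed = 78)
  emp <- stats::cov(t(s))
  H <- crossprod(fx$J) / fx$sig2
  Prec <- dense_operator(function(v) gliomatwin:::bp_precision(fx$bp, v), fx$npar)
  dense_post <- solve(H + Prec)
  # SE ~ sqrt((C_ii C_jj + C_ij^2)/n)
  dg <- diag(dense_post)
  se <- sqrt((outer(dg, dg) + dense_post^2) / n)
  # entrywise 4-SE band, aggregated with multiplicity in mind: the maximum
  # over ~1.7e4 entries of a correct sampler is expected to reach ~4.2 SE,
  # so allow the handful of exceedances an exact Gaussian sampler produces
  # (expected ~1 per 16k at 4 SE) while capping all entries at 6 SE
  z <- abs(emp - dense_post) / (se + 1e-14)
  expect_lt(sum(z > 4), 10)
  expect_lt(max(z), 6)
  # sample mean near the MAP
  expect_lt(max(abs(rowMeans(s) - res$m_map) / (4 * sqrt(dg / n) + 1e-14)), 1.5)
})

test_that("rank-0 Laplace samples are prior samples shifted to the MAP", {
  fx <- linear_fixture()
  m_map <- gliomatwin:::bp_mean(fx$bp) + 0.1
  post0 <- laplace_posterior(m_map, NULL, fx$bp)
  a <- sample_laplace(post0, 3000, seed = 31)
  b <- gliomatwin:::bp_sample(fx$bp, 3000, seed = 32) +
    (m_map - gliomatwin:::bp_mean(fx$bp))
  # marginal two-sample check on a handful of degrees of freedom
  for (i in c(1, 17, fx$npar)) {
    expect_gt(stats::ks.test(a[i, ], b[i, ])$p.value, 1e-4)
  }
})

test_that("the Laplace approximation is exact for linear inverse problems", {
  fx <- linear_fixture()
  res <- solve_map(fx$ip, fx$bp,
                   settings = newtoncg_settings(ew_eta_max = 1e-12, max_cg = 4000,
                                                gn_iters = 0, grad_rtol = 1e-10))
  pairs <- misfit_hessian_gevp(fx$ip, fx$bp, res$m_map, k = 40, p = 15, seed = 5)
  post <- laplace_posterior(res$m_map, pairs, fx$bp)
  H <- crossprod(fx$J) / fx$sig2
  Prec <- dense_operator(function(v) gliomatwin:::bp_precision(fx$bp, v), fx$npar)
  Sigma <- solve(H + Prec)
  mu <- as.numeric(Sigma %*% (crossprod(fx$J, fx$d) / fx$sig2 +
                                Prec %*% gliomatwin:::bp_mean(fx$bp)))
  expect_lt(max(abs(res$m_map - mu)), 1e-6)
  Cpost <- dense_operator(function(v) posterior_cov_action(post, v), fx$npar)
  expect_lt(max(abs(Cpost - Sigma)), 1e-6)
})
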