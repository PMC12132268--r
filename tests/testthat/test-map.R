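# Adjoint gradient, Hessian actions, and the inexact Newton-CG MAP solver.

test_that("adjoint gradient passes the central finite-difference test, RT events included", {
  sp <- small_inverse_problem()
  fx <- sp$fixture
  n <- nrow(fx$domain$vertices)
  set.seed(17)
  points <- list(
    pf_concat(parameter_field(rep(log(0.2), n), rep(log(0.2), n))),
    pf_concat(parameter_field(rep(log(0.3), n) + 0.1 * rnorm(n),
                              rep(log(0.1), n) + 0.1 * rnorm(n))),
    pf_concat(fx$m_true) + 0.05 * rnorm(2 * n)
  )
  for (mv in points) {
    lin <- gliomatwin:::ip_linearize(sp$ip, mv)
    for (trial in 1:5) {
      v <- rnorm(2 * n); v <- v / sqrt(sum(v^2))
      eps <- 1e-5
      fd <- (gliomatwin:::ip_cost(sp$ip, mv + eps * v) -
               gliomatwin:::ip_cost(sp$ip, mv - eps * v)) / (2 * eps)
      expect_lt(abs(fd - sum(lin$grad * v)) / abs(fd), 1e-5)
    }
  }
})

test_that("gradient decouples into misfit and prior parts and vanishes at the noise-free optimum", {
  sp <- small_inverse_problem(with_noise = FALSE)
  fx <- sp$fixture
  bp <- small_prior()
  # misfit-only gradient at the generating parameters is zero
  g_mis <- gradient_adjoint(fx$domain, fx$m_true, sp$obs, prior = NULL,
                            fx$u0, fx$schedule, fx$settings)
  expect_lt(max(abs(g_mis)), 1e-6)
  # at the prior mean, full gradient = misfit gradient + prior gradient,
  # and the prior part is zero there
  m0 <- gliomatwin:::bp_mean(bp)
  g_full <- gradient_adjoint(fx$domain, m0, sp$obs, bp, fx$u0, fx$schedule, fx$settings)
  g_mis0 <- gradient_adjoint(fx$domain, m0, sp$obs, NULL, fx$u0, fx$schedule, fx$settings)
  expect_equal(g_full, g_mis0, tolerance = 1e-12)
})

test_that("Hessian actions are symmetric, PSD in Gauss-Newton mode, and match gradient differences", {
  sp <- small_inverse_problem()
  fx <- sp$fixture
  n <- nrow(fx$domain$vertices)
  set.seed(23)
  mv <- pf_concat(parameter_field(rep(log(0.25), n) + 0.05 * rnorm(n),
                                  rep(log(0.12), n) + 0.05 * rnorm(n)))
  lin <- gliomatwin:::ip_linearize(sp$ip, mv)
  for (trial in 1:3) {
    v <- rnorm(2 * n); w <- rnorm(2 * n)
    Hv <- gliomatwin:::misfit_hess_action(lin, v, "full")
    Hw <- gliomatwin:::misfit_hess_action(lin, w, "full")
    expect_lt(abs(sum(Hv * w) - sum(Hw * v)) / max(abs(sum(Hv * w)), 1e-12), 1e-8)
    Gv <- gliomatwin:::misfit_hess_action(lin, v, "gauss_newton")
    expect_gt(sum(v * Gv), -1e-10 * sum(v * v))
  }
  # full Hessian vs central differences of the adjoint gradient
  v <- rnorm(2 * n); v <- v / sqrt(sum(v^2))
  eps <- 1e-5
  gp <- gliomatwin:::ip_linearize(sp$ip, mv + eps * v)$grad
  gm <- gliomatwin:::ip_linearize(sp$ip, mv - eps * v)$grad
  fdH <- (gp - gm) / (2 * eps)
  Hv <- gliomatwin:::misfit_hess_action(lin, v, "full")
  expect_lt(sqrt(sum((fdH - Hv)^2)) / sqrt(sum(fdH^2)), 1e-4)
})

test_that("Newton converges in one iteration on a quadratic (linear forward map)", {
  dom <- small_domain()
  bp <- block_prior(list(mD = matern_prior(dom, -1, 0.05, 10),
                         mkappa = matern_prior(dom, -2, 0.02, 10)))
  npar <- bp$npar
  set.seed(31)
  J <- matrix(rnorm(20 * npar), 20, npar)
  m_star <- gliomatwin:::bp_mean(bp) + 0.3 * rnorm(npar)
  d <- as.numeric(J %*% m_star)
  lip <- gliomatwin:::linear_inverse_problem(J, d, 0.1)
  res <- solve_map(lip, bp,
                   settings = newtoncg_settings(ew_eta_max = 1e-10, max_cg = 2000,
                                                gn_iters = 0, grad_rtol = 1e-8))
  expect_true(res$converged)
  expect_equal(res$newton_iters, 1L)
  # analytic minimizer of the quadratic
  Prec <- dense_operator(function(v) gliomatwin:::bp_precision(bp, v), npar)
  H <- crossprod(J) / 0.1 + Prec
  rhs <- as.numeric(crossprod(J, d)) / 0.1 + Prec %*% gliomatwin:::bp_mean(bp)
  m_exact <- solve(H, rhs)
  expect_equal(res$m_map, as.numeric(m_exact), tolerance = 1e-6)
})

test_that("MAP estimation improves the misfit with a monotone cost history", {
  sp <- small_inverse_problem()
  fx <- sp$fixture
  bp <- small_prior()
  res <- solve_map(sp$ip, bp, settings = newtoncg_settings(max_newton = 25, grad_rtol = 1e-4))
  expect_true(all(diff(res$history$cost) <= 1e-10))
  mis_map <- tail(res$history$misfit, 1)
  mis_prior_mean <- gliomatwin:::ip_cost(sp$ip, gliomatwin:::bp_mean(bp))
  expect_lt(mis_map, mis_prior_mean)
  expect_s3_class(tidy(res), "data.frame")
  expect_equal(nrow(glance(res)), 1L)
})

test_that("Newton iteration counts are stable under mesh refinement", {
  # same continuous problem at h and h/1.5: uniform-parameter recovery
  counts <- vapply(c(7, 4.7), function(h) {
    dom <- build_synthetic_brain(2, radius_mm = 30, h_mm = h)
    n <- nrow(dom$vertices)
    grid <- make_voxel_grid(dom, 6)
    sch <- treatment_schedule()
    fs <- forward_settings(0, 6, dt = 1)
    u0 <- pmin(0.8 * exp(-rowSums(dom$vertices^2) / 60), 1)
    m_true <- parameter_field(rep(log(0.3), n), rep(log(0.15), n))
    traj <- solve_forward(dom, u0, m_true, sch, fs)
    dd <- vapply(c(3, 6), function(t) observe(gliomatwin:::trajectory_state(traj, t), grid),
                 numeric(grid$nd))
    obs <- observation_set(c(3, 6), dd, 0.02^2, grid)
    ip <- calibration_problem(dom, obs, u0, sch, fs)
    bp <- default_block_prior(dom, rho_mm = 48)
    res <- solve_map(ip, bp, settings = newtoncg_settings(grad_rtol = 1e-4))
    res$newton_iters
  }, integer(1))
  expect_lte(abs(diff(counts)), 2L)
})
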