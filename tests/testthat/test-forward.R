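# Forward model: LQ radiotherapy response, chemotherapy rate, implicit-Euler
# stepping, conservation and invariant-region properties.

test_that("linear-quadratic surviving fraction matches direct evaluation", {
  expect_equal(surviving_fraction_lq(0, 0.025, 0.0025), 1.0)
  # 2 Gy fraction at alpha = 0.025/Gy, alpha/beta = 10 Gy
  expect_equal(surviving_fraction_lq(2, 0.025, 0.025 / 10),
               exp(-0.025 * 2 - 0.0025 * 4))
  expect_lt(surviving_fraction_lq(4, 0.025, 0.0025),
            surviving_fraction_lq(2, 0.025, 0.0025))
  expect_error(surviving_fraction_lq(-1, 0.025, 0.0025), "nonnegative")
})

test_that("chemotherapy factor follows the decaying-exponential model", {
  sch <- treatment_schedule(ct_times = c(10, 11), ct_doses = 1,
                            alpha_ct = 0.9, beta_ct = 24 / 1.8)
  expect_equal(chemo_factor(9.5, sch), 0)
  sch0 <- treatment_schedule(ct_times = 0, alpha_ct = 0.9)
  expect_equal(chemo_factor(0, sch0), 0.9)
  # two doses one day apart, evaluated after the second: two-term sum
  t <- 11.5
  oracle <- 0.9 * (exp(-(24 / 1.8) * (t - 10)) + exp(-(24 / 1.8) * (t - 11)))
  expect_equal(chemo_factor(t, sch), oracle)
  # step average integrates the impulse exactly
  avg <- gliomatwin:::chemo_factor_avg(10, 11, sch)
  b <- 24 / 1.8
  expect_equal(avg, 0.9 * (1 - exp(-b)) / b)
  expect_equal(gliomatwin:::chemo_factor_avg(0, 5, sch), 0)
})

test_that("constant states are steady under pure diffusion and zero is absorbing", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  sch <- treatment_schedule()
  m <- parameter_field(rep(log(0.5), n), rep(log(1e-12), n))
  u <- step_implicit_euler(dom, rep(0.4, n), m, 1, 1, sch)
  expect_equal(as.numeric(u), rep(0.4, n), tolerance = 1e-9)
  m2 <- parameter_field(rep(log(0.5), n), rep(log(0.15), n))
  fs <- forward_settings(0, 10, dt = 1)
  traj0 <- solve_forward(dom, rep(0, n), m2, sch, fs)
  expect_equal(max(abs(traj0$states)), 0)
})

test_that("spatially uniform dynamics match the scalar implicit-Euler logistic", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  sch <- treatment_schedule()
  kappa <- 0.15
  m <- parameter_field(rep(log(0.3), n), rep(log(kappa), n))
  u0 <- 0.5
  nsteps <- 10
  fs <- forward_settings(0, nsteps, dt = 1)
  traj <- solve_forward(dom, rep(u0, n), m, sch, fs)
  # scalar oracle: solve u - uprev = dt*kappa*u*(1-u) per step by Newton
  scalar_step <- function(uprev, dt) {
    u <- uprev
    for (it in 1:100) {
      r <- (u - uprev) / dt - kappa * u * (1 - u)
      if (abs(r) < 1e-14) break
      u <- u - r / (1 / dt - kappa * (1 - 2 * u))
    }
    u
  }
  u_ref <- u0
  for (k in seq_len(nsteps)) {
    u_ref <- scalar_step(u_ref, 1)
    expect_equal(unname(traj$states[, k + 1]), rep(u_ref, n), tolerance = 1e-8)
  }
  # dt -> 0 convergence to the analytic logistic solution, first order
  exact <- u0 / (u0 + (1 - u0) * exp(-kappa * 5))
  errs <- vapply(c(1, 0.5, 0.25), function(dt) {
    fs <- forward_settings(0, 5, dt = dt)
    tr <- solve_forward(dom, rep(u0, n), m, sch, fs)
    abs(tr$final[1] - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  rates <- errs[-length(errs)] / errs[-1]
  expect_gt(min(rates), 1.6)   # ~2 for first order under halving
})

test_that("mass is conserved under pure diffusion with Neumann boundaries", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  sch <- treatment_schedule()
  m <- parameter_field(rep(log(0.4), n), rep(log(1e-14), n))
  u0 <- exp(-rowSums(dom$vertices^2) / 40)
  fs <- forward_settings(0, 20, dt = 1, newton_tol = 1e-12)
  traj <- solve_forward(dom, u0, m, sch, fs)
  mass <- function(u) sum(dom$fem$mass %*% u)
  expect_lt(abs(mass(traj$final) - mass(u0)) / mass(u0), 1e-8)
})

test_that("radiotherapy kill is multiplicative, commutes with scaling, and composes", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  sch <- treatment_schedule(rt_times = 5, rt_doses = 2)
  u <- runif(n)
  expect_equal(apply_radiotherapy(u, 0, sch), u)
  expect_equal(apply_radiotherapy(rep(0, n), 3, sch), rep(0, n))
  s <- surviving_fraction_lq(2, sch$alpha_rt, sch$beta_rt)
  expect_equal(sum(dom$fem$mass %*% apply_radiotherapy(u, 2, sch)),
               s * sum(dom$fem$mass %*% u))
  expect_equal(apply_radiotherapy(3 * u, 2, sch), 3 * apply_radiotherapy(u, 2, sch))
  # trajectory with one RT event == segment solve, kill, segment solve
  m <- parameter_field(rep(log(0.3), n), rep(log(0.15), n))
  u0 <- pmin(0.8 * exp(-rowSums(dom$vertices^2) / 50), 1)
  full <- solve_forward(dom, u0, m, sch, forward_settings(0, 10, dt = 1))
  seg1 <- solve_forward(dom, u0, m, treatment_schedule(),
                        forward_settings(0, 5, dt = 1))
  mid <- s * seg1$final
  seg2 <- solve_forward(dom, mid, m, treatment_schedule(),
                        forward_settings(5, 10, dt = 1))
  expect_equal(full$final, seg2$final, tolerance = 1e-9)
})

test_that("the state stays within [0,1] up to tolerance on the virtual patient", {
  vp <- twin_generate(list(imaging = "fortnightly", coarse_h_mm = 5, fine_h_mm = 3.5))
  fine <- vp$fine_domain
  fs <- forward_settings(0, vp$spec$t_pred, dt = 1)
  traj <- solve_forward(fine, vp$truth$u0_fine, vp$truth$m, vp$schedule, fs)
  expect_gt(min(traj$states), -1e-6)
  expect_lt(max(traj$states), 1 + 1e-6)
})

test_that("observe extracts the unmasked voxel vector", {
  dom <- small_domain()
  g <- make_voxel_grid(dom, 4)
  f <- dom$vertices[, 2]
  expect_equal(observe(f, g, dom), unname(g$centers[, 2]), tolerance = 1e-12)
  other <- build_synthetic_brain(2, 24, 5)
  expect_error(observe(rep(1, nrow(other$vertices)), g, other), "mesh|grid")
})

test_that("the forward model and adjoint gradient are dimension-generic (3-D ball)", {
  dom <- build_synthetic_brain(3, radius_mm = 20, h_mm = 4.8)
  n <- nrow(dom$vertices)
  grid <- make_voxel_grid(dom, 5)
  sch <- treatment_schedule(rt_times = 2, rt_doses = 4, ct_times = 1)
  fs <- forward_settings(0, 4, dt = 1)
  u0 <- pmin(0.8 * exp(-rowSums(dom$vertices^2) / 60), 1)
  m <- parameter_field(rep(log(0.3), n), rep(log(0.15), n))
  traj <- solve_forward(dom, u0, m, sch, fs)
  expect_true(all(is.finite(traj$final)))
  expect_gt(min(traj$states), -1e-9)
  dd <- vapply(c(2, 4), function(t) observe(gliomatwin:::trajectory_state(traj, t), grid),
               numeric(grid$nd))
  obs <- observation_set(c(2, 4), dd + 0.02, 0.02^2, grid)
  ip <- calibration_problem(dom, obs, u0, sch, fs)
  mv <- gliomatwin:::pf_concat(m) + 0.05
  lin <- gliomatwin:::ip_linearize(ip, mv)
  set.seed(97)
  v <- rnorm(2 * n); v <- v / sqrt(sum(v^2))
  eps <- 1e-5
  fd <- (gliomatwin:::ip_cost(ip, mv + eps * v) -
           gliomatwin:::ip_cost(ip, mv - eps * v)) / (2 * eps)
  expect_lt(abs(fd - sum(lin$grad * v)) / abs(fd), 1e-5)
})
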