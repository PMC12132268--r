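# Shared small fixtures, built once per test session.

fix_env <- new.env()

small_domain <- function(h = 4, radius = 20, ...) {
  key <- paste0("dom_", radius, "_", h, "_", paste(c(...), collapse = "_"))
  if (is.null(fix_env[[key]])) {
    fix_env[[key]] <- build_synthetic_brain(2, radius_mm = radius, h_mm = h, ...)
  }
  fix_env[[key]]
}

# Small PDE inverse problem with RT/chemo events in the window, used by the
# adjoint, Hessian, and Laplace tests.
small_inverse_problem <- function(noise_seed = 1, with_noise = TRUE) {
  if (is.null(fix_env$sip)) {
    dom <- small_domain()
    n <- nrow(dom$vertices)
    grid <- make_voxel_grid(dom, 4)
    sch <- treatment_schedule(rt_times = c(3, 5), rt_doses = 4,
                              ct_times = c(2, 4))
    fs <- forward_settings(0, 8, dt = 1)
    u0 <- pmin(0.8 * exp(-rowSums(dom$vertices^2) / 50), 1)
    m_true <- parameter_field(rep(log(0.3), n), rep(log(0.15), n))
    traj <- solve_forward(dom, u0, m_true, sch, fs)
    tobs <- c(2, 5, 8)
    clean <- vapply(tobs, function(t) observe(gliomatwin:::trajectory_state(traj, t), grid),
                    numeric(grid$nd))
    noisy <- clean + gliomatwin:::with_seed(noise_seed,
      matrix(stats::rnorm(length(clean), sd = 0.02), nrow(clean)))
    fix_env$sip <- list(domain = dom, grid = grid, schedule = sch, settings = fs,
                        u0 = u0, m_true = m_true, clean = clean, noisy = noisy,
                        times = tobs)
  }
  s <- fix_env$sip
  data <- if (with_noise) s$noisy else s$clean
  obs <- observation_set(s$times, data, 0.02^2, s$grid)
  ip <- calibration_problem(s$domain, obs, s$u0, s$schedule, s$settings)
  list(ip = ip, obs = obs, fixture = s)
}

small_prior <- function(rho = 60) {
  key <- paste0("prior_", rho)
  if (is.null(fix_env[[key]])) {
    fix_env[[key]] <- default_block_prior(small_domain(), rho_mm = rho)
  }
  fix_env[[key]]
}

# Dense matrix of a linear operator given by its action.
dense_operator <- function(fun, n) {
  vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    fun(e)
  }, numeric(n))
}

# Empirical correlation length: distance at which the distance-binned mean
# correlation with the center vertex first falls to 0.1 (linear interpolation).
empirical_corr_length <- function(dom, samples) {
  center <- which.min(rowSums(dom$vertices^2))
  cc <- suppressWarnings(as.numeric(cor(t(samples))[center, ]))
  r <- sqrt(rowSums(sweep(dom$vertices, 2, dom$vertices[center, ])^2))
  bins <- cut(r, breaks = seq(0, max(r), by = 2), include.lowest = TRUE)
  rb <- tapply(r, bins, mean)
  cb <- tapply(cc, bins, mean)
  ok <- is.finite(rb) & is.finite(cb)
  rb <- rb[ok]; cb <- cb[ok]
  i <- which(cb < 0.1)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  # interpolate the crossing between bins i-1 and i
  rb[i - 1] + (0.1 - cb[i - 1]) * (rb[i] - rb[i - 1]) / (cb[i] - cb[i - 1])
}

# Matern-type field prior: hyperparameter mapping, sampling statistics,
# cost/gradient, covariance/precision actions, Robin boundary treatment.

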