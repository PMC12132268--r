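# Implicit-Euler / P1-FEM solver for the reaction-diffusion growth model
# with chemoradiation source terms.

#' Parameter field on a mesh
#'
#' The inversion parameter is the pair of nodal log fields
#' `m = (mD, mkappa) = (log D, log kappa)`, which guarantees positivity of
#' the diffusivity `D = exp(mD)` (log mm^3/day, as conventionally printed)
#' and proliferation rate `kappa = exp(mkappa)` (log 1/day).
#'
#' @param mD Nodal log-diffusion values.
#' @param mkappa Nodal log-proliferation values.
#' @export
parameter_field <- function(mD, mkappa) {
  if (length(mD) != length(mkappa)) stop("mD and mkappa must live on the same mesh")
  if (!all(is.finite(mD)) || !all(is.finite(mkappa))) stop("parameter fields must be finite")
  structure(list(mD = as.numeric(mD), mkappa = as.numeric(mkappa)),
            class = "parameter_field")
}

pf_concat <- function(m) c(m$mD, m$mkappa)
pf_split <- function(v) {
  n <- length(v) / 2L
  parameter_field(v[seq_len(n)], v[n + seq_len(n)])
}

#' Forward solver settings
#'
#' @param t0,tf Simulation window in days.
#' @param dt Time step in days (default 1).
#' @param newton_tol Relative residual tolerance of the per-step Newton solve.
#' @param max_newton_per_step Maximum damped-Newton iterations per step.
#' @export
forward_settings <- function(t0 = 0, tf, dt = 1,
                             newton_tol = 1e-10, max_newton_per_step = 25L) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(newton_tol, "newton_tol", positive = TRUE)
  if (tf <= t0) stop("tf must exceed t0")
  structure(list(t0 = t0, tf = tf, dt = dt, newton_tol = newton_tol,
                 max_newton_per_step = as.integer(max_newton_per_step)),
            class = "forward_settings")
}

# Residual and Jacobian of one implicit-Euler step:
#   R(u) = M (u - u_prev)/dt + K(mD) u - M [kappa u (1-u)] + cbar M u
# With the (default) lumped mass the reaction/time terms are diagonal, the
# Jacobian is symmetric, and assembly reduces to a diagonal update of K.
step_residual <- function(u, u_prev, Mm, K, kappa, cbar, dt, mdiag = NULL) {
  w <- (u - u_prev) / dt + cbar * u - kappa * u * (1 - u)
  if (!is.null(mdiag)) {
    sym_spmv(K, u) + mdiag * w
  } else {
    as.numeric(Mm %*% w + K %*% u)
  }
}

step_jacobian <- function(u, Mm, K, kappa, cbar, dt, mdiag = NULL, dpos = NULL) {
  w <- 1 / dt + cbar - kappa * (1 - 2 * u)
  if (!is.null(mdiag)) {
    if (is.null(dpos)) dpos <- diag_positions(K)
    J <- K
    # in-place diagonal update of the CSC value slot (pattern unchanged)
    methods::slot(J, "x", check = FALSE) <- {
      x <- K@x; x[dpos] <- x[dpos] + mdiag * w; x
    }
    J
  } else {
    Mm %*% Matrix::Diagonal(x = w) + K
  }
}

# positions of the diagonal entries inside a dgCMatrix value slot (P1
# stiffness matrices always carry an explicit diagonal)
diag_positions <- function(K) {
  col <- rep.int(seq_len(ncol(K)), diff(K@p))
  pos <- which(K@i + 1L == col)
  if (length(pos) != ncol(K)) stop("matrix lacks explicit diagonal entries")
  pos
}

mass_diag_or_null <- function(Mm) {
  if (methods::is(Mm, "diagonalMatrix")) Mm@x else NULL
}

domain_mass_diag <- function(domain) domain$fem$mass_diag

#' Advance the state by one implicit-Euler step
#'
#' Solves the nonlinear algebraic system of a single backward-Euler step of
#' the reaction-diffusion model by damped Newton iteration with the analytic
#' Jacobian. The chemotherapy rate is the exact time average of the decaying
#' exponential over the step, treated implicitly.
#'
#' @param domain A `tissue_domain`.
#' @param u_prev State at the previous time (nodal vector).
#' @param m A [parameter_field()].
#' @param t_next Target time of the step (days).
#' @param dt Step size (days).
#' @param schedule A [treatment_schedule()].
#' @param settings A [forward_settings()] (only the Newton controls are used).
#' @return The nodal state at `t_next` (before any radiotherapy kill at that
#'   time), with attributes `newton_iters` and `residual`.
#' @export
step_implicit_euler <- function(domain, u_prev, m, t_next, dt, schedule,
                                settings = forward_settings(0, t_next, dt = dt)) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(is.finite(u_prev))) stop("u_prev must be finite")
  Mm <- domain$fem$mass
  K <- stiffness_matrix(domain, cell_diffusivity(domain, m$mD))
  kappa <- exp(m$mkappa)
  cbar <- chemo_factor_avg(t_next - dt, t_next, schedule)
  newton_step(u_prev, u_prev, Mm, K, kappa, cbar, dt,
              tol = settings$newton_tol, maxit = settings$max_newton_per_step,
              mdiag = domain_mass_diag(domain))
}

newton_step <- function(u0, u_prev, Mm, K, kappa, cbar, dt, tol, maxit,
                        mdiag = mass_diag_or_null(Mm),
                        dpos = if (!is.null(mdiag)) diag_positions(K)) {
  u <- u0
  r <- step_residual(u, u_prev, Mm, K, kappa, cbar, dt, mdiag)
  rn0 <- sqrt(sum(r^2))
  floor_tol <- 1e-13 * max(1, sqrt(sum(u_prev^2)))
  hist <- numeric(0)
  fact <- NULL
  prev_rn <- Inf
  for (it in seq_len(maxit)) {
    rn <- sqrt(sum(r^2)); hist <- c(hist, rn)
    if (rn <= max(tol * rn0, floor_tol)) {
      return(structure(u, newton_iters = it - 1L, residual = rn))
    }
    # chord iteration: refactor the Jacobian only while progress is slow
    if (is.null(fact) || rn > 0.3 * prev_rn) {
      fact <- Matrix::lu(step_jacobian(u, Mm, K, kappa, cbar, dt, mdiag, dpos))
    }
    prev_rn <- rn
    du <- as.numeric(Matrix::solve(fact, -r))
    alpha <- 1
    for (ls in 1:20) {
      u_try <- u + alpha * du
      r_try <- step_residual(u_try, u_prev, Mm, K, kappa, cbar, dt, mdiag)
      if (sqrt(sum(r_try^2)) < rn) break
      alpha <- alpha / 2
    }
    u <- u_try; r <- r_try
  }
  rn <- sqrt(sum(r^2))
  if (rn > max(tol * rn0, floor_tol)) {
    stop(sprintf("implicit-Euler Newton solve did not converge: residuals %s",
                 paste(signif(c(hist, rn), 4), collapse = " -> ")))
  }
  structure(u, newton_iters = maxit, residual = rn)
}

#' Apply an instantaneous radiotherapy kill
#'
#' Multiplies the state pointwise by the linear-quadratic surviving fraction
#' of the given dose — the exact integration of an impulsive kill term.
#'
#' @inheritParams step_implicit_euler
#' @param u Nodal state.
#' @param dose Dose in Gy.
#' @export
apply_radiotherapy <- function(u, dose, schedule) {
  if (dose < 0) stop("dose must be nonnegative")
  if (dose == 0 || schedule$alpha_rt <= 0) return(u)
  surviving_fraction_lq(dose, schedule$alpha_rt, schedule$beta_rt) * u
}

#' Solve the forward tumor-growth model
#'
#' Marches implicit-Euler steps over `(t0, tf]`; radiotherapy fractions are
#' applied as instantaneous multiplicative kills at their (grid-snapped)
#' times, between steps. Observation of a state is via [observe()].
#'
#' @param domain A `tissue_domain`.
#' @param u0 Initial nodal tumor volume fraction.
#' @param m A [parameter_field()].
#' @param schedule A [treatment_schedule()].
#' @param settings A [forward_settings()].
#' @param keep_states If `TRUE` (default) all step states are retained.
#' @param cache If `TRUE`, retain per-step Jacobian factorizations and
#'   pre-kill states for adjoint/Hessian computations (internal use).
#' @return A `tumor_trajectory`: list with `times`, `states` (vertices by
#'   times matrix of post-kill states), `domain` reference, and bookkeeping.
#' @export
solve_forward <- function(domain, u0, m, schedule, settings,
                          keep_states = TRUE, cache = FALSE) {
  t0 <- settings$t0; tf <- settings$tf; dt <- settings$dt
  nsteps <- as.integer(round((tf - t0) / dt))
  if (abs(t0 + nsteps * dt - tf) > 1e-8 * max(1, abs(tf))) {
    stop("(tf - t0) must be an integer multiple of dt")
  }
  n <- nrow(domain$vertices)
  if (length(u0) != n) stop("u0 does not live on the domain mesh")
  times <- t0 + dt * (0:nsteps)
  # snap RT fractions to the nearest grid time (must be within dt/2)
  s_fac <- rep(1, nsteps + 1L)
  if (length(schedule$rt_times) && schedule$alpha_rt > 0) {
    idx <- round((schedule$rt_times - t0) / dt)
    keep <- schedule$rt_times > t0 - dt / 2 & schedule$rt_times <= tf + dt / 2 &
      abs(schedule$rt_times - (t0 + idx * dt)) <= dt / 2 + 1e-9
    idx <- pmin(pmax(idx[keep], 0L), nsteps)
    sv <- surviving_fraction_lq(schedule$rt_doses[keep], schedule$alpha_rt, schedule$beta_rt)
    for (j in seq_along(idx)) s_fac[idx[j] + 1L] <- s_fac[idx[j] + 1L] * sv[j]
  }
  Mm <- domain$fem$mass
  mdiag <- domain_mass_diag(domain)
  K <- stiffness_matrix(domain, cell_diffusivity(domain, m$mD))
  dpos <- if (!is.null(mdiag)) diag_positions(K)
  kappa <- exp(m$mkappa)

  u <- as.numeric(u0) * s_fac[1L]
  states <- if (keep_states) matrix(NA_real_, n, nsteps + 1L) else NULL
  if (keep_states) states[, 1L] <- u
  u_minus <- if (cache) vector("list", nsteps) else NULL
  luA <- if (cache) vector("list", nsteps) else NULL
  luAt <- if (cache) vector("list", nsteps) else NULL
  cbars <- numeric(nsteps)
  for (k in seq_len(nsteps)) {
    cbars[k] <- chemo_factor_avg(times[k], times[k + 1L], schedule)
    um <- newton_step(u, u, Mm, K, kappa, cbars[k], dt,
                      tol = settings$newton_tol, maxit = settings$max_newton_per_step,
                      mdiag = mdiag, dpos = dpos)
    um <- as.numeric(um)
    if (any(!is.finite(um))) stop("forward solve produced non-finite state")
    if (cache) {
      A <- step_jacobian(um, Mm, K, kappa, cbars[k], dt, mdiag, dpos)
      u_minus[[k]] <- um
      luA[[k]] <- Matrix::lu(as_dgc(A))
      # with lumped mass A is symmetric: reuse the factor for adjoint solves
      luAt[[k]] <- if (!is.null(mdiag)) luA[[k]] else Matrix::lu(as_dgc(Matrix::t(A)))
    }
    u <- um * s_fac[k + 1L]
    if (keep_states) states[, k + 1L] <- u
  }
  structure(list(
    times = times, states = states, final = u, s_fac = s_fac, cbars = cbars,
    u_minus = u_minus, luA = luA, luAt = luAt,
    domain = domain, m = m, schedule = schedule, settings = settings
  ), class = "tumor_trajectory")
}

#' Extract the voxel observation vector of a state
#'
#' Applies the observation operator: P1 interpolation of the nodal state at
#' the unmasked voxel centers of the grid, returning the length-`nd` vector.
#'
#' @param u Nodal state vector.
#' @param grid A `voxel_grid` built on the state's mesh.
#' @param domain Optional `tissue_domain` for validation.
#' @export
observe <- function(u, grid, domain = NULL) {
  if (!is.null(domain)) check_grid_domain(grid, domain)
  if (length(u) != ncol(grid$B)) stop("state does not live on the grid's mesh")
  voxel_values(u, grid)
}

# State at a requested time from a trajectory (must be a grid time).
trajectory_state <- function(traj, t) {
  k <- which(abs(traj$times - t) < 1e-8)
  if (!length(k)) stop("time not on the trajectory grid")
  traj$states[, k[1L]]
}

#' @export
summary.tumor_trajectory <- function(object, threshold = 0.1, ...) {
  Mm <- object$domain$fem$mass
  ttc <- apply(object$states, 2, function(u) sum(Mm %*% (u * (u > threshold))))
  vol <- apply(object$states, 2, function(u) sum(Mm %*% as.numeric(u > threshold)))
  mass <- apply(object$states, 2, function(u) sum(Mm %*% u))
  data.frame(time = object$times, total_cellularity = ttc,
             tumor_volume = vol, total_mass = mass)
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  cat(sprintf("<tumor_trajectory> %d states over days [%.4g, %.4g], dt = %.3g\n",
              length(x$times), min(x$times), max(x$times),
              x$settings$dt))
  invisible(x)
}
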