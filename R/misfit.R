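# Observation model and data-misfit machinery: negative log-likelihood,
# discrete adjoint gradient, and misfit Hessian actions (Gauss-Newton and
# full), derived for the discretized forward model (discretize-then-optimize)
# so that adjoint gradients are exact for the implemented cost.

#' Longitudinal voxel observation set
#'
#' Voxel-resolved tumor cellularity observations `d(x_vox, t_i)` with an
#' additive Gaussian noise model of variance `noise_var` (uncorrelated across
#' voxels and times).
#'
#' @param times Acquisition times in days, strictly increasing.
#' @param data Numeric matrix, `nd` unmasked voxels by `nt` times.
#' @param noise_var Noise variance `sigma_noise^2` (positive scalar).
#' @param grid The `voxel_grid` the rows of `data` refer to.
#' @export
observation_set <- function(times, data, noise_var, grid) {
  times <- as.numeric(times)
  data <- as.matrix(data)
  if (is.unsorted(times, strictly = TRUE)) stop("observation times must be strictly increasing")
  if (ncol(data) != length(times)) stop("data must have one column per observation time")
  if (nrow(data) != grid$nd) stop("data rows must match the grid's unmasked voxel count")
  if (!all(is.finite(data))) stop("observation data must be finite")
  stopifnot_scalar(noise_var, "noise_var", positive = TRUE)
  structure(list(times = times, data = data, noise_var = noise_var, grid = grid,
                 nd = grid$nd, nt = length(times)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d voxels x %d times (days %.4g..%.4g), noise sd %.4g\n",
              x$nd, x$nt, min(x$times), max(x$times), sqrt(x$noise_var)))
  invisible(x)
}

# Bundle of everything needed to evaluate the PDE-constrained misfit.
tumor_inverse_problem <- function(domain, obs, u0, schedule, settings) {
  check_grid_domain(obs$grid, domain)
  nsteps <- as.integer(round((settings$tf - settings$t0) / settings$dt))
  times <- settings$t0 + settings$dt * (0:nsteps)
  oidx <- vapply(obs$times, function(t) {
    k <- which(abs(times - t) < 1e-8)
    if (!length(k)) stop("observation time ", t, " is not a forward-solver grid time")
    k[1L]
  }, integer(1))
  if (any(oidx == 1L)) stop("observations must lie strictly after t0")
  structure(list(domain = domain, obs = obs, u0 = as.numeric(u0),
                 schedule = schedule, settings = settings,
                 obs_state_idx = oidx, nsteps = nsteps),
            class = "tumor_inverse_problem")
}

# Sum of per-element bilinear forms p' K_e u for the unit-coefficient
# stiffness, one value per element.
elem_bilinear <- function(dom, p, u) {
  cells <- dom$cells
  nvp <- dom$fem$nvp
  Sx <- dom$fem$K_index$x_geom
  pe <- matrix(p[cells], ncol = nvp)
  ue <- matrix(u[cells], ncol = nvp)
  out <- numeric(nrow(cells))
  for (a in seq_len(nvp)) for (b in seq_len(nvp)) {
    out <- out + pe[, a] * Sx[, (b - 1L) * nvp + a] * ue[, b]
  }
  out
}

# Scatter per-element values to vertices: out[v] = sum over cells containing v.
scatter_cells_to_vertices <- function(dom, val) {
  nvp <- dom$fem$nvp
  out <- numeric(nrow(dom$vertices))
  rs <- rowsum(rep(val, nvp), group = as.vector(dom$cells))
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

# Stiffness-derivative matrix K'(vD) for a nodal direction vD:
# per-element coefficient is the vertex mean of exp(mD) * vD.
stiffness_derivative <- function(dom, mD, vD) {
  w <- exp(mD) * vD
  stiffness_matrix(dom, rowMeans(matrix(w[dom$cells], ncol = dom$fem$nvp)))
}

misfit_cost_from_traj <- function(ip, traj) {
  B <- ip$obs$grid$B
  resid <- matrix(0, ip$obs$nd, ip$obs$nt)
  for (i in seq_len(ip$obs$nt)) {
    u <- traj$states[, ip$obs_state_idx[i]]
    resid[, i] <- as.numeric(B %*% u) - ip$obs$data[, i]
  }
  list(cost = 0.5 * sum(resid^2) / ip$obs$noise_var, resid = resid)
}

# Full linearization at a field pair m: forward solve with cached per-step
# Jacobian factorizations, residuals, adjoint trajectory, and the misfit
# gradient with respect to the (mD, mkappa) fields.
linearize_misfit <- function(ip, m) {
  dom <- ip$domain
  traj <- solve_forward(dom, ip$u0, m, ip$schedule, ip$settings, cache = TRUE)
  mc <- misfit_cost_from_traj(ip, traj)
  n <- nrow(dom$vertices)
  nsteps <- ip$nsteps
  Mm <- dom$fem$mass
  md <- dom$fem$mass_diag
  dt <- ip$settings$dt
  B <- ip$obs$grid$B
  sig2 <- ip$obs$noise_var
  obs_of_step <- integer(nsteps)               # 0 = unobserved
  obs_of_step[ip$obs_state_idx - 1L] <- seq_len(ip$obs$nt)
  kappa <- exp(m$mkappa); expD <- exp(m$mD)

  # adjoint recursion: A_k' p_k = s_k (M/dt) p_{k+1} - s_k * B'(r_k)/sig2
  p <- matrix(0, n, nsteps)
  p_next <- numeric(n)
  for (k in rev(seq_len(nsteps))) {
    s_k <- traj$s_fac[k + 1L]
    rhs <- s_k * mass_mult(Mm, p_next, md) / dt
    if (obs_of_step[k] > 0L) {
      rhs <- rhs - s_k * as.numeric(Matrix::t(B) %*% mc$resid[, obs_of_step[k]]) / sig2
    }
    p[, k] <- as.numeric(Matrix::solve(traj$luAt[[k]], rhs))
    p_next <- p[, k]
  }

  # gradient contraction over steps
  gD <- numeric(n); gk <- numeric(n)
  for (k in seq_len(nsteps)) {
    um <- traj$u_minus[[k]]
    gD <- gD + scatter_cells_to_vertices(dom, elem_bilinear(dom, p[, k], um))
    gk <- gk - um * (1 - um) * mass_mult(Mm, p[, k], md)
  }
  gD <- gD * expD / dom$fem$nvp
  gk <- gk * kappa

  structure(list(ip = ip, m = m, traj = traj, resid = mc$resid, cost = mc$cost,
                 p = p, obs_of_step = obs_of_step,
                 grad = c(gD, gk), kappa = kappa, expD = expD),
            class = "misfit_linearization")
}

# Misfit Hessian action in field space at the linearization point.
# mode "gauss_newton" keeps only the observation-chain terms (PSD by
# construction); "full" adds the second-order state and cross terms that
# involve the adjoint.
misfit_hess_action <- function(lin, v, mode = c("gauss_newton", "full")) {
  mode <- match.arg(mode)
  ip <- lin$ip; dom <- ip$domain; traj <- lin$traj
  n <- nrow(dom$vertices)
  nsteps <- ip$nsteps
  vD <- v[seq_len(n)]; vk <- v[n + seq_len(n)]
  Mm <- dom$fem$mass
  md <- dom$fem$mass_diag
  dt <- ip$settings$dt
  B <- ip$obs$grid$B
  sig2 <- ip$obs$noise_var
  kappa <- lin$kappa
  Kp <- stiffness_derivative(dom, lin$m$mD, vD)

  # incremental forward: A_k du_k = (M/dt) du_{k-1} - C_k v ; du_k^+ = s_k du_k
  du_minus <- matrix(0, n, nsteps)
  du_prev <- numeric(n)
  for (k in seq_len(nsteps)) {
    um <- traj$u_minus[[k]]
    Cv <- sym_spmv(Kp, um) - mass_mult(Mm, kappa * vk * um * (1 - um), md)
    rhs <- mass_mult(Mm, du_prev, md) / dt - Cv
    du_minus[, k] <- as.numeric(Matrix::solve(traj$luA[[k]], rhs))
    du_prev <- traj$s_fac[k + 1L] * du_minus[, k]
  }

  # incremental adjoint
  q <- matrix(0, n, nsteps)
  q_next <- numeric(n)
  for (k in rev(seq_len(nsteps))) {
    s_k <- traj$s_fac[k + 1L]
    rhs <- s_k * mass_mult(Mm, q_next, md) / dt
    if (lin$obs_of_step[k] > 0L) {
      du_post <- s_k * du_minus[, k]
      rhs <- rhs - s_k * as.numeric(Matrix::t(B) %*% (B %*% du_post)) / sig2
    }
    if (mode == "full") {
      um <- traj$u_minus[[k]]
      Mp <- mass_mult(Mm, lin$p[, k], md)
      rhs <- rhs - sym_spmv(Kp, lin$p[, k]) -
        2 * kappa * du_minus[, k] * Mp +
        kappa * vk * (1 - 2 * um) * Mp
    }
    q[, k] <- as.numeric(Matrix::solve(traj$luAt[[k]], rhs))
    q_next <- q[, k]
  }

  hD <- numeric(n); hk <- numeric(n)
  for (k in seq_len(nsteps)) {
    um <- traj$u_minus[[k]]
    hD <- hD + scatter_cells_to_vertices(dom, elem_bilinear(dom, q[, k], um))
    hk <- hk - um * (1 - um) * mass_mult(Mm, q[, k], md)
    if (mode == "full") {
      Mp <- mass_mult(Mm, lin$p[, k], md)
      bil_pu <- scatter_cells_to_vertices(dom, elem_bilinear(dom, lin$p[, k], um))
      bil_pdu <- scatter_cells_to_vertices(dom, elem_bilinear(dom, lin$p[, k], du_minus[, k]))
      hD <- hD + vD * bil_pu + bil_pdu
      hk <- hk - vk * um * (1 - um) * Mp - (1 - 2 * um) * du_minus[, k] * Mp
    }
  }
  hD <- hD * lin$expD / dom$fem$nvp
  hk <- hk * kappa
  c(hD, hk)
}

#' Negative log-likelihood (data misfit)
#'
#' Runs the forward model and evaluates
#' `Phi(m; d) = sum_i ||F_i(m) - d_i||^2 / (2 sigma_noise^2)` over the
#' observation times.
#'
#' @param domain A `tissue_domain`.
#' @param m A [parameter_field()].
#' @param obs An [observation_set()].
#' @param u0 Initial nodal state.
#' @param schedule A [treatment_schedule()].
#' @param settings A [forward_settings()] whose window contains all
#'   observation times.
#' @export
neg_log_likelihood <- function(domain, m, obs, u0, schedule, settings) {
  ip <- tumor_inverse_problem(domain, obs, u0, schedule, settings)
  traj <- solve_forward(domain, u0, m, schedule, settings)
  misfit_cost_from_traj(ip, traj)$cost
}

# --- linear forward-map fixture ------------------------------------------

# F(m) = J m with data d and noise variance sig2: the quadratic misfit whose
# Laplace approximation is exact. Used as the verification fixture for the
# optimizer and the low-rank posterior machinery.
linear_inverse_problem <- function(J, d, noise_var) {
  structure(list(J = as.matrix(J), d = as.numeric(d), noise_var = noise_var,
                 npar = ncol(J)),
            class = "linear_inverse_problem")
}

linearize_linear <- function(ip, mvec) {
  r <- as.numeric(ip$J %*% mvec) - ip$d
  structure(list(ip = ip, cost = 0.5 * sum(r^2) / ip$noise_var,
                 grad = as.numeric(crossprod(ip$J, r)) / ip$noise_var),
            class = "linear_linearization")
}

# --- common misfit interface ---------------------------------------------

ip_npar_fields <- function(ip) {
  if (inherits(ip, "tumor_inverse_problem")) 2L * nrow(ip$domain$vertices) else ip$npar
}

ip_linearize <- function(ip, m_fields) {
  if (inherits(ip, "tumor_inverse_problem")) {
    linearize_misfit(ip, pf_split(m_fields))
  } else {
    linearize_linear(ip, m_fields)
  }
}

ip_cost <- function(ip, m_fields) {
  if (inherits(ip, "tumor_inverse_problem")) {
    m <- pf_split(m_fields)
    traj <- solve_forward(ip$domain, ip$u0, m, ip$schedule, ip$settings)
    misfit_cost_from_traj(ip, traj)$cost
  } else {
    r <- as.numeric(ip$J %*% m_fields) - ip$d
    0.5 * sum(r^2) / ip$noise_var
  }
}

lin_hess_action <- function(lin, v, mode) {
  if (inherits(lin, "misfit_linearization")) {
    misfit_hess_action(lin, v, mode)
  } else {
    as.numeric(crossprod(lin$ip$J, lin$ip$J %*% v)) / lin$ip$noise_var
  }
}
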