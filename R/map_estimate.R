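# MAP estimation: adjoint gradients and inexact Newton-CG with
# Eisenstat-Walker forcing, Steihaug truncation, prior-covariance
# preconditioning, and Armijo backtracking.

#' Inexact Newton-CG solver settings
#'
#' @param max_newton Maximum outer Newton iterations (default 50).
#' @param grad_rtol Relative gradient-norm convergence tolerance.
#' @param grad_atol Absolute gradient-norm tolerance.
#' @param ew_eta_max Cap on the Eisenstat-Walker forcing term; the forcing at
#'   iteration k is `min(ew_eta_max, ew_c * |g_k| / |g_{k-1}|)`.
#' @param ew_c Multiplier in the forcing term.
#' @param armijo_c Sufficient-decrease constant of the backtracking search.
#' @param armijo_backtrack Step shrink factor per backtrack.
#' @param max_armijo Maximum backtracks before the solver gives up.
#' @param max_cg Per-Newton cap on inner CG iterations.
#' @param gn_iters Number of initial iterations using the Gauss-Newton
#'   Hessian before switching to the full Hessian.
#' @param verbose Print a per-iteration solver log line.
#' @export
newtoncg_settings <- function(max_newton = 50L, grad_rtol = 1e-6, grad_atol = 1e-12,
                              ew_eta_max = 0.5, ew_c = 1.0,
                              armijo_c = 1e-4, armijo_backtrack = 0.5,
                              max_armijo = 25L, max_cg = 100L, gn_iters = 5L,
                              verbose = FALSE) {
  stopifnot(grad_rtol > 0, grad_atol > 0, ew_eta_max > 0,
            armijo_c > 0, armijo_c < 1,
            armijo_backtrack > 0, armijo_backtrack < 1)
  structure(list(max_newton = as.integer(max_newton), grad_rtol = grad_rtol,
                 grad_atol = grad_atol, ew_eta_max = ew_eta_max, ew_c = ew_c,
                 armijo_c = armijo_c, armijo_backtrack = armijo_backtrack,
                 max_armijo = as.integer(max_armijo), max_cg = as.integer(max_cg),
                 gn_iters = as.integer(gn_iters), verbose = isTRUE(verbose)),
            class = "newtoncg_settings")
}

#' Negative log-posterior
#'
#' Total cost `Phi(m; d) + 1/2 ||m - m_pr||^2_{C^-1}` together with its two
#' components.
#'
#' @inheritParams neg_log_likelihood
#' @param prior A [block_prior()].
#' @return List with `total`, `misfit`, and `prior` components.
#' @export
neg_log_posterior <- function(domain, m, obs, prior, u0, schedule, settings) {
  mis <- neg_log_likelihood(domain, m, obs, u0, schedule, settings)
  mvec <- if (inherits(m, "parameter_field")) pf_concat(m) else as.numeric(m)
  pc <- prior_cost_and_grad(prior, field_inverse(prior, mvec))$cost
  list(total = mis + pc, misfit = mis, prior = pc)
}

# For identity field maps the parameter and field vectors coincide; with a
# field map the caller must already work in parameter space.
field_inverse <- function(prior, mvec) {
  if (!is.null(prior$field_map) && length(mvec) != prior$npar) {
    stop("with a field_map, supply the parameter-space vector")
  }
  mvec
}

#' Adjoint gradient of the negative log-posterior
#'
#' One forward solve plus one backward (adjoint) solve of the linearized,
#' time-reversed model with jump conditions at observation and radiotherapy
#' times; the gradient is exact for the discretized cost
#' (discretize-then-optimize).
#'
#' @inheritParams neg_log_posterior
#' @param m A [parameter_field()] (identity parameterization) or
#'   parameter-space vector.
#' @return Numeric gradient vector in parameter space; when `prior` is
#'   `NULL`, the misfit-only gradient in field space.
#' @export
gradient_adjoint <- function(domain, m, obs, prior = NULL, u0, schedule, settings) {
  ip <- tumor_inverse_problem(domain, obs, u0, schedule, settings)
  mvec <- if (inherits(m, "parameter_field")) pf_concat(m) else as.numeric(m)
  if (is.null(prior)) {
    lin <- ip_linearize(ip, mvec)
    return(lin$grad)
  }
  mf <- bp_to_fields(prior, mvec)
  lin <- ip_linearize(ip, mf)
  bp_fields_adjoint(prior, lin$grad) + prior_cost_and_grad(prior, mvec)$grad
}

#' Hessian action of the negative log-posterior
#'
#' Applies `H(m) v` via incremental forward and adjoint solves about the
#' stored trajectories. Mode `"gauss_newton"` drops second-order state terms
#' and is positive semidefinite; `"full"` is the exact Hessian of the
#' discrete cost.
#'
#' @inheritParams gradient_adjoint
#' @param v Direction vector (parameter space, or field space when `prior`
#'   is `NULL`).
#' @param mode `"gauss_newton"` or `"full"`.
#' @param include_prior Add the prior precision contribution (default `TRUE`
#'   when a prior is given).
#' @export
hessian_action <- function(domain, m, v, obs, prior = NULL, u0, schedule, settings,
                           mode = c("gauss_newton", "full"), include_prior = !is.null(prior)) {
  mode <- match.arg(mode)
  ip <- tumor_inverse_problem(domain, obs, u0, schedule, settings)
  mvec <- if (inherits(m, "parameter_field")) pf_concat(m) else as.numeric(m)
  if (is.null(prior)) {
    lin <- ip_linearize(ip, mvec)
    return(lin_hess_action(lin, v, mode))
  }
  mf <- bp_to_fields(prior, mvec)
  lin <- ip_linearize(ip, mf)
  out <- bp_fields_adjoint(prior, lin_hess_action(lin, bp_to_fields(prior, v), mode))
  if (include_prior) out <- out + bp_precision(prior, v)
  out
}

# Parameter-space linearization wrapper shared by the solver and the GEVP.
par_linearize <- function(ip, prior, mvec) {
  lin <- ip_linearize(ip, bp_to_fields(prior, mvec))
  list(lin = lin,
       misfit = lin$cost,
       grad_misfit = bp_fields_adjoint(prior, lin$grad),
       hess = function(v, mode) {
         bp_fields_adjoint(prior, lin_hess_action(lin, bp_to_fields(prior, v), mode))
       })
}

#' Compute the MAP estimate by inexact Newton-CG
#'
#' Minimizes the negative log-posterior with prior-covariance-preconditioned
#' conjugate-gradient inner solves, Eisenstat-Walker forcing, Steihaug
#' negative-curvature truncation, and Armijo backtracking. The first
#' `gn_iters` iterations use the Gauss-Newton Hessian for robustness far
#' from the minimizer.
#'
#' @param ip A `tumor_inverse_problem` (see [calibration_problem()]) or a
#'   linear fixture.
#' @param prior A [block_prior()].
#' @param m0 Initial parameter vector; defaults to the prior mean.
#' @param settings A [newtoncg_settings()].
#' @return A `map_result` with the MAP parameter vector `m_map`, the field
#'   pair `fields`, per-iteration `history` (cost decomposition, gradient
#'   norm, CG iterations, step length), and convergence flags.
#' @export
solve_map <- function(ip, prior, m0 = NULL, settings = newtoncg_settings()) {
  m <- if (is.null(m0)) bp_mean(prior) else as.numeric(m0)
  stopifnot(length(m) == prior$npar)
  total_cost <- function(mvec, misfit = NULL) {
    mis <- if (is.null(misfit)) ip_cost(ip, bp_to_fields(prior, mvec)) else misfit
    pc <- prior_cost_and_grad(prior, mvec)
    list(total = mis + pc$cost, misfit = mis, prior = pc$cost, pgrad = pc$grad)
  }
  pl <- par_linearize(ip, prior, m)
  pc <- prior_cost_and_grad(prior, m)
  cost <- pl$misfit + pc$cost
  g <- pl$grad_misfit + pc$grad
  gnorm <- sqrt(sum(g^2)); g0norm <- gnorm; gprev <- gnorm
  hist <- list()
  converged <- FALSE
  total_cg <- 0L
  it <- 0L
  while (it < settings$max_newton) {
    if (gnorm <= max(settings$grad_rtol * g0norm, settings$grad_atol)) {
      converged <- TRUE
      break
    }
    it <- it + 1L
    mode <- if (it <= settings$gn_iters) "gauss_newton" else "full"
    eta <- if (it == 1L) settings$ew_eta_max else {
      min(settings$ew_eta_max, settings$ew_c * gnorm / gprev)
    }
    hess_total <- function(v) pl$hess(v, mode) + bp_precision(prior, v)
    cg <- pcg_steihaug(hess_total, -g, function(v) bp_covariance(prior, v),
                       eta, settings$max_cg)
    total_cg <- total_cg + cg$iters
    d <- cg$x
    gd <- sum(g * d)
    if (gd >= 0) {  # not a descent direction (can occur with the full Hessian)
      d <- -bp_covariance(prior, g)
      gd <- sum(g * d)
    }
    alpha <- 1; ok <- FALSE
    for (ls in seq_len(settings$max_armijo)) {
      m_try <- m + alpha * d
      ct <- total_cost(m_try)
      if (is.finite(ct$total) && ct$total <= cost + settings$armijo_c * alpha * gd) {
        ok <- TRUE
        break
      }
      alpha <- alpha * settings$armijo_backtrack
    }
    if (!ok) {
      hist[[it]] <- data.frame(iter = it, cost = cost, misfit = NA_real_,
                               prior = NA_real_, grad_norm = gnorm,
                               cg_iters = cg$iters, step_length = 0,
                               mode = mode)
      converged <- FALSE
      break
    }
    m <- m_try
    pl <- par_linearize(ip, prior, m)
    pc <- prior_cost_and_grad(prior, m)
    cost <- pl$misfit + pc$cost
    gprev <- gnorm
    g <- pl$grad_misfit + pc$grad
    gnorm <- sqrt(sum(g^2))
    hist[[it]] <- data.frame(iter = it, cost = cost, misfit = pl$misfit,
                             prior = pc$cost, grad_norm = gnorm,
                             cg_iters = cg$iters, step_length = alpha,
                             mode = mode)
    if (settings$verbose) {
      message(sprintf("newton %3d  cost %.6e  misfit %.6e  |g| %.3e  cg %3d  alpha %.3g  [%s]",
                      it, cost, pl$misfit, gnorm, cg$iters, alpha, mode))
    }
  }
  if (gnorm <= max(settings$grad_rtol * g0norm, settings$grad_atol)) converged <- TRUE
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(iter = integer(0), cost = numeric(0), misfit = numeric(0),
               prior = numeric(0), grad_norm = numeric(0), cg_iters = integer(0),
               step_length = numeric(0), mode = character(0))
  fields <- pf_split(bp_to_fields(prior, m))
  structure(list(m_map = m, fields = fields, cost = cost, grad_norm = gnorm,
                 history = history, converged = converged,
                 newton_iters = it, total_cg_iters = total_cg,
                 linearization = pl, prior = prior, ip = ip),
            class = "map_result")
}

# Preconditioned CG with Steihaug truncation: solves H x = b, preconditioner
# action P (an approximation of H^-1, here the prior covariance); terminates
# when the P-weighted residual norm falls below eta * initial, or on
# negative curvature (returning the current iterate, or the preconditioned
# steepest-descent direction on the first iteration).
pcg_steihaug <- function(Hfun, b, Pfun, eta, max_cg) {
  x <- numeric(length(b))
  r <- b
  z <- Pfun(r)
  p <- z
  rz <- sum(r * z)
  tol2 <- (eta^2) * rz
  iters <- 0L
  neg_curv <- FALSE
  for (i in seq_len(max_cg)) {
    Hp <- Hfun(p)
    pHp <- sum(p * Hp)
    iters <- i
    if (pHp <= 0) {
      neg_curv <- TRUE
      if (i == 1L) x <- z
      break
    }
    a <- rz / pHp
    x <- x + a * p
    r <- r - a * Hp
    z <- Pfun(r)
    rznew <- sum(r * z)
    if (rznew <= tol2) break
    p <- z + (rznew / rz) * p
    rz <- rznew
  }
  list(x = x, iters = iters, neg_curvature = neg_curv)
}

#' Assemble a calibration problem
#'
#' Convenience constructor bundling the domain, observations, initial state,
#' treatment schedule and forward settings into the inverse-problem object
#' consumed by [solve_map()] and [misfit_hessian_gevp()].
#'
#' @inheritParams neg_log_likelihood
#' @export
calibration_problem <- function(domain, obs, u0, schedule, settings) {
  tumor_inverse_problem(domain, obs, u0, schedule, settings)
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("<map_result> %s after %d Newton / %d CG iterations; cost %.6g, |grad| %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$newton_iters, x$total_cg_iters, x$cost, x$grad_norm))
  invisible(x)
}

#' @method tidy map_result
#' @export
tidy.map_result <- function(x, ...) {
  out <- x$history
  if (requireNamespace("tibble", quietly = TRUE)) tibble::as_tibble(out) else out
}

#' @method glance map_result
#' @export
glance.map_result <- function(x, ...) {
  out <- data.frame(converged = x$converged, newton_iters = x$newton_iters,
                    total_cg_iters = x$total_cg_iters, cost = x$cost,
                    grad_norm = x$grad_norm)
  if (requireNamespace("tibble", quietly = TRUE)) tibble::as_tibble(out) else out
}

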