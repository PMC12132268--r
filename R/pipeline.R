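# End-to-end pipeline wrappers: generate -> calibrate -> predict, driven by
# a single configuration list, plus plotting helpers for the standard
# figures (spectra, pushforward distributions, burden curves).

#' Generate a virtual-patient data bundle from a configuration
#'
#' Thin wrapper over [generate_observations()]: entries of `config`
#' override the defaults of [virtual_patient_spec()].
#'
#' @param config Named list of [virtual_patient_spec()] overrides.
#' @export
twin_generate <- function(config = list()) {
  spec <- do.call(virtual_patient_spec, config)
  generate_observations(spec)
}

#' Calibrate the digital twin to a virtual patient's observations
#'
#' Runs MAP estimation ([solve_map()]) followed by the randomized
#' generalized eigensolve ([misfit_hessian_gevp()]) and assembles the
#' low-rank Laplace posterior.
#'
#' @param vp A `virtual_patient_data` bundle (or any list with `domain`,
#'   `obs`, `u0`, `schedule`, `settings`).
#' @param prior A [block_prior()]; defaults to the study configuration
#'   ([default_block_prior()]) on the inversion mesh.
#' @param nk_settings A [newtoncg_settings()].
#' @param k,p Retained rank and oversampling of the eigensolve.
#' @param seed Seed for the randomized eigensolver.
#' @return List with `map` (a `map_result`), `pairs` (an `eigen_pair_set`),
#'   `posterior` (a [laplace_posterior()]), and `prior`.
#' @export
twin_calibrate <- function(vp, prior = NULL,
                           nk_settings = newtoncg_settings(grad_rtol = 1e-5),
                           k = 50L, p = 10L, seed = 1L) {
  if (is.null(prior)) prior <- default_block_prior(vp$domain)
  ip <- calibration_problem(vp$domain, vp$obs, vp$u0, vp$schedule, vp$settings)
  map <- solve_map(ip, prior, settings = nk_settings)
  pairs <- misfit_hessian_gevp(ip, prior, map$m_map, k = k, p = p, seed = seed)
  list(map = map, pairs = pairs,
       posterior = laplace_posterior(map$m_map, pairs, prior), prior = prior)
}

#' Push prior and posterior uncertainty to prediction-time QoIs
#'
#' Draws samples from the prior and the Laplace posterior, propagates each
#' through the prediction window (from the state estimated at the last
#' image to the prediction day), evaluates QoIs against the stored truth,
#' and compares the two pushforward distributions per QoI with the
#' Mann-Whitney U-test (location) and Levene's test (spread).
#'
#' @param vp A `virtual_patient_data` bundle.
#' @param calib Result of [twin_calibrate()].
#' @param n Samples per distribution (the reference study uses 500).
#' @param seed Base seed; prior and posterior draws use `seed` and `seed + 1`.
#' @param qois QoIs to evaluate, see [pushforward_qoi()].
#' @return List with `records` (per-sample QoI data frame) and `tests`
#'   (per-QoI p-values, prior vs posterior).
#' @export
twin_predict <- function(vp, calib, n = 500L, seed = 1L,
                         qois = c("rel_error_volume", "ccc")) {
  spec <- vp$spec
  truth <- list(tumor_volume = vp$truth$tumor_volume,
                total_cellularity = vp$truth$total_cellularity,
                voxel_values = vp$truth$voxel_values, grid = vp$grid)
  args <- list(n = n, domain = vp$domain, u0 = vp$u0_pred,
               t0 = spec$t_end_imaging, t_pred = spec$t_pred,
               schedule = vp$schedule, dt = spec$dt, qois = qois,
               truth = truth, threshold = spec$threshold)
  rec_prior <- do.call(pushforward_qoi,
                       c(list(dist = calib$prior, seed = seed), args))
  rec_post <- do.call(pushforward_qoi,
                      c(list(dist = calib$posterior, seed = seed + 1L), args))
  records <- rbind(rec_prior, rec_post)
  tests <- do.call(rbind, lapply(qois, function(q) {
    a <- rec_post$value[rec_post$qoi == q]
    b <- rec_prior$value[rec_prior$qoi == q]
    pv <- compare_distributions(a, b)
    data.frame(qoi = q, location_p = pv[["location_p"]],
               variance_p = pv[["variance_p"]])
  }))
  list(records = records, tests = tests)
}

# --- plotting -------------------------------------------------------------

#' @method autoplot eigen_pair_set
#' @export
autoplot.eigen_pair_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = pmax(.data$eigenvalue, .Machine$double.eps))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "eigenvalue index", y = "eigenvalue",
                  title = "Spectrum of the prior-preconditioned data-misfit Hessian")
}

#' @method autoplot tumor_trajectory
#' @export
autoplot.tumor_trajectory <- function(object, threshold = 0.1, ...) {
  df <- summary(object, threshold = threshold)
  long <- data.frame(
    time = rep(df$time, 2),
    value = c(df$total_cellularity, df$tumor_volume),
    quantity = rep(c("total cellularity", "tumor volume"), each = nrow(df))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL, title = "Tumor burden over time")
}

#' Plot pushforward QoI distributions by provenance
#'
#' Density plot of per-sample QoI values, faceted by QoI and colored by
#' provenance (prior vs Laplace posterior), in the style of the standard
#' predictive-distribution comparison figures.
#'
#' @param records Data frame from [twin_predict()] or [pushforward_qoi()].
#' @export
plot_pushforward <- function(records) {
  ggplot2::ggplot(records[is.finite(records$value), ],
                  ggplot2::aes(x = .data$value, fill = .data$provenance)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~qoi, scales = "free") +
    ggplot2::labs(x = "QoI value", y = "density", fill = NULL)
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL
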