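# Chemoradiation treatment schedules and response models.

#' Define a chemoradiation treatment schedule
#'
#' Radiotherapy acts as an instantaneous multiplicative cell kill at each
#' fraction time, with the surviving fraction given by the linear-quadratic
#' model ([surviving_fraction_lq()]); chemotherapy acts as a decaying
#' exponential death-rate term following each administration
#' ([chemo_factor()]).
#'
#' @param rt_times Days at which radiotherapy fractions are delivered.
#' @param rt_doses Dose per fraction in Gy (recycled to `length(rt_times)`).
#' @param alpha_rt LQ radiosensitivity alpha, 1/Gy.
#' @param alpha_over_beta LQ alpha/beta ratio in Gy; `beta_rt` is derived as
#'   `alpha_rt / alpha_over_beta`.
#' @param ct_times Days at which chemotherapy is administered.
#' @param ct_doses Dimensionless dose magnitude per administration (default 1).
#' @param alpha_ct Dimensionless chemotherapy efficacy.
#' @param beta_ct Clearance rate in 1/day. The default corresponds to the
#'   1.8-hour clearance time of temozolomide, i.e. `24 / 1.8` per day.
#' @return A `treatment_schedule` object.
#' @export
treatment_schedule <- function(rt_times = numeric(0), rt_doses = 2,
                               alpha_rt = 0.025, alpha_over_beta = 10,
                               ct_times = numeric(0), ct_doses = 1,
                               alpha_ct = 0.9, beta_ct = 24 / 1.8) {
  rt_times <- as.numeric(rt_times); ct_times <- as.numeric(ct_times)
  rt_doses <- rep_len(as.numeric(rt_doses), length(rt_times))
  ct_doses <- rep_len(as.numeric(ct_doses), length(ct_times))
  if (any(rt_doses < 0) || any(ct_doses < 0)) stop("doses must be nonnegative")
  if (alpha_rt < 0 || alpha_ct < 0 || beta_ct < 0) stop("rates must be nonnegative")
  if (alpha_rt > 0 && alpha_over_beta <= 0) stop("alpha_over_beta must be positive")
  o <- order(rt_times); rt_times <- rt_times[o]; rt_doses <- rt_doses[o]
  o <- order(ct_times); ct_times <- ct_times[o]; ct_doses <- ct_doses[o]
  structure(list(
    rt_times = rt_times, rt_doses = rt_doses,
    alpha_rt = alpha_rt, alpha_over_beta = alpha_over_beta,
    beta_rt = if (alpha_rt > 0) alpha_rt / alpha_over_beta else 0,
    ct_times = ct_times, ct_doses = ct_doses,
    alpha_ct = alpha_ct, beta_ct = beta_ct
  ), class = "treatment_schedule")
}

#' Stupp-like chemoradiation schedule
#'
#' Standard-of-care fractionation for high-grade glioma: 2 Gy radiotherapy
#' fractions on weekdays over a six-week block with concurrent daily
#' chemotherapy, preceded and followed by untreated windows.
#'
#' @param start_day First treatment day (end of the untreated lead-in).
#' @param weeks Length of the chemoradiation block in weeks.
#' @param rt_dose Dose per fraction, Gy.
#' @param weekdays_only If `TRUE` (default) radiotherapy is delivered 5 days
#'   per week; chemotherapy is daily regardless.
#' @param ... Passed to [treatment_schedule()] (radio/chemo sensitivities).
#' @export
stupp_schedule <- function(start_day = 14, weeks = 6, rt_dose = 2,
                           weekdays_only = TRUE, ...) {
  days <- start_day + seq_len(7 * weeks) - 1L
  rel <- (days - start_day) %% 7
  rt_days <- if (weekdays_only) days[rel < 5] else days
  treatment_schedule(rt_times = rt_days, rt_doses = rt_dose,
                     ct_times = days, ct_doses = 1, ...)
}

#' Linear-quadratic surviving fraction
#'
#' `S(z) = exp(-alpha * z - beta * z^2)`, the fraction of tumor cells
#' surviving an instantaneous radiotherapy dose `z`.
#'
#' @param dose Dose in Gy (nonnegative).
#' @param alpha_rt Radiosensitivity alpha in 1/Gy.
#' @param beta_rt Radiosensitivity beta in 1/Gy^2.
#' @return Surviving fraction in (0, 1].
#' @examples
#' surviving_fraction_lq(2, 0.025, 0.0025)  # exp(-0.05 - 0.01)
#' @export
surviving_fraction_lq <- function(dose, alpha_rt, beta_rt) {
  if (any(dose < 0)) stop("dose must be nonnegative")
  if (any(alpha_rt <= 0) || any(beta_rt <= 0)) stop("alpha_rt and beta_rt must be positive")
  exp(-alpha_rt * dose - beta_rt * dose^2)
}

#' Chemotherapy death-rate factor
#'
#' The pointwise-in-time chemotherapy kill rate: zero before the first
#' administration, afterwards
#' `alpha_ct * sum_k z_k * exp(-beta_ct * (t - tau_k))` over administered
#' doses with `tau_k <= t` (units 1/day).
#'
#' @param t Time in days (vectorized).
#' @param schedule A `treatment_schedule`.
#' @export
chemo_factor <- function(t, schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  vapply(t, function(tt) {
    if (!is.finite(tt)) stop("t must be finite")
    k <- schedule$ct_times <= tt
    if (!any(k)) return(0)
    schedule$alpha_ct * sum(schedule$ct_doses[k] *
                              exp(-schedule$beta_ct * (tt - schedule$ct_times[k])))
  }, numeric(1))
}

# Exact time average of the chemotherapy rate over a step (t0, t1]:
# (1/dt) * integral of chemo_factor. Used by the implicit time stepper so
# that the sub-step exponential impulse is integrated exactly rather than
# sampled at a grid point.
chemo_factor_avg <- function(t0, t1, schedule) {
  dt <- t1 - t0
  if (dt <= 0) stop("t1 must exceed t0")
  k <- which(schedule$ct_times <= t1 + 1e-12)
  if (!length(k)) return(0)
  tau <- schedule$ct_times[k]; z <- schedule$ct_doses[k]
  a <- pmax(t0, tau)
  b <- schedule$beta_ct
  if (b == 0) return(schedule$alpha_ct * sum(z * (t1 - a)) / dt)
  intg <- (exp(-b * (a - tau)) - exp(-b * (t1 - tau))) / b
  schedule$alpha_ct * sum(z * intg) / dt
}

# Combined surviving fraction of all radiotherapy fractions snapped to grid
# time t (within half a step).
rt_survival_at <- function(t, dt, schedule) {
  k <- abs(schedule$rt_times - t) <= dt / 2 - 1e-12 |
    abs(schedule$rt_times - t) < 1e-9
  if (!any(k) || schedule$alpha_rt <= 0) return(1)
  prod(surviving_fraction_lq(schedule$rt_doses[k], schedule$alpha_rt, schedule$beta_rt))
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("<treatment_schedule> %d RT fractions (%.3g Gy, alpha=%.3g/Gy, a/b=%.3g Gy), %d chemo doses (alpha_ct=%.3g, beta_ct=%.3g/day)\n",
              length(x$rt_times), if (length(x$rt_doses)) x$rt_doses[1] else 0,
              x$alpha_rt, x$alpha_over_beta,
              length(x$ct_times), x$alpha_ct, x$beta_ct))
  invisible(x)
}
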