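# Prediction map and clinical quantities of interest, plus Monte Carlo
# pushforward of parameter distributions and distribution-comparison tests.

#' Predict the tumor state at a future time
#'
#' Forward solve of the growth model over `(t0, t_pred)` from `u0`; identical
#' to the final state of [solve_forward()] over that window. With
#' `t_pred == t0` the initial state is returned unchanged.
#'
#' @param domain A `tissue_domain`.
#' @param m A [parameter_field()].
#' @param u0 Initial nodal state (e.g. estimated from the last acquired scan).
#' @param t0,t_pred Prediction window in days.
#' @param schedule A [treatment_schedule()].
#' @param dt Time step (days).
#' @param newton_tol,max_newton_per_step Per-step Newton controls.
#' @export
predict_state <- function(domain, m, u0, t0, t_pred, schedule,
                          dt = 1, newton_tol = 1e-10, max_newton_per_step = 25L) {
  if (t_pred < t0) stop("t_pred must not precede t0")
  if (t_pred == t0) return(as.numeric(u0))
  fs <- forward_settings(t0, t_pred, dt = dt, newton_tol = newton_tol,
                         max_newton_per_step = max_newton_per_step)
  solve_forward(domain, u0, m, schedule, fs, keep_states = FALSE)$final
}

#' Threshold the measurable tumor region
#'
#' `u_hat = u` where `u > threshold` and 0 elsewhere, with the associated
#' 0/1 indicator. The default threshold 0.1 is the volume fraction at which
#' a lesion is considered measurable.
#'
#' @param u Nodal (or voxel) values.
#' @param threshold Measurability threshold in (0, 1).
#' @return List with `u_hat` and `indicator`.
#' @export
measurable_region <- function(u, threshold = 0.1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  ind <- as.numeric(u > threshold)
  list(u_hat = u * ind, indicator = ind)
}

#' Total tumor cellularity
#'
#' `q_TTC = integral of u_hat over the domain` (mass-matrix quadrature of the
#' thresholded volume fraction); units mm^dim.
#'
#' @param domain A `tissue_domain`.
#' @param u Nodal state.
#' @param threshold Measurability threshold.
#' @export
total_tumor_cellularity <- function(domain, u, threshold = 0.1) {
  uh <- measurable_region(u, threshold)$u_hat
  sum(domain$fem$mass %*% uh)
}

#' Tumor volume
#'
#' `q_TV = integral of the measurable-region indicator` (mass-matrix
#' quadrature of the nodal indicator); units mm^dim.
#'
#' @inheritParams total_tumor_cellularity
#' @export
tumor_volume <- function(domain, u, threshold = 0.1) {
  ind <- measurable_region(u, threshold)$indicator
  sum(domain$fem$mass %*% ind)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`:
#' correlation with a penalty for departing from the identity line.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("x and y must have equal length >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("CCC is undefined for two constant inputs")
  2 * stats::cov(x, y) / (vx + vy + (mean(x) - mean(y))^2)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two indicator sets on the same
#' support. Two empty sets are defined to agree perfectly (Dice 1), which is
#' needed for near-remission states after therapy.
#'
#' @param a,b Logical or 0/1 vectors on the same support.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("indicator sets must share the same support")
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  2 * sum(a & b) / tot
}

#' Monte Carlo pushforward of a parameter distribution to QoIs
#'
#' Draws `n` parameter samples from the prior or a Laplace posterior, runs
#' the prediction map for each, and evaluates quantities of interest,
#' optionally against a supplied truth (for relative errors, CCC against
#' true voxel values, and Dice against the true measurable region).
#'
#' @param dist A [block_prior()] (prior-predictive) or [laplace_posterior()]
#'   (posterior-predictive).
#' @param n Number of Monte Carlo samples (the reference study uses 500).
#' @param seed Integer seed.
#' @param domain,u0,t0,t_pred,schedule,dt Prediction-map arguments
#'   (see [predict_state()]).
#' @param qois Character vector among `total_cellularity`, `tumor_volume`,
#'   `rel_error_volume`, `rel_error_cellularity`, `ccc`, `dice`.
#' @param truth Optional list with elements `tumor_volume`,
#'   `total_cellularity` (scalars), `voxel_values` (true cellularity on the
#'   grid's unmasked voxels at `t_pred`), and `grid`.
#' @param threshold Measurability threshold.
#' @param label Provenance label recorded per record; defaults to
#'   `"prior"`/`"laplace"` by distribution class.
#' @return Data frame with one row per sample and QoI: `sample_id`,
#'   `provenance`, `t_pred`, `qoi`, `value`. Individual forward failures are
#'   recorded as `NA` values rather than aborting the study.
#' @export
pushforward_qoi <- function(dist, n, seed, domain, u0, t0, t_pred, schedule,
                            dt = 1, qois = c("rel_error_volume", "ccc"),
                            truth = NULL, threshold = 0.1, label = NULL) {
  if (n < 1) stop("n must be at least 1")
  known <- c("total_cellularity", "tumor_volume", "rel_error_volume",
             "rel_error_cellularity", "ccc", "dice")
  if (!all(qois %in% known)) stop("unknown QoI requested")
  if (inherits(dist, "block_prior")) {
    samples <- bp_sample(dist, n, seed = seed)
    bp <- dist
    if (is.null(label)) label <- "prior"
  } else if (inherits(dist, "laplace_posterior")) {
    samples <- sample_laplace(dist, n, seed = seed)
    bp <- dist$prior
    if (is.null(label)) label <- "laplace"
  } else stop("dist must be a block_prior or laplace_posterior")
  needs_truth <- intersect(qois, c("rel_error_volume", "rel_error_cellularity", "ccc", "dice"))
  if (length(needs_truth) && is.null(truth)) stop("these QoIs need a supplied truth: ",
                                                  paste(needs_truth, collapse = ", "))
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    m <- pf_split(bp_to_fields(bp, samples[, j]))
    vals <- tryCatch({
      u <- predict_state(domain, m, u0, t0, t_pred, schedule, dt = dt)
      tv <- tumor_volume(domain, u, threshold)
      tc <- total_tumor_cellularity(domain, u, threshold)
      out <- c(total_cellularity = tc, tumor_volume = tv)
      if (!is.null(truth)) {
        if ("rel_error_volume" %in% qois) {
          out["rel_error_volume"] <- (tv - truth$tumor_volume) / truth$tumor_volume
        }
        if ("rel_error_cellularity" %in% qois) {
          out["rel_error_cellularity"] <- (tc - truth$total_cellularity) / truth$total_cellularity
        }
        if (any(c("ccc", "dice") %in% qois)) {
          pv <- observe(u, truth$grid)
          if ("ccc" %in% qois) out["ccc"] <- ccc(pv, truth$voxel_values)
          if ("dice" %in% qois) {
            out["dice"] <- dice(pv > threshold, truth$voxel_values > threshold)
          }
        }
      }
      out[qois]
    }, error = function(e) {
      warning("forward solve failed for sample ", j, ": ", conditionMessage(e))
      stats::setNames(rep(NA_real_, length(qois)), qois)
    })
    rows[[j]] <- data.frame(sample_id = j, provenance = label, t_pred = t_pred,
                            qoi = qois, value = unname(vals))
  }
  do.call(rbind, rows)
}

#' Compare two QoI sample distributions
#'
#' Two-sided Mann-Whitney U-test for location and Levene's test (via the
#' car package) for spread.
#'
#' @param a,b Numeric sample vectors (each of length at least 20).
#' @return Named vector `c(location_p, variance_p)`.
#' @export
compare_distributions <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 20 || length(b) < 20) stop("each sample must have at least 20 values")
  if (stats::var(c(a, b)) == 0) stop("degenerate comparison: all values identical")
  loc <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)$p.value
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lev <- car::leveneTest(c(a, b), grp)
  c(location_p = loc, variance_p = lev[["Pr(>F)"]][1])
}
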