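# Synthetic virtual patient: ground-truth tissue-dependent parameters, a
# Stupp-like chemoradiation schedule, longitudinal voxel imaging with
# additive Gaussian noise, and the inverse-crime-avoiding fine/coarse mesh
# pairing.

#' Default virtual-patient study specification
#'
#' The desk-scale synthetic study conditions: a 2-D disk "brain" of radius
#' 50 mm with an annular gray rim around a white-matter core; ground-truth
#' diffusivity 0.03 mm^3/day in gray matter and 0.3 mm^3/day in white
#' matter with proliferation rate 0.15/day everywhere; two weeks of
#' untreated growth, six weeks of concurrent chemoradiation (2 Gy weekday
#' fractions, daily chemotherapy), then another untreated month; imaging
#' daily, weekly, or fortnightly over the 12-week window; 2% additive
#' Gaussian voxel noise; prediction 30 days past the last image.
#' Radiosensitivity alpha = 0.025/Gy with alpha/beta = 10 Gy, chemotherapy
#' efficacy 0.9 with a 1.8-hour clearance time. Data are generated on a
#' fine mesh and inverted on a strictly coarser mesh so the inversion never
#' sees its own discretization.
#'
#' @param dim Spatial dimension (2 by default).
#' @param radius_mm Domain radius.
#' @param coarse_h_mm,fine_h_mm Target edge lengths of the inversion and
#'   data-generation meshes (`fine_h_mm` must be strictly smaller).
#' @param tissue_spec Gray/white partition, see [build_synthetic_brain()].
#' @param D_gray,D_white True diffusivities (mm^3/day as conventionally
#'   printed) by tissue.
#' @param kappa True proliferation rate (1/day).
#' @param seed_center,seed_widths,seed_amplitude Gaussian tumor seed.
#' @param pre_days,rt_weeks,post_days Treatment timeline (days/weeks).
#' @param pred_days Prediction horizon after the last imaging day.
#' @param imaging `"daily"`, `"weekly"`, `"fortnightly"`, or an explicit
#'   vector of imaging days.
#' @param voxel_mm Voxel spacing of the observation grid.
#' @param noise_sd Absolute noise standard deviation on the volume-fraction
#'   scale (0.02 implements 2% noise).
#' @param threshold Measurability threshold.
#' @param dt Time step in days.
#' @param alpha_rt,alpha_over_beta,rt_dose,weekdays_only,alpha_ct,beta_ct
#'   Treatment-model parameters, see [treatment_schedule()].
#' @param noise_seed Seed for the observation noise.
#' @param domain_seed Seed for the (deterministic by default) tissue labels.
#' @return A `virtual_patient_spec` list.
#' @export
virtual_patient_spec <- function(dim = 2, radius_mm = 50,
                                 coarse_h_mm = 3, fine_h_mm = 2,
                                 tissue_spec = list(type = "annulus", rim_start = 0.6),
                                 D_gray = 0.03, D_white = 0.3, kappa = 0.15,
                                 seed_center = c(18, 0), seed_widths = 6,
                                 seed_amplitude = 0.8,
                                 pre_days = 14, rt_weeks = 6, post_days = 28,
                                 pred_days = 30, imaging = "weekly",
                                 voxel_mm = 2, noise_sd = 0.02, threshold = 0.1,
                                 dt = 1, alpha_rt = 0.025, alpha_over_beta = 10,
                                 rt_dose = 2, weekdays_only = TRUE,
                                 alpha_ct = 0.9, beta_ct = 24 / 1.8,
                                 noise_seed = 101L, domain_seed = 1L) {
  if (fine_h_mm >= coarse_h_mm) {
    stop("fine_h_mm must be strictly smaller than coarse_h_mm (inverse-crime guard)")
  }
  spec <- list(dim = dim, radius_mm = radius_mm, coarse_h_mm = coarse_h_mm,
               fine_h_mm = fine_h_mm, tissue_spec = tissue_spec,
               D_gray = D_gray, D_white = D_white, kappa = kappa,
               seed_center = rep_len(seed_center, dim), seed_widths = seed_widths,
               seed_amplitude = seed_amplitude,
               pre_days = pre_days, rt_weeks = rt_weeks, post_days = post_days,
               pred_days = pred_days, imaging = imaging,
               voxel_mm = voxel_mm, noise_sd = noise_sd, threshold = threshold,
               dt = dt, alpha_rt = alpha_rt, alpha_over_beta = alpha_over_beta,
               rt_dose = rt_dose, weekdays_only = weekdays_only,
               alpha_ct = alpha_ct, beta_ct = beta_ct,
               noise_seed = as.integer(noise_seed),
               domain_seed = as.integer(domain_seed))
  spec$t_end_imaging <- pre_days + 7 * rt_weeks + post_days
  spec$t_pred <- spec$t_end_imaging + pred_days
  imaging_days <- vp_imaging_days(spec)
  if (any(imaging_days <= 0) || any(imaging_days > spec$t_end_imaging)) {
    stop("imaging days must lie within (0, end of the imaging window]")
  }
  structure(spec, class = "virtual_patient_spec")
}

vp_imaging_days <- function(spec) {
  te <- spec$t_end_imaging
  if (is.numeric(spec$imaging)) return(sort(as.numeric(spec$imaging)))
  switch(spec$imaging,
    daily = seq(1, te),
    weekly = seq(7, te, by = 7),
    fortnightly = seq(14, te, by = 14),
    stop("imaging must be 'daily', 'weekly', 'fortnightly', or a day vector")
  )
}

vp_schedule <- function(spec) {
  stupp_schedule(start_day = spec$pre_days, weeks = spec$rt_weeks,
                 rt_dose = spec$rt_dose, weekdays_only = spec$weekdays_only,
                 alpha_rt = spec$alpha_rt, alpha_over_beta = spec$alpha_over_beta,
                 alpha_ct = spec$alpha_ct, beta_ct = spec$beta_ct)
}

#' Gaussian tumor seed
#'
#' Initial condition `u0(x) = amplitude * exp(-sum_k (x_k - c_k)^2 / (2 w_k^2))`,
#' clipped at 1.
#'
#' @param domain A `tissue_domain`.
#' @param center Seed center (mm).
#' @param widths Gaussian standard deviations per axis (mm), recycled.
#' @param amplitude Peak volume fraction in (0, 1].
#' @export
seed_tumor <- function(domain, center, widths, amplitude = 0.8) {
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must lie in (0, 1]")
  d <- domain$dim
  center <- rep_len(as.numeric(center), d)
  widths <- rep_len(as.numeric(widths), d)
  if (any(widths <= 0)) stop("widths must be positive")
  dx <- sweep(domain$vertices, 2, center)
  ex <- exp(-rowSums(sweep(dx^2, 2, 2 * widths^2, `/`)))
  pmin(amplitude * ex, 1)
}

#' Tumor cellularity from apparent diffusion coefficient
#'
#' `d = (ADC_w - ADC) / (ADC_w - ADC_min)`, clipped to [0, 1]: free water
#' maps to 0, the minimum in-tumor ADC to maximal cellularity 1.
#'
#' @param adc Measured ADC values (voxel array or vector).
#' @param adc_w ADC of free water.
#' @param adc_min Minimum ADC recorded within the tumor.
#' @export
cellularity_from_adc <- function(adc, adc_w, adc_min) {
  if (adc_w <= adc_min) stop("adc_w must exceed adc_min")
  pmin(pmax((adc_w - adc) / (adc_w - adc_min), 0), 1)
}

#' Tumor cellularity from segmentation regions of interest
#'
#' Assigns volume fraction 0.8 to enhancing-tumor voxels and 0.16 to
#' non-enhancing-tumor voxels (invasive/diffuse disease), 0 elsewhere.
#'
#' @param enhancing_mask,nonenhancing_mask Disjoint logical masks.
#' @param enhancing_value,nonenhancing_value Assigned volume fractions.
#' @export
roi_cellularity <- function(enhancing_mask, nonenhancing_mask,
                            enhancing_value = 0.8, nonenhancing_value = 0.16) {
  e <- as.logical(enhancing_mask); ne <- as.logical(nonenhancing_mask)
  if (length(e) != length(ne)) stop("masks must have the same support")
  if (any(e & ne)) stop("enhancing and non-enhancing masks must be disjoint")
  out <- numeric(length(e))
  out[e] <- enhancing_value
  out[ne] <- nonenhancing_value
  dim(out) <- dim(enhancing_mask)
  out
}

# Nodal state estimated from a voxel image: interpolate to the mesh, zero
# sub-threshold values (the ROI pipeline records no cellularity outside the
# measurable lesion), clamp to [0, 1].
state_from_voxels <- function(values, grid, domain, threshold) {
  u <- voxels_to_fem(values, grid, domain)
  u[u <= threshold] <- 0
  pmin(pmax(u, 0), 1)
}

#' Generate the synthetic virtual-patient data bundle
#'
#' Solves the forward model on the fine mesh from the Gaussian tumor seed
#' with the tissue-dependent truth parameters and the Stupp-like schedule,
#' interpolates the state onto the observation voxel grid at each imaging
#' day, pollutes the voxel measurements with seeded additive Gaussian
#' noise, and packages an [observation_set()] paired with the strictly
#' coarser inversion mesh. The noise-free truth trajectory and the true
#' prediction-time state are returned for QoI scoring; initial states for
#' calibration and prediction are estimated from the day-0 and final noisy
#' images respectively.
#'
#' @param spec A [virtual_patient_spec()].
#' @return A `virtual_patient_data` list: `domain` (coarse inversion mesh),
#'   `fine_domain`, `grid`, `obs`, `u0` (calibration initial state),
#'   `u0_pred` (prediction restart state from the last image), `schedule`,
#'   `settings` (calibration window), `imaging_days`, `spec`, and `truth`
#'   (true parameter fields, trajectory summary, prediction-time state,
#'   voxel values, and QoI values).
#' @export
generate_observations <- function(spec = virtual_patient_spec()) {
  stopifnot(inherits(spec, "virtual_patient_spec"))
  fine <- build_synthetic_brain(spec$dim, spec$radius_mm, spec$fine_h_mm,
                                spec$tissue_spec, seed = spec$domain_seed)
  coarse <- build_synthetic_brain(spec$dim, spec$radius_mm, spec$coarse_h_mm,
                                  spec$tissue_spec, seed = spec$domain_seed)
  if (nrow(fine$vertices) <= nrow(coarse$vertices)) {
    stop("fine mesh must be strictly finer than the inversion mesh")
  }
  grid <- make_voxel_grid(coarse, spec$voxel_mm)
  schedule <- vp_schedule(spec)
  imaging_days <- vp_imaging_days(spec)

  m_true <- parameter_field(
    mD = ifelse(fine$tissue == 1L, log(spec$D_gray), log(spec$D_white)),
    mkappa = rep(log(spec$kappa), nrow(fine$vertices))
  )
  u0_fine <- seed_tumor(fine, spec$seed_center, spec$seed_widths, spec$seed_amplitude)
  fs_full <- forward_settings(0, spec$t_pred, dt = spec$dt)
  traj <- solve_forward(fine, u0_fine, m_true, schedule, fs_full)

  # interpolate the fine states at the coarse grid's voxel centers; the few
  # rim voxels inside the coarse polygon but outside the fine one are
  # clamped to the nearest fine cell
  Bf <- interp_matrix(fine, grid$centers, nearest = TRUE)
  clean <- vapply(c(0, imaging_days), function(t) {
    as.numeric(Bf %*% trajectory_state(traj, t))
  }, numeric(grid$nd))
  noisy <- clean + with_seed(spec$noise_seed,
                             matrix(stats::rnorm(length(clean), sd = spec$noise_sd),
                                    nrow(clean)))
  obs <- observation_set(imaging_days, noisy[, -1, drop = FALSE],
                         noise_var = max(spec$noise_sd, 1e-12)^2, grid = grid)
  u0 <- state_from_voxels(noisy[, 1], grid, coarse, spec$threshold)
  u0_pred <- state_from_voxels(noisy[, ncol(noisy)], grid, coarse, spec$threshold)

  u_pred_true <- trajectory_state(traj, spec$t_pred)
  truth <- list(
    m = m_true, u0_fine = u0_fine, trajectory = summary(traj, threshold = spec$threshold),
    u_pred = u_pred_true,
    voxel_values = as.numeric(Bf %*% u_pred_true),
    tumor_volume = tumor_volume(fine, u_pred_true, spec$threshold),
    total_cellularity = total_tumor_cellularity(fine, u_pred_true, spec$threshold),
    clean_obs = clean[, -1, drop = FALSE],
    grid = grid
  )
  structure(list(domain = coarse, fine_domain = fine, grid = grid, obs = obs,
                 u0 = u0, u0_pred = u0_pred, schedule = schedule,
                 settings = forward_settings(0, spec$t_end_imaging, dt = spec$dt),
                 imaging_days = imaging_days, spec = spec, truth = truth),
            class = "virtual_patient_data")
}

#' @export
print.virtual_patient_data <- function(x, ...) {
  cat(sprintf("<virtual_patient_data> %s imaging: %d scans over days (0, %g]; coarse mesh %d / fine mesh %d vertices; nd = %d voxels\n",
              if (is.character(x$spec$imaging)) x$spec$imaging else "custom",
              length(x$imaging_days), x$spec$t_end_imaging,
              nrow(x$domain$vertices), nrow(x$fine_domain$vertices), x$grid$nd))
  invisible(x)
}
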