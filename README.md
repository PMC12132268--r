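# gliomatwin

Predictive digital twins for high-grade glioma growth with quantified
uncertainty, at desk scale.

Clinicians monitoring a glioma see a handful of noisy MRI-derived snapshots
of tumor cell density. `gliomatwin` turns such longitudinal voxel
observations into a calibrated, patient-specific mechanistic model and
probabilistic forecasts of tumor progression. It is aimed at researchers in
computational oncology and PDE-constrained Bayesian inversion who want a
self-contained, fully testable implementation of the methodology — forward
model, adjoint machinery, scalable posterior approximation, and uncertainty
pushforward — exercised end to end on a synthetic virtual patient.

## The model and the inference

Tumor volume fraction $u(x,t)$ evolves by a semi-linear reaction-diffusion
equation with chemoradiation source terms,

$$u_t - \nabla\cdot(D\,\nabla u) - \kappa\,u(1-u) = f_{rt} + f_{ct},
\qquad \nabla u\cdot\eta = 0 \text{ on } \partial\Omega,$$

with linear-quadratic radiotherapy kills
$S_{rt}(z)=e^{-\alpha_{rt}z-\beta_{rt}z^2}$ applied impulsively at fraction
times and an exponentially clearing chemotherapy death rate. The unknowns
are the spatially varying log fields $m = (\log D, \log\kappa)$, endowed
with Matérn-type Gaussian random-field priors defined through the squared
inverse elliptic operator $(-\gamma\Delta+\delta I)^{-2}$. Given voxel
observations $d_i$ with additive Gaussian noise, the package:

1. computes the MAP estimate by adjoint-based inexact **Newton-CG**
   (Eisenstat-Walker forcing, Steihaug truncation, Armijo backtracking,
   prior-covariance preconditioning);
2. builds a **low-rank Laplace approximation** of the posterior from a
   double-pass randomized solve of the prior-preconditioned generalized
   eigenproblem $H_{misfit} v = \lambda\,\Gamma_{pr}^{-1} v$, with the
   Sherman-Morrison-Woodbury covariance
   $\Gamma_{post} = \Gamma_{pr} - \sum_j \frac{\lambda_j}{1+\lambda_j}
   v_j v_j^\top$;
3. **pushes uncertainty forward** through the prediction map to clinical
   quantities of interest — total tumor cellularity, tumor volume, Lin's
   concordance correlation, Dice overlap — and compares prior against
   posterior predictive distributions (Mann-Whitney, Levene).

The discretization is P1 finite elements (assembled in-package on disk/ball
meshes) with implicit Euler in time; gradients are exact discrete adjoints,
verified against finite differences to 1e-5.

## Worked example

Generate a synthetic patient (two untreated weeks, six weeks of Stupp-like
chemoradiation, another untreated month, weekly imaging, 2% voxel noise),
calibrate, and forecast 30 days past the last scan:

```r
library(gliomatwin)

vp  <- twin_generate(list(imaging = "weekly"))
vp
#> <virtual_patient_data> weekly imaging: 12 scans over days (0, 84];
#>   coarse mesh 919 / fine mesh 1951 vertices; nd = 1954 voxels

cal <- twin_calibrate(vp, seed = 2)
cal$map
#> <map_result> converged after 33 Newton / 218 CG iterations;
#>   cost 15806.1, |grad| 2.59

# tissue heterogeneity is recovered where the tumor is active:
active <- vp$u0_pred > 0.1
tapply(exp(cal$map$fields$mD)[active], vp$domain$tissue[active], mean)
#>     0     1
#> 0.431 0.112     # truth: 0.3 in white (0), 0.03 in gray (1)

pred <- twin_predict(vp, cal, n = 150, seed = 11)
pred$tests
#>                qoi   location_p   variance_p
#> 1 rel_error_volume 2.660099e-52 1.638674e-05
#> 2              ccc 1.079428e-50 2.166221e-37
```

The calibrated posterior concentrates sharply around the truth (posterior
predictive CCC 0.976 +/- 0.001 against 0.20 +/- 0.15 for the prior;
relative tumor-volume error 0.021 +/- 0.005 against 0.48 +/- 0.03), and
both test p-values fall far below
0.001 — patient-specific calibration demonstrably improves the forecast and
shrinks its spread. `autoplot(cal$pairs)` draws the spectrum of the
prior-preconditioned data-misfit Hessian (more frequent imaging, larger
leading eigenvalues, more informed directions);
`plot_pushforward(pred$records)` draws the predictive distributions.

Lower-level entry points mirror the pipeline stages:
`build_synthetic_brain()`, `solve_forward()`, `matern_prior()` /
`sample_prior()`, `solve_map()`, `misfit_hessian_gevp()`,
`sample_laplace()`, `pushforward_qoi()`.

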