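---
title: "Methods: mechanistic glioma modeling and scalable Bayesian calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic glioma modeling and scalable Bayesian calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gliomatwin` treats the tumor as a volume-fraction field $u(x,t) \in [0,1]$
(cell density normalized by the tissue carrying capacity) on a bounded
domain $\Omega$ and evolves it by the semi-linear reaction-diffusion
equation

$$\frac{\partial u}{\partial t} - \nabla\!\cdot(D(x)\nabla u)
  - \kappa(x)\,u(1-u) = f(u, t), \qquad
  \nabla u \cdot \eta = 0 \ \text{on } \partial\Omega ,$$

with spatially varying diffusivity $D$ (tumor invasion, preferentially
along white-matter fiber bundles) and proliferation rate $\kappa$
(logistic growth). The homogeneous Neumann condition encodes confinement
by the skull. The treatment source $f$ combines:

* **Radiotherapy** — an instantaneous kill at each fraction time. A dose
  $z$ leaves the surviving fraction
  $S_{rt}(z) = \exp(-\alpha_{rt} z - \beta_{rt} z^2)$ (linear-quadratic
  model); the impulsive source integrates exactly to the multiplicative
  update $u^+ = S_{rt} u^-$, which is how the solver applies it. This
  removes the free dimensional constant that a literal Dirac-in-time
  source would carry.
* **Chemotherapy** — an exponentially clearing death rate
  $c(t) = \alpha_{ct} \sum_k z_k e^{-\beta_{ct}(t-\tau_k)}$ for
  administrations $\tau_k \le t$. With the default clearance time of 1.8
  hours ($\beta_{ct} = 24/1.8\ \mathrm{day}^{-1}$) the impulse decays
  well inside a single 1-day step, so the stepper uses the *exact step
  average* $\bar c_n = \Delta t^{-1}\int_{t_n}^{t_{n+1}} c\,dt$ (closed
  form) rather than a point value. Point evaluation at a grid time would
  make the discrete dynamics depend discontinuously on whether a dose
  coincides with a grid point — full strength if it does, essentially
  zero if it misses by a day — which is not a property of the continuous
  model. The per-dose integrated kill is
  $\alpha_{ct} z_k / \beta_{ct} \approx 0.0675$ per unit dose at the
  defaults.

Units are mm, days, and Gy throughout.

## Discretization

Space: first-order Lagrange (P1) simplex elements for state, parameter,
and adjoint, on a concentric-ring disk triangulation (2-D, near
equilateral) or a Kuhn-triangulated cube mapped radially onto a ball
(3-D). Time: implicit Euler with a damped (chord) Newton solve per step,
relative residual tolerance $10^{-10}$, at most 25 inner iterations.

**Mass quadrature.** The package defaults to the *lumped* (diagonal) mass
matrix. With consistent mass, nodal logistic reaction and $\Delta t = 1$
day, the P1 solution develops negative undershoots at the tumor front
(front width $\sqrt{D/\kappa} \approx 0.5$–$1.4$ mm against mesh sizes of
2–3 mm); the logistic term amplifies any excursion below $u = 0$, and
over a multi-month simulation the solve diverges. On the near-acute
meshes used here the lumped scheme is monotone and keeps
$u \in [0, 1]$ to solver tolerance, which the test suite asserts over
the full virtual-patient timeline. The consistent mass remains available
(`build_synthetic_brain(lumped_mass = FALSE)`); all adjoint and Hessian
expressions are derived for whichever discretization is active, so
gradient exactness is unaffected. The state is never clipped during a
solve; bound violations would be reported, not silently repaired.

# The inverse problem

The inversion parameter is the log pair
$m = (m_D, m_\kappa) = (\log D, \log\kappa)$, which enforces positivity.
Voxel observations $d(\bar x, t_i)$ of the volume fraction (derived from
ADC maps or segmentation ROIs in a real pipeline, synthesized by the
virtual-patient generator here) enter an additive Gaussian likelihood
with $\Gamma_{noise} = \sigma^2_{noise} I$:

$$\Phi(m; d) = \sum_{i=1}^{n_t}
  \frac{1}{2\sigma^2_{noise}} \lVert \mathcal{B}u(\cdot, t_i) - d_i \rVert^2 ,$$

where $\mathcal B$ is P1 interpolation onto the voxel centers inside the
mesh. The synthetic default is an *absolute* noise standard deviation of
0.02 on the volume-fraction scale ("2% noise"); the cohort-style default
variance 3.9e-3 corresponds to 6.25%-equivalent noise. Observation noise
is never clamped; only *state estimates* built from images (initial
conditions) are post-processed, see below.

## Prior

Each block of $m$ is a Gaussian random field whose covariance is the
squared inverse of an elliptic operator,
$\mathcal{C} = (-\gamma\Delta + \delta I)^{-2}$ — a Matérn-type (SPDE)
field with smoothness $\nu = 2 - d/2$. The hyperparameters follow from
the requested marginal variance $\sigma^2$ and correlation length $\rho$
via $\kappa_m = \sqrt{8\nu}/\rho$,
$\gamma = \sqrt{\Gamma(\nu) / (\Gamma(2)(4\pi)^{d/2}\kappa_m^{2\nu}\sigma^2)}$,
$\delta = \kappa_m^2\gamma$; in 2-D,
$\gamma = \rho/(4\sigma\sqrt{2\pi})$ and
$\delta = 2/(\sigma\rho\sqrt{2\pi})$. The mapping is certified
empirically by the test suite: sampled pointwise variance within 10% and
the distance at which the sampled correlation falls to 0.1 within 20% of
the Matérn prediction, interior vertices only. A Robin boundary term
$\sqrt{\gamma\delta}/1.42\,\langle u, v\rangle_{\partial\Omega}$ reduces
boundary variance inflation (the constant is the standard empirical
choice for this operator order).

Discretely, covariance and precision are defined against the
mass-weighted inner product ($\Gamma_{pr} = A^{-1} M A^{-1}$,
$\Gamma_{pr}^{-1} = A M^{-1} A$), so field statistics are stable under
refinement. Blocks are independent; defaults for the virtual patient are
mean $-1.30$ / variance $0.05$ for $m_D$, mean $-1.00$ / variance $0.02$
for $m_\kappa$, $\rho = 180$ mm for both. A cohort-style tissue-split
mode models gray- and white-matter log-diffusivity as independent fields
combined through the gray-matter indicator
(`tissue_split_prior()`, white-matter $\rho = 360$ mm).

## MAP estimation

The MAP point minimizes $\Phi(m; d) + \tfrac12\lVert m - m_{pr}
\rVert^2_{\Gamma_{pr}^{-1}}$ by inexact Newton-CG:

* gradients and Hessian actions come from the discrete adjoint
  (discretize-then-optimize): one forward and one backward solve for the
  gradient; one incremental forward and one incremental adjoint solve
  per Hessian action, reusing the factorized per-step Jacobians of the
  trajectory. The multiplicative radiotherapy kill transposes to the
  same factor on the adjoint at the kill times. Exactness is asserted by
  central finite-difference tests (relative error below $10^{-5}$ for
  the gradient, $10^{-4}$ for the full Hessian), including windows with
  radiotherapy events;
* inner CG is preconditioned by the prior covariance, truncated by the
  Eisenstat-Walker forcing
  $\eta_k = \min(0.5, \lVert g_k\rVert / \lVert g_{k-1}\rVert)$ and the
  Steihaug negative-curvature rule;
* globalization is Armijo backtracking ($c = 10^{-4}$, halving, at most
  25 backtracks) on the total cost;
* the first 5 iterations use the Gauss-Newton (positive-semidefinite)
  Hessian, then the full Hessian; convergence is declared on relative
  gradient-norm decrease (default $10^{-6}$; the pipeline driver uses
  $10^{-5}$) with at most 50 Newton iterations.

The initial iterate is the prior mean.

## Low-rank Laplace posterior

The posterior is approximated by
$\mathcal N(m_{MAP}, \Gamma_{post})$ with
$\Gamma_{post} = (H_{misfit} + \Gamma_{pr}^{-1})^{-1}$. The
prior-preconditioned generalized eigenproblem
$H_{misfit} v_j = \lambda_j \Gamma_{pr}^{-1} v_j$ is solved by a
double-pass randomized eigensolver (defaults: rank 50, oversampling 10)
in whitened coordinates: with $G = A^{-1} F$, $F F^\top = M$, the
symmetric operator $G^\top H G$ is compressed by $k+p$ Gaussian probes
and diagonalized, so returned eigenvectors are exactly
$\Gamma_{pr}^{-1}$-orthonormal. The Gauss-Newton Hessian is used so all
$\lambda_j \ge 0$; negative estimates (roundoff) are truncated to zero.
The covariance action is the Sherman-Morrison-Woodbury form
$\Gamma_{post} v = \Gamma_{pr} v - \sum_j
\tfrac{\lambda_j}{1+\lambda_j} v_j (v_j^\top v)$, and sampling applies
$z \mapsto z - \sum_j (1 - (1+\lambda_j)^{-1/2}) w_j (w_j^\top z)$ to
whitened noise before the prior factor. On linear forward maps the whole
construction reproduces the analytic Gaussian posterior to $10^{-6}$,
and all three pieces (eigenvalues, covariance action, sampler) are
checked against dense oracles on small meshes.

## Prediction and quantities of interest

The prediction map runs the forward model from a state estimated at the
last acquired image over a future window. QoIs: total tumor cellularity
$\int_\Omega \hat u\,dx$ and tumor volume $\int_\Omega 1_{\hat u}\,dx$
with the measurability threshold $\bar u = 0.1$ ($\hat u = u\,1_{u >
\bar u}$); Lin's concordance correlation coefficient between predicted
and reference voxel values (computed on the observation voxels, where
data live); and the Dice overlap of thresholded regions, with
$\mathrm{Dice}(\emptyset,\emptyset) := 1$ so that post-therapy
near-remission states compare as perfect agreement. The relative volume
error is signed, $(q - q^\dagger)/q^\dagger$. Pushforwards draw $n$
parameter samples (reference studies use 500), run the prediction per
sample, and compare posterior- against prior-predictive distributions
with the two-sided Mann-Whitney U-test (location) and Levene's test
(spread). CCC is evaluated at the prediction time only.

# The virtual patient

The generator emulates a longitudinal imaging study under
standard-of-care chemoradiation at desk scale:

* **Geometry** — a disk "brain" of radius 50 mm with an annular gray rim
  (gray for $r \ge 0.6R$) around a white core. Data are generated on a
  fine mesh (2 mm edges, ~1950 vertices) and inverted on a strictly
  coarser mesh (3 mm, ~920 vertices), so the inversion never sees its
  own discretization (inverse-crime avoidance). These sizes are the
  package's desk-scale choice; every operation is dimension- and
  resolution-generic.
* **Truth** — $D = 0.3$ mm³/day in white matter, $0.03$ in gray
  (preferential white-matter invasion), $\kappa = 0.15$/day everywhere;
  a Gaussian tumor seed (amplitude 0.8, width 6 mm) centered 18 mm
  off-center so that growth crosses the tissue interface and the
  heterogeneity is identifiable. Diffusivity units are quoted as printed
  in the modeling literature this configuration reproduces.
* **Treatment** — two untreated weeks, then six weeks of 2 Gy weekday
  fractions ($30 \times 2$ Gy) with concurrent daily chemotherapy
  ($\alpha_{rt} = 0.025$/Gy, $\alpha/\beta = 10$ Gy,
  $\alpha_{ct} = 0.9$, 1.8 h clearance, unit dose magnitude per
  administration), then another untreated month. Imaging is daily,
  weekly, or fortnightly over the 12-week window; prediction is 30 days
  past the last image. Under these conditions the tumor burden falls
  during chemoradiation and regrows swiftly afterwards, with a larger
  extent at the prediction time than during imaging.
* **Observations** — fine-mesh states interpolated to a 2 mm voxel grid
  and polluted with seeded additive Gaussian noise (sd 0.02). Noise is
  kept unclamped in the data.
* **State estimation from images** — initial conditions (day-0 for
  calibration, last image for prediction restarts) interpolate the voxel
  image to the mesh, zero values at or below the measurability threshold,
  and clamp to $[0,1]$. The zeroing mirrors ROI-based cellularity maps,
  which are exactly zero outside the segmented lesion; without it,
  clamped background noise ($\sim 0.01$) would seed spurious logistic
  growth over the multi-week windows.

What the generator does *not* emulate: patient anatomy (no gyri,
ventricles, or hemispheric restriction), MRI physics and contrast
synthesis, registration error, resection, heteroscedastic or spatially
correlated noise, and mass effect or multi-species biology. Passing
tests therefore demonstrate correctness of the inference machinery under
the stated noise model and geometry, not clinical validity on real
images.

# Numerical choices and degenerate inputs

* Radiotherapy fraction times are snapped to the nearest time-step
  boundary (they must land within half a step); the kill applies after
  the step reaching that time and before observation at it.
* Voxel centers follow `origin + (index + 0.5) * spacing`, 0-based;
  only voxels whose centers fall inside the mesh are observed, and that
  count is the likelihood's data dimension.
* Mesh-to-voxel interpolation is exact for linear fields; points
  marginally outside the fine mesh during data generation (rim voxels of
  the coarser polygon) are clamped to the nearest cell with renormalized
  barycentric weights.
* The per-step Newton solve fails loudly with its residual history; a
  Newton line search that cannot decrease the MAP objective returns the
  best iterate flagged as not converged.
* Two constant inputs make CCC undefined (error); two empty regions have
  Dice 1; `compare_distributions()` refuses fully degenerate samples.
* Seeds: every stochastic operation (tissue blobs, noise, probes,
  samplers) takes an explicit integer seed and restores the caller's RNG
  state; equal seeds give byte-identical output.

# Study sizes used by the automated checks

The packaged acceptance study calibrates the default virtual patient
under all three imaging schedules and pushes 300–400 samples per
distribution through the 30-day prediction; adjoint, Hessian, prior
calibration, and dense-oracle checks run on meshes of 91–2700 vertices.
These sizes were chosen so the full suite runs on a single CPU in tens
of minutes while leaving every assertion's tolerance at the values
stated above.

# Known limitations

* The Laplace approximation is exact only for linear forward maps; no
  MCMC correction is provided, so far-from-Gaussian posteriors are
  summarized optimistically.
* The Gauss-Newton spectrum underlying the low-rank update ignores
  negative curvature of the full Hessian away from the optimum.
* Isotropic scalar diffusion only — no anisotropy tensors, mass effect,
  or vascular/metabolic coupling.
* The treatment model is fixed across a study; efficacy parameters are
  not inferred.
* 3-D ball meshes use a radially mapped cube triangulation whose element
  quality is lower than the 2-D rings; large 3-D studies would warrant a
  proper tetrahedral mesher.
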