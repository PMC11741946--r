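---
title: "Quantitative photoacoustic inversion with a fluence marker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative photoacoustic inversion with a fluence marker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A photoacoustic image is proportional to the absorbed optical energy
density $H(\mathbf r,\lambda) = \mu_a(\mathbf r,\lambda)\,
\phi(\mathbf r,\lambda)$: the product of the tissue's absorption
coefficient, which carries the diagnostic information (hemoglobin, lipid,
contrast agents), and the light fluence, which is unknown and decays with
depth in a way that depends on the very coefficients one wants to recover.
Dividing the image by a modeled fluence is ill-posed; the apparent spectra
of deep chromophores are distorted by wavelength-dependent attenuation
along the photon path ("spectral coloring").

`qpamarker` anchors the inversion with a *fluence marker*: a chromophore
whose absorption and location are known a priori. Arterial blood is the
motivating example — its absorption follows from oxygen saturation (pulse
oximetry) and hematocrit (routine blood test), and co-registered ultrasound
locates the lumen. Everything here is 2D and starts from the absorbed
energy map; acoustic reconstruction and the Grüneisen factor (set to 1) are
out of scope, as is recovery of the scattering map, which is assumed known.

## Forward model

Light transport is the diffusion approximation

$$\mu_a \phi - \nabla\cdot(\kappa \nabla \phi) = q_0,
\qquad \kappa = \frac{1}{3(\mu_a + \mu_s')},$$

valid for scattering-dominated tissue ($\mu_s' \gg \mu_a$; the
`optical_map()` constructor warns when this is violated). It is discretized
with linear finite elements on a triangular mesh derived from the pixel
grid: one node per pixel center, each grid cell split by a fixed diagonal
into two congruent right triangles (`build_mesh()`). Element optical
properties are copied from the pixel at the cell's top-left corner node —
no interpolation, so phantom masks map exactly onto the model.

The boundary condition is the exit-only Robin condition
$\phi + 2A\kappa\,\partial\phi/\partial n = 0$. The internal-reflection
coefficient $A$ uses the standard polynomial fit
$R_\mathrm{eff} = -1.440/n^2 + 0.710/n + 0.668 + 0.0636\,n$,
$A = (1+R_\mathrm{eff})/(1-R_\mathrm{eff})$ with $n = n_{in}/n_{out}$
(1.33/1.0 by default). Any standard $A(n)$ reproduces exit-only behavior;
the choice scales absolute fluence smoothly and inversion round trips are
insensitive to it.

Sources are isotropic Gaussians of width one grid spacing (truncated at
three widths, normalized to unit power), placed one grid spacing inside the
boundary and equally spaced by arc length around the inset rectangle
(`default_sources()`; ten sources by default). Fluence units are arbitrary
but internally consistent: all comparisons are between $H_M$ and $H_C$
computed in the same units. Measurements are synthesized by adding white
Gaussian noise whose variance is set from the mean signal power at a stated
SNR (`add_noise()`; 30 dB for the nine-region study, 40 dB for the carotid
study).

The discrete operator is symmetric positive definite; it is assembled from
a precomputed sparsity plan and factorized with CHOLMOD (`Matrix`), reusing
the symbolic analysis across inversion iterations. Solves are checked to a
relative residual of 1e-10. Mass-lumped nodal areas give the quadrature
weights $w_i$ used by all energy integrals; with them, absorbed power plus
boundary outflow reproduces the injected power to rounding error on
homogeneous phantoms (`power_balance()`).

## Inversion methods

All iterative methods start from $\mu_a = 10^{-10}\,\mathrm{mm}^{-1}$
(any sufficiently small value behaves identically), clamp negative updates
to zero, and run a configured number of iterations (700 for the nine-region
study).

**Direct Beer–Lambert inversion** (`invert_beer_lambert_marker()`): for a
homogeneous layer of thickness $r$ above the marker,
$\mu_a^{u} e^{\mu_a^{u} r} = (H^{u}/H^{m})\,\mu_a^{m}$, solved by
safeguarded Newton iteration from $10^{-5}$; at $r=0$ it reduces exactly to
the **equal-fluence baseline** `invert_equal_fluence()`, which is biased
whenever the fluences actually differ.

**SIM** (`run_sim()`): fixed-point update
$\mu_a \leftarrow H_M / (\phi_C + \sigma)$ with the current iterate's
modeled fluence. $\sigma$ (fluence units, default 0.002) stabilizes
low-fluence regions. Note that because fluence units are arbitrary, the
meaning of a fixed $\sigma$ depends on the source normalization; with unit
source power the default reproduces the intended mild regularization, and
the residual floor of SIM on noise-free data is set by $\sigma/\phi$.

**GBM** (`run_gbm()`): limited-memory BFGS minimization of
$\varepsilon = \tfrac12\sum_i w_i (H_M - H_C)_i^2$ with the analytic
adjoint gradient. The adjoint field solves the same factorized system with
source $\mu_a w (H_M - H_C)$; the gradient per pixel combines the data term
$-w\,(H_M-H_C)\,\phi$, the adjoint-mass term ($\phi\phi^*$ integrated
consistently over the pixel's two triangles), and the diffusion-sensitivity
term $-3\kappa_e^2\,\phi^{*T} S_e \phi$ from
$\partial\kappa/\partial\mu_a$. This is the exact gradient of the discrete
functional: the test suite certifies it against central finite differences
at 1e-4 (it agrees to ~1e-9, the truncation floor of the differences).
With a marker, the marker pixels are reset to the known value after each
accepted iteration ("reset variant"). Because the line search enforces
sufficient decrease before the reset is applied, the error trace here is
essentially monotone — an implementation whose optimizer cannot see the
reset (e.g. a black-box BFGS) instead shows transient oscillations; both
converge to the same answer.

**Constrained GBM** (`run_gbm_constrained()`): the marker enters as the
equality constraint $\mu_a(i_m,j_m) = \mu_a^{marker}$, implemented in
reduced space — marker pixels are removed from the optimization variables
and their gradient entries zeroed, which is mathematically equivalent to
the $A_{eq} X = B_{eq}$ formulation and keeps marker pixels bit-exact
without any reset.

Optimizer internals (memory 10, Armijo constant $10^{-4}$, at most 25 step
halvings, a 0.01 mm$^{-1}$ cap on the first step's largest pixel change)
are exposed in `inversion_config()`. "Iteration" means one outer
quasi-Newton iteration: one gradient evaluation plus a line search. A run
stops at `max_iter`, at an optional residual threshold, or when no step
achieves any decrease ("no_decrease" — the function no longer decreases
within machine tolerance).

## Phantoms: what they emulate, and what they do not

`make_nine_region_phantom()` is a 20 mm square at 0.2 mm pixels, uniform
$\mu_s' = 2\ \mathrm{mm}^{-1}$, nine absorption levels from 0.001 to 0.2
mm$^{-1}$, and a central 2 mm-radius marker disc at 0.2 mm$^{-1}$. The five
scored regions probe depth: three shallow discs (truths 0.020, 0.075,
0.150), one deep disc (0.075) laterally offset from the marker shadow, and
a background patch directly beneath the marker. The exact inclusion layout
is this package's documented choice (the reference figure is not printed at
pixel precision); depth is measured from the top boundary in the image
convention. One consequence of combining that layout with perimeter
illumination is that the "deep" regions here are better lit than in a
top-illuminated geometry, so absolute deep-region errors are smaller than
in the original depth-dependence analysis, while shallow-region recoveries
— the quantities scored by the acceptance targets — are directly
comparable.

`make_spectral_phantom()` puts an unknown-chromophore annulus around the
marker disc, with a bundled five-point synthetic spectrum (unimodal unknown
peaking at the middle wavelength; monotonically increasing background that
drives spectral coloring). The numeric spectra are package-defined
(documented in `inst/extdata/`), so spectral tests are qualitative round
trips, not reproductions of published curves.
`make_carotid_phantom()` (24 mm at 0.15 mm) layers superficial tissue and
muscle above a blood lumen (marker, 0.650 mm$^{-1}$) with a lipid plaque
annulus and a deep background-tissue target; component truths are the
literature values at 930 nm where lipid absorption peaks. Scattering is
uniform at 2 mm$^{-1}$.

None of the phantoms include acoustic artifacts, transducer bandwidth,
3D out-of-plane light transport, or scattering heterogeneity — passing
tests demonstrate correct inversion of the stated 2D diffusion model, not
performance on experimental images.

## Numerical choices and degenerate inputs

* Noise can make $H_M$ locally negative; the SIM ratio update then produces
  negative candidates that the clamp zeroes (the documented behavior).
  $\phi + \sigma$ cannot vanish for $\sigma > 0$.
* The Newton root-finder for the Beer–Lambert relation is safeguarded
  against negative iterates (the root is positive since the right-hand side
  is); it is cross-checked against the Lambert-W closed form in the tests.
* Curvature pairs with $s^T y \le 10^{-12}\|s\|\|y\|$ are skipped to keep
  the L-BFGS Hessian approximation positive definite under projection.
* PSNR uses the maximum of the ground truth over the non-excluded pixels as
  its peak (a phantom-intrinsic, deterministic choice; the peak definition
  used for the published table is unstated, so PSNR comparisons are treated
  as orderings, not absolute decibels). The marker region is excluded.
* Equal-fluence regional estimates apply the formula to region means of
  $H_M$ against the marker-region mean.
* Map I/O uses 32-bit float TIFF scaled into $[0,1]$ with the scale factor
  in a JSON sidecar (the range the TIFF writer round-trips), plus 16-bit
  TIFFs for labels and CSV/JSON for tables and metadata.

## Problem sizes used by the shipped checks

The test suite runs the nine-region study at full scale (100×100, ten
sources, SNR 30 dB, 700 iterations) for the two marker-aided gradient
methods and the three baselines, averaged over three noise seeds — the
seed-averaged orderings reuse those three seeds. The carotid
reproduction runs at half resolution (80×80 at 0.3 mm) with 400
iterations and SNR 40 dB; spectral round trips use three wavelengths on a
70×70 grid, noise-free, with 250 iterations; the gradient oracle uses
twenty random 20×20 instances probed at ten to twelve pixels each. These
sizes are the package's reproducibility defaults; `scripts/acceptance.R`
re-runs the nine-region quantities from scratch at full scale.

## Known limitations

* 2D only; no radiative-transfer or Monte-Carlo reference solver.
* $\mu_s'$ is assumed known and is not estimated.
* Concentration unmixing across wavelengths is out of scope (each
  wavelength is inverted independently).
* The deep-shadow region below a strong marker remains unidentifiable at
  realistic SNR — all methods fail there, which the scoring reports rather
  than hides.
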