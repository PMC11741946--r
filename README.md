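# qpamarker

Quantitative photoacoustic (QPA) optical inversion anchored by a fluence
marker.

A photoacoustic image is proportional to the absorbed optical energy
density

    H(r, λ) = μa(r, λ) · φ(r, λ; μa, μs′)

— the product of the absorption coefficient μa (the quantity of clinical
interest: hemoglobin, lipid, contrast agents) and the light fluence φ,
which is unknown and itself depends on the absorption along the photon
paths. This coupling makes naive "divide by a modeled fluence" recovery
ill-posed and distorts the apparent spectra of deep chromophores
(spectral coloring). `qpamarker` resolves the ambiguity with a *fluence
marker*: a chromophore whose absorption and location are known a priori —
typically arterial blood, whose μa follows from pulse-oximetry and
hematocrit measurements, and whose position is visible in co-registered
ultrasound. The package is aimed at researchers developing quantitative
photoacoustic methods, e.g. for carotid plaque characterization.

## What it implements

* **Forward model** — 2D diffusion approximation
  `μa φ − ∇·(κ∇φ) = q0`, `κ = 1/(3(μa + μs′))`, solved by linear finite
  elements on a triangulated pixel grid (one node per pixel center), with
  an exit-only Robin boundary condition and Gaussian boundary sources;
  measurement synthesis adds white Gaussian noise at a stated SNR.
* **Inversion algorithms**
  * `invert_beer_lambert_marker()` — direct homogeneous-layer inversion of
    `μa e^{μa r} = (H_unknown / H_marker) · μa_marker`;
  * `invert_equal_fluence()` — the equal-fluence baseline
    `μa = (H_unknown / H_marker) · μa_marker`;
  * `run_sim()` — simple iterative method, the fixed-point update
    `μa ← H_M / (φ_C + σ)`;
  * `run_gbm()` — adjoint-gradient quasi-Newton (L-BFGS) minimization of
    `½ Σ w (H_M − H_C)²`, with per-iteration marker reset;
  * `run_gbm_constrained()` — the marker imposed as an equality
    constraint (reduced-space optimization).
* **Digital phantoms** (`make_nine_region_phantom()`,
  `make_spectral_phantom()`, `make_carotid_phantom()`,
  `make_two_layer_phantom()`) so every study runs without external data,
  and **scoring** (`psnr()`, `region_means()`, `recover_spectrum()`,
  `marker_sensitivity()`).
* **Experiment driver** — YAML-configured subcommands
  `phantom | forward | invert | report` (`qpa_main()`, wrapper script in
  `inst/cli/qpamarker.R`), with float-TIFF/JSON/CSV artifacts.

## Worked example

Recover the nine-region phantom with the equality-constrained gradient
method at the study conditions (ten sources, SNR 30 dB, up to 700
iterations):

```r
library(qpamarker)

phantom <- make_nine_region_phantom()            # 20 mm x 20 mm, 0.2 mm pixels
grid <- phantom$optics$grid
mesh <- build_mesh(grid)
sources <- default_sources(grid, 10)             # ten boundary sources

phi <- solve_fluence(mesh, phantom$optics, sources)
H <- absorbed_energy(phantom$optics, phi)        # H = mu_a * phi
H_M <- add_noise(H, snr_db = 30, seed = 1)       # measured data

optics_unknown <- optical_map(matrix(0, grid$ny, grid$nx), 2, grid)
res <- run_gbm_constrained(H_M, optics_unknown,
                           inversion_config("GBM_CONSTRAINED", max_iter = 700),
                           marker = phantom$marker, sources = sources)
res
#> <inversion_result> GBM_CONSTRAINED: 214 iterations (converged: no_decrease), final log||dH||^2 = -10.302

report <- region_means(res$mu_a_hat, phantom$labels)
print(subset(report, label <= 5), digits = 3)
#>   label    name truth recovered percent_error n_pixels
#> 1     1 region1 0.020   0.01996        0.1868      172
#> 2     2 region2 0.075   0.07483        0.2285      172
#> 3     3 region3 0.150   0.14944        0.3738      172
#> 4     4 region4 0.075   0.07502        0.0224      172
#> 5     5 region5 0.001   0.00104        3.5666      172

psnr(res$mu_a_hat, phantom$optics$mu_a, marker_mask(phantom$marker))
#> [1] 46.92751
```

The optimizer stops when the misfit no longer decreases ("no_decrease",
here after 214 of the allowed 700 iterations). The report lists, per
scored region, the ground-truth absorption (1/mm), the mean recovered
absorption over the region's pixels, and the percent error: shallow
inclusions (regions 1–3) and the deep inclusion (region 4) come back
within a fraction of a percent, while region 5 — a background patch in the
marker's shadow with μa = 0.001/mm — is the hardest target. The PSNR
(46.9 dB) is computed excluding the marker region.

The same study from the shell:

```sh
Rscript inst/cli/qpamarker.R all config.yml     # phantom, forward, invert, report
```

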