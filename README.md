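# ctrecon

Sparse-view parallel-beam CT reconstruction in R.

## The problem

X-ray computed tomography reconstructs a 2D map of linear attenuation
coefficients μ(x, y) from line integrals (a *sinogram*) measured along many
view angles. Radiation dose is proportional to the number of views, so there
is strong interest — clinically and in small-animal micro-CT — in
reconstructing from *sparse-view* data (tens of views instead of hundreds).
Filtered backprojection (FBP), the standard analytic method, assumes densely
sampled angles and produces severe streak artifacts when that assumption is
violated. Algebraic solvers (ART/SART) degrade more gracefully but still
leave streaks and blur at very low view counts.

`ctrecon` implements a compressed-sensing reconstruction that addresses this
regime, alongside the baselines it is usually compared with:

* **Projector** — exact ray/pixel intersection lengths (Siddon-style) as a
  sparse system matrix A, with its exact adjoint;
* **FBP** — Ram-Lak and Shepp-Logan ramp filters, FFT convolution, linear
  interpolation backprojection;
* **ART (Kaczmarz)** and **SART** — row-action and simultaneous algebraic
  solvers;
* **TV** and **joint TV + wavelet** compressed sensing: minimize

      J(μ) = λ₁‖μ‖_TV + λ₂‖Φμ‖₁ + ‖Aμ − y‖₂²

  by nonlinear conjugate gradient (Polak–Ribière+, Armijo backtracking),
  where ‖·‖_TV is isotropic total variation and Φ an orthonormal 2D wavelet
  transform (Daubechies-4 by default). Absolute values are smoothed as
  |x| ≈ √(x² + ξ), ξ = 10⁻¹⁵, so the objective is differentiable. The TV
  method is the λ₂ = 0 special case. TV suppresses streaks and noise; the
  wavelet term preserves edges and low-contrast detail that TV alone tends
  to oversmooth.

It also provides a phantom generator (piecewise-constant objects with
low-contrast inserts and fine bars), a norm-exact Gaussian sinogram noise
model, uniform view decimation, the evaluation metrics RRMSE, streak
indicator (TV of the error image) and SSIM, a regularization-weight search
(grid for TV, alternating coordinate search for the joint method), and a
small CLI (`simulate`, `reconstruct`, `evaluate`, `sweep`, `param-search`).

## Worked example

Fifty noisy views of a 128 × 128 phantom, reconstructed by FBP, SART and the
joint compressed-sensing solver:

```r
library(ctrecon)

# ground-truth phantom and a densely sampled parallel-beam scan
truth <- generate_phantom(default_phantom_spec(side_px = 128))
scan  <- simulate_sinogram(truth, uniform_geometry(n_views = 360, n_detectors = 128))

# sparse-view acquisition: keep 50 of 360 views, add 5% Gaussian noise
y <- add_noise(decimate_views(scan, 50), relative_level = 0.05, seed = 1)
A <- build_system_matrix(truth, y$geometry)

# reconstruct with FBP, SART, and the joint TV + wavelet-l1 solver
rec_fbp  <- fbp_reconstruct(y, side_px = 128)
rec_sart <- sart_reconstruct(A, y)$image
rec_cs   <- nlcg_reconstruct(A, y, cs_config(lambda1 = 10, lambda2 = 1))$image

for (r in list(fbp = rec_fbp, sart = rec_sart, cs = rec_cs))
  print(round(evaluate_recon(r, truth), 4))
```

Output:

```
    rrmse        si      ssim
   0.4783 2416.5065    0.1646
    rrmse        si      ssim
   0.3147 1482.0708    0.2625
    rrmse        si      ssim
   0.1573  286.2074    0.7671
```

Reading the numbers: relative error (RRMSE, fraction of the reference norm)
drops from 48% (FBP) through 31% (SART) to 16% for the compressed-sensing
solver; the streak indicator (total variation of the error image — lower
means fewer streaks) falls by an order of magnitude; and structural
similarity (SSIM, 1 = identical) rises from 0.16 to 0.77. This is the
qualitative pattern that motivates compressed sensing for sparse-view CT.
The weights `lambda1`, `lambda2` depend on the data scale; select them with
`param_search()` (see the methods vignette).

## Layout

* `R/` — projector, phantom/noise simulation, FBP, ART/SART, wavelet, CS
  solver, metrics, I/O, experiment driver, CLI
* `src/` — Rcpp ray tracer and ART inner loop
* `vignettes/sparse-view-ct.Rmd` — methods: models, conventions, parameter
  guidance, limitations
* `inst/cli/ctrecon` — command-line launcher
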