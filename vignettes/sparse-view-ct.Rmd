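---
title: "Sparse-view CT reconstruction: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view CT reconstruction: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
imaging model, the reconstruction methods and their assumptions, the
parameters that matter, what the synthetic data generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. Imaging model and conventions

A parallel-beam scan measures line integrals of the attenuation map
$\mu(x,y)$: by Beer's law the detected intensity is
$I = I_0 \exp(-\int_l \mu\, dl)$, so $y = \ln(I_0/I)$ is the integral of
$\mu$ along the ray. Digitizing $\mu$ on a square pixel lattice with
indicator basis functions turns acquisition into a linear system
$y = A\mu$, where $A_{ji}$ is the length of the intersection of ray $j$
with pixel $i$.

Fixed conventions (used by every function and every test):

* the image is centred at the physical origin; array row 1 is the top of
  the image; pixels are flattened **row-major**;
* a ray with view angle $\theta \in [0^\circ, 180^\circ)$ and signed
  detector offset $t$ passes through $(t\cos\theta, t\sin\theta)$ with
  direction $(-\sin\theta, \cos\theta)$, i.e.
  $t = x\cos\theta + y\sin\theta$ along the ray;
* detector bins are centred at $t_k = (k - (n_d-1)/2)\,\Delta$,
  $k = 0, \dots, n_d - 1$, with pitch $\Delta$.

`build_system_matrix()` computes the **exact** chord lengths by a
Siddon-style traversal: all crossings of the ray with grid lines are
sorted and each inter-crossing segment is attributed to the pixel
containing its midpoint. This matches the line-integral definition of
$A_{ji}$ literally for the indicator basis; entries are nonnegative and
bounded by the pixel diagonal. Rays that miss the image square produce
empty rows, which all solvers skip. Backprojection is the exact adjoint
$A^T$; the test suite checks $\langle A\mu, y\rangle = \langle \mu, A^T
y\rangle$ to $10^{-10}$ and sparse/dense equivalence against an
independent ray-box clipping oracle.

A boundary note: a ray lying exactly on a pixel grid line is a
measure-zero degeneracy; the traversal assigns its chord to one of the two
adjacent pixel columns (the midpoint rule), whereas a per-pixel clipping
computation would count it for both. Oracle tests therefore use detector
layouts whose rays avoid exact grid lines.

Geometry defaults are `n_detectors = side_px` and
`detector_spacing = pixel_size` — common parallel-beam practice. Nothing
in the package depends on this choice; see §3 for when a finer pitch is
appropriate.

## 2. Filtered backprojection

FBP implements the inversion
$\mu(x,y) = \int_0^\pi \int P_\theta(t')\,\varphi(t - t')\,dt'\,d\theta$:
ramp-filter each view, then smear the filtered views back across the
image. Choices made here:

* **Filters.** Band-limited ramp sampled at the detector pitch: Ram-Lak
  ($h(0) = 1/4\Delta^2$, $h(k) = -1/(\pi k \Delta)^2$ for odd $k$, zero
  otherwise) and Shepp-Logan (sinc-apodized ramp, closed form
  $h(k) = -2/(\pi^2\Delta^2(4k^2-1))$). Default kernel length is
  $2 n_d - 1$ taps. Ram-Lak is the default filter; the two differ only in
  high-frequency roll-off.
* **Convolution.** Zero-padded FFT convolution (length the next power of
  two $\ge 2 n_d + $ taps). The **full linear-convolution support is
  kept**: the ramp response has slowly decaying negative tails beyond the
  detector window, and truncating the filtered view to the measured bins
  biases the reconstruction upward near the image periphery (this was
  measurable as a corner bias on smooth phantoms before the fix).
  Backprojection may therefore interpolate up to $(n_{taps}-1)/2$ bins
  past each detector edge.
* **Backprojection.** Linear interpolation in $t$, accumulation over
  views, scaled by $\pi / n_{views}$ (the Riemann discretization of
  $\int_0^\pi d\theta$ for uniform angles) and by $\Delta$ (the
  discretization of $\int dt'$).

FBP is linear, and shifting all view angles by $90^\circ$ (mod
$180^\circ$) rotates the reconstruction by $90^\circ$; both are asserted
in the tests.

## 3. Detector pitch and the FBP convergence check

The acceptance suite verifies that FBP error on a hard-edged disc
decreases strictly with view count and converges below RRMSE 0.05 at 720
views. That check uses a **half-pixel detector pitch** ($2\times$ bins).
At the default matched pitch the limiting error at dense angles is
detector-bin aliasing of the discontinuous edge — not view sampling — and
neither this implementation nor a reference FBP gets below $\sim$0.07 on
that configuration. With the edge resolved by the finer pitch, the
quantity the check is about (convergence in *view sampling*) is actually
what is measured.

## 4. Algebraic reconstruction

**ART (Kaczmarz).** One iteration is a sweep through the rays in order,
each projecting the iterate onto the hyperplane of one equation:
$x \leftarrow x + \lambda\,(b_i - \langle a_i, x\rangle)/\|a_i\|^2\, a_i$.
The relaxation parameter $\lambda \in (0,2)$ defaults to the classical 1;
the default sweep count is 30, past which the error on simulated phantoms
plateaus. On consistent systems the distance to the solution is
nonincreasing (asserted on random systems). The inner loop is compiled
(Rcpp) over a CSR copy of $A$.

**SART.** All rays act simultaneously:
$x \leftarrow x + \lambda\,V^{-1} A^T W^{-1} (b - Ax)$ with
$W = \mathrm{diag}(\|a_i\|_1)$ (row sums, normalizing each ray residual
by the ray's total intersection length) and
$V = \mathrm{diag}(\|a_j\|_1)$ (column sums, normalizing each pixel
update by its total ray coverage). Published matrix forms of SART are
not always dimensionally consistent about which factor sits where; the
convention above is the standard one and is verified against an explicit
dense-matrix evaluation in the tests. Default: 150 iterations,
$\lambda = 1$. Pixels with zero column sum (uncovered by any ray) and
zero rows are excluded from updates.

Nonnegativity clamping after each sweep/iteration is available
(`nonneg = TRUE`) but off by default: the baseline algorithms are defined
without it, and it changes none of the contracts.

## 5. The compressed-sensing solver

Sparse-view data make $y = A\mu$ underdetermined; the solver selects
among its solutions by sparsity priors:

$$J(\mu) = \lambda_1 \|\mu\|_{TV} + \lambda_2 \|\Phi\mu\|_1 +
\|A\mu - y\|_2^2 .$$

TV (sum of isotropic gradient magnitudes) favours piecewise-constant
structure and suppresses streaks and noise; the wavelet $\ell_1$ term
favours images sparse under an orthonormal wavelet transform, preserving
point singularities, edges and low-contrast detail that TV alone tends to
flatten. $\lambda_2 = 0$ gives the TV-only method.

Numerical definitions:

* **TV.** Forward differences with replicate (Neumann) boundary — the
  difference past the last row/column is zero — and the isotropic
  combination $\sum_{ij}\sqrt{(\nabla_x\mu)^2 + (\nabla_y\mu)^2 + \xi}$.
  The gradient is the negative discrete divergence of the normalized
  gradient field with *exactly adjoint* boundary handling, so
  finite-difference checks pass at relative $10^{-4}$.
* **Smoothing.** Both $\ell_1$-type terms use
  $|x| \approx \sqrt{x^2 + \xi}$ with $\xi = 10^{-15}$, in the objective
  *and* in the gradient, so the monotone-descent property is exact rather
  than approximate. Shrinking $\xi$ further changes $J$ by at most
  $(\lambda_1 P + \lambda_2 Q)\sqrt{\xi}$ ($P$ pixels, $Q$ coefficients);
  reported objective values use the smoothed form.
* **Wavelet operator $\Phi$.** Multi-level periodic orthonormal 2D DWT,
  built from per-level orthogonal step matrices; families `haar` and
  `db4` (Daubechies extremal phase, 4 vanishing moments; the default, a
  robust choice for images that are not exactly piecewise constant).
  Default depth 4. Orthonormality gives $\|\Phi\mu\|_2 = \|\mu\|_2$ and
  $\Phi^T = \Phi^{-1}$, which the gradient uses. Non-power-of-two sides
  are zero-padded to the next power of two inside the operator only (TV
  and the data term act on the unpadded image); the depth is reduced if a
  level would drop below size 2. No wavelet package is available in the
  target environment, so the transform is implemented here and held to
  perfect-reconstruction and $\ell_2$-preservation contracts at
  $10^{-10}$.

**Optimizer.** Polak–Ribière+ nonlinear conjugate gradient with restart
to steepest descent whenever the direction fails to be a descent
direction, and an Armijo backtracking line search (shrink 0.5,
sufficient-decrease constant $10^{-4}$, at most 20 backtracks). The
initial step along direction $d$ is the exact minimizer of the quadratic
data term, $\alpha_0 = -g^T d / (2\|Ad\|_2^2)$. A fixed unit initial
step — sometimes quoted for this class of solver — is poorly scaled here:
the data term dominates the curvature, its natural step is orders of
magnitude below 1, and the backtracking budget is spent rediscovering the
scale at every iteration; measured on the package's own benchmark
phantom, 150 iterations with the fixed step left the TV solution far from
the regularized minimizer (error roughly 2.5$\times$ higher than with the
quadratic-model step). Since only strictly decreasing steps are accepted,
the recorded cost trace is nonincreasing by construction — a property
asserted on every solver run in the tests. Iteration cap 150 by default
(consistent with the plateau observed for this family of methods);
stopping also occurs when $\|\nabla J\| < 10^{-6}(1 + |J|)$.
Initialization is the zero image; an FBP warm start can be passed via
`x0`.

## 6. Choosing the regularization weights

$\lambda_1, \lambda_2$ balance the priors against the data term, and the
balance depends on the *scale* of the data: the data term is quadratic in
$\mu$ and grows with ray count and path lengths, while the priors are
(1-)homogeneous. Weights quoted for one dataset therefore do not transfer
to another scale. The package defaults
($\lambda_1 = 10^{-3}$, $\lambda_2 = 5\times10^{-4}$) are conventional
reference values for data normalized the way micro-CT scans often are;
for any serious use, run `param_search()`:

* TV method: grid search over $\lambda$, minimizing RRMSE against a
  reference (ground truth in simulation; a full-view FBP reconstruction
  for real decimation experiments);
* joint method: alternating one-dimensional searches — fix $\lambda_2$,
  scan $\lambda_1$; fix the winner, scan $\lambda_2$; repeat until
  neither coordinate moves. Evaluations are cached.

A multiplicative (half-decade) grid is recommended. If the search selects
a grid *boundary*, the grid does not bracket the minimum and should be
widened — this is a diagnostic, not an answer. The acceptance suite runs
exactly this protocol on the package's benchmark phantom with the grids
$10^{\{-3, -2.5, \dots, 1.5\}}$ for $\lambda_1$ and
$10^{\{-4, \dots, 0\}}$ for $\lambda_2$.

## 7. The synthetic world

`default_phantom_spec()` builds the benchmark object: 128 × 128, a disc
of value 0.2 and radius $0.45\,\mathrm{side}$ on zero background, four
disc inserts at additive contrasts 0.5, 0.1, 0.05, 0.02 (spanning
conspicuous to low-contrast), and a comb of five 2-px bars (value 0.3,
emulating trabecular-like fine structure). Rasterization is by pixel-
centre membership — deterministic and exactly testable, at the cost of
staircase edges (no area-weighted anti-aliasing). Projections are exact
line integrals of the rasterized phantom, so simulation and
reconstruction share the same forward model (an "inverse crime": the
simulation measures solver behaviour, not model mismatch).

Noise follows the additive white Gaussian model on the sinogram with a
*relative* level: the drawn noise is rescaled so that
$\|e\|_2/\|A\mu\|_2$ equals the requested level exactly (to $10^{-12}$),
making the contamination level deterministic while the pattern varies
with the seed. The benchmark level is 0.05. View decimation keeps
`n_keep` views at a uniform index stride starting at the first view,
copying rows bit-exactly.

What the generator does **not** emulate: Poisson/photon-counting
statistics, beam hardening, scatter, detector blur, real anatomical
texture, and model mismatch between acquisition and reconstruction. A
green test on this world establishes solver correctness and the relative
ordering of methods under ideal sparse-view conditions — not clinical
performance.

## 8. Metrics

* **RRMSE** $= \|y - y_{ref}\|_2 / \|y_{ref}\|_2$.
* **Streak indicator** $= TV(y - y_{ref})$ with the exact (unsmoothed)
  TV under the same forward-difference convention as the solver, so the
  metric and the objective are mutually consistent. Zero iff the error
  image is constant.
* **SSIM**: mean-pooled product of luminance, contrast and structure
  similarities over sliding windows. Constants are unstated in much of
  the CT literature; the package adopts the standard reference settings —
  11 × 11 Gaussian window with $\sigma = 1.5$, $C_1 = (0.01 L)^2$,
  $C_2 = (0.03 L)^2$, $C_3 = C_2/2$ (which reduces the product to the
  familiar two-term form), $L$ = data range of the reference by default —
  all exposed in `ssim_config()`. The implementation is verified against
  a brute-force window-by-window evaluation to $10^{-10}$.

In simulations the reference is the ground-truth phantom; for real
decimation experiments the full-view FBP reconstruction is the customary
reference.

## 9. Known limitations

* Parallel-beam 2D only; no fan/cone-beam geometry or rebinning.
* The constrained formulation $\min \|\Phi\mu\|_1$ s.t.
  $\|A\mu - y\|_2 < \varepsilon$ is not implemented; only the penalized
  objective is solved. No L-curve selection; no proximal/ADMM solvers.
* The general SIRT family with arbitrary positive-definite weighting
  matrices is not implemented — only its SART specialization.
* NLCG convergence on the joint objective is first-order: for very small
  weights the regularized minimizer is approached slowly, and results at
  a fixed iteration budget depend on that budget (by design, matching
  how these methods are used and reported).
* TIFF/PNG raster I/O is replaced by CSV (lossless) and 16-bit ASCII PGM
  containers, as no raster-image package is available in the target
  environment.
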