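---
title: "Plug-and-play ADMM dipole inversion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plug-and-play ADMM dipole inversion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmpnp)
```

## The inverse problem

Quantitative susceptibility mapping (QSM) recovers the tissue magnetic
susceptibility distribution $\chi$ (in ppm) from the measured local field
perturbation $\phi$ (the B0-normalized field offset that remains after
phase unwrapping and background-field removal, expressed here in the same
ppm unit). The physics is a convolution with the unit dipole response,
diagonal in the Fourier domain:

$$ F\phi = D \, F\chi + Fn, \qquad
   D(\mathbf k) = \frac13 - \frac{(\mathbf k \cdot \hat b_0)^2}{|\mathbf k|^2}, $$

with $n$ i.i.d. Gaussian field noise. $D$ vanishes on the magic-angle
cone ($\approx 54.7^\circ$ to $\hat b_0$), so single-orientation
inversion is ill-posed: straight division amplifies noise into streaking
artifacts. `dipole_kernel()` builds $D$ on the unshifted FFT grid in
physical frequencies (cycles/mm), so anisotropic voxels — e.g. thick-slice
axial acquisitions — scale the cone correctly. $D(0)$ is undefined by the
formula; the package sets it to 0 by default (zero-mean field response,
the common QSM convention) and exposes it as `dc_value` for sensitivity
tests. Convolution is circular; `forward_field(pad = TRUE)` provides a
pad-by-two mode for sources near the grid boundary.

## Solvers

Three regularized solvers share the fidelity term
$\tfrac{\mu}{2}\lVert M(F^H D F \chi - \phi)\rVert_2^2$:

* **`l2_closed_form()`** — Tikhonov penalty $\alpha\lVert P\chi\rVert^2$
  with $P$ the identity or the 3D gradient (default), solved in one
  Fourier division.
* **`tv_admm()`** — isotropic total variation
  $\alpha\lVert W\nabla\chi\rVert_1$ via ADMM splitting on the gradient
  field: shrinkage (soft threshold at $\alpha W/\beta$) for the gradient
  block, a Fourier-diagonal solve for $\chi$.
* **`pnp_admm()`** — the package's centerpiece. ADMM splitting
  $\chi = v$ with scaled multiplier $u$ turns the regularizer update into
  a proximal step; the plug-and-play idea replaces that step with one
  application of an arbitrary denoiser:
  $$ \chi^{n+1} = \arg\min_\chi
       \tfrac{\beta}{2}\lVert \chi - v^n + u^n\rVert^2 +
       \tfrac{\mu}{2}\lVert M(F^H D F\chi - \phi)\rVert^2, \qquad
     v^{n+1} = D_\sigma(\chi^{n+1} + u^n), \qquad
     u^{n+1} = u^n + \chi^{n+1} - v^{n+1}. $$
  Any function registered with `register_denoiser()` plugs in without
  touching the loop — that modularity is the point of the design, and a
  test iterates the solver over every registered denoiser.

Notational choice: some treatments write the proximal weight of the
$\chi$-subproblem as $\alpha/2$ and others as $\beta/2$ for the same
term; this package reserves $\beta$ for the splitting penalty throughout
and lets $\alpha$ enter the PnP solver only through the default denoiser
strength $\sigma = \sqrt{\alpha/\beta}$ (the proximal-operator
correspondence). `sigma_mode` selects that default, a user-fixed
$\sigma$, or a geometric decay schedule.

With identity fidelity weight the $\chi$-subproblem is solved exactly in
one Fourier division; with a binary mask or magnitude-derived weights it
is solved by warm-started conjugate gradients on the normal equations
(`cg_iters`, `cg_tol`). The two paths agree to $10^{-6}$ relative when
$M \equiv 1$, and that equivalence is a test.

An optional *adding-noise-back* step (`noise_back_lambda` $\in [0,1]$,
default 0 = off) refreshes the observation once per outer iteration as
$\phi \leftarrow \phi + \lambda(\phi - A\chi)$, countering the
progressive over-smoothing of iterated denoising. The exact placement and
form of this step varies across the literature; the $\lambda$-mixing form
applied before the $\chi$-update is this package's documented choice.

Initialization is $\chi^0 = v^0 = u^0 = 0$ (or a supplied `initial_chi`,
which also seeds $v^0$). Iterations stop at `max_iters` or when the
relative change of $\chi$ drops below `rel_tol` (default $10^{-3}$). No
reference values for $\mu$, $\alpha$, $\beta$ or iteration counts exist
for this family of reconstructions beyond "empirically tuned", so the
defaults ($\mu = 1$, $\beta = 1$, `max_iters = 50`) are plain starting
points, exposed in every interface and recorded in the run manifest.

## Denoisers

The block-matching collaborative-filtering family is implemented from
scratch (C++ hot loops, exported pure-R reference pipeline —
`block_match()`, `collaborative_filter()`, `aggregate_patches()` — that
the tests cross-check against the compiled path):

* **bm4d**: 3D patches (default $4^3$), grouped by mean-squared distance
  within a search radius (default 4) into stacks of up to 16, separable
  orthonormal DCT over the three patch axes and the grouping axis, hard
  threshold at $2.7\sigma$ with the group DC always retained, aggregation
  weight $1/(1+N_\text{retained})$, optional empirical-Wiener second
  stage (default off). These are the classic published defaults for
  volumetric collaborative filtering; the reference stride is half the
  patch (minimum 1), which guarantees coverage, and matching is done on
  the raw volume (no coarse pre-filter stage — a deliberate
  simplification).
* **bm3d_slices**: the same pipeline with 2D patches, applied
  independently per axial slice.
* **nlpca**: per reference patch, the matched group is mean-centered and
  decomposed along principal axes; components are kept when their
  variance exceeds the noise floor of a pure-noise patch matrix, the
  Marchenko–Pastur edge $\sigma^2(\sqrt{g-1}+\sqrt{p})^2/(g-1)$ for $g$
  patches of $p$ voxels. A naive per-component $\sigma^2$ cutoff retains
  essentially every noise component and denoises nothing measurable; the
  MP edge is the statistically calibrated version of the same idea. This
  denoiser is a nonlocal-PCA approximation in the spirit of
  texture-adaptive clustering methods, not a reimplementation of any
  published codebase.
* **nlm**: nonlocal means with the noise-compensated weight
  $\exp(-\max(d^2 - 2\sigma^2, 0)/h^2)$, $h = 0.75\sigma$; its search
  window is capped at radius 3 because it visits every voxel rather than
  a patch stride.
* **gaussian**: separable Gaussian smoothing; for this baseline $\sigma$
  doubles as the spatial bandwidth in voxels, so $\sigma \to 0$ is the
  identity.

All denoisers are deterministic, treat constant volumes as exact fixed
points, and restrict work to the mask's bounding box when a mask is
present.

## The synthetic phantoms

`make_phantom()` voxelizes spheres/ellipsoids/cuboids by center-of-voxel
membership — no antialiasing, so per-ROI means are exactly the assigned
values, which the ROI-recovery tests rely on. `analytic_sphere_field()`
is the independent oracle for the forward model: the closed-form external
dipole field $(\Delta\chi/3)(a/r)^3(3\cos^2\theta - 1)$ with zero
(Lorentz-corrected) internal field. The discrete convolution matches it
to well under 5% relative $L_2$ error over the shell $1.5a < r < 3a$ on a
$128^3$ grid.

`make_brainlike_phantom()` is an engineered stand-in for a brain, not a
reproduction of any subject: an ellipsoidal support with eight labeled
structures spanning $-0.045$ to $0.15$ ppm (globus pallidus, putamen,
caudate, thalamus, white matter, CSF analogues), four thin cylindrical
"veins" at 0.30 ppm and 2–3 voxels across, and a smooth random
intra-tissue texture of 0.008 ppm amplitude. The texture covers *all*
tissue, including ROI interiors, re-centered within each ROI so the
assigned means stay exact. That choice matters: a phantom with perfectly
uniform ROI interiors is precisely the image model for which a TV prior
is the oracle, and it cannot discriminate between smoothness priors and
patch-based priors; textured interiors and thin vessels are the features
that patch-based denoising is claimed to preserve. Field observations add
i.i.d. Gaussian noise of 0.004 ppm (about 5% of the peak field, a
realistic SNR for 3 T gradient-echo field maps) after the convolution —
noise lives in the field, not the raw complex signal.

What the phantom does *not* emulate: phase wrapping and unwrapping
residue, background-field removal error, spatially varying phase noise,
flow and motion, microstructure anisotropy, partial-volume antialiasing.
Passing tests therefore validate the inversion and denoising machinery
under the stated forward model, not end-to-end performance on scanner
data.

## Metrics

`metrics_report()` mirrors the standard QSM evaluation panel: RMSE and
HFEN in the $\times 100$ normalized convention
($100\,\lVert t - r\rVert_2 / \lVert r\rVert_2$, HFEN after a
Laplacian-of-Gaussian filter of size 15 and $\sigma = 1.5$ voxels — the
reconstruction-challenge parameters, adopted because the metric's users
expect magnitudes on that scale); SSIM in 3D with an 11-point Gaussian
window ($\sigma = 1.5$) and standard constants, dynamic range taken from
the reference within the mask; Pearson cross correlation; Shannon mutual
information over a 64-bin joint histogram (each variable binned over its
own masked range, natural log); and a no-reference perceptual blur score
computed per axial slice (neighboring-pixel variation before vs after a
fixed 9-tap low-pass, averaged over mask-intersecting slices; 0 = sharp,
1 = blurred). Every metric is invariant to voxels outside the mask.
`roi_analysis()` reports per-ROI means, ordinary least-squares slope and
$R^2$ (with intercept — the convention when none is stated), and a
Bland–Altman bias $\pm 2\sigma$ summary.

## Numerical choices and degenerate inputs

* FFTs are unnormalized forward / $1/N$ inverse (`stats::fft`); all
  operators take the real part after the inverse transform.
* The $k = 0$ bin: kernel DC is `dc_value` (default 0); the
  gradient-mode Tikhonov filter and the TV $\chi$-update define the DC
  of the solution as 0 (zero-mean susceptibility), since neither the
  data nor a gradient penalty constrains it.
* Kernel values are clamped to the closed interval $[-2/3, 1/3]$; bare
  floating-point evaluation lands one ulp outside at the poles.
* Block-matching ties are broken by lexicographic corner order with the
  reference always first; thresholding keeps coefficients with
  $|c| \ge 2.7\sigma$ and always the group DC.
* TKD treats $\operatorname{sign}(0)$ as $+1$ when clipping the kernel.
* Degenerate metric inputs fail loudly (constant reference for CC/SSIM,
  zero reference for RMSE/HFEN, empty masks) except MI, which returns 0
  for a degenerate histogram.
* Divisions guard their zero sets explicitly; the aggregation step
  errors on uncovered voxels rather than renormalizing silently.

## Problem sizes and reproducibility

The bundled experiments use sizes a laptop handles comfortably: the
sphere oracle at $128^3$, denoiser contracts at $64^3$, and the
end-to-end solver comparison and ROI recovery on the $96^3$ brain-like
phantom with 0.004 ppm field noise — chosen as the smallest grid on which
the thin vessels and eight ROIs remain well resolved. For the comparison,
each solver is tuned on its own terms (the standard practice for
reconstruction baselines): Tikhonov $\alpha = 0.03$ (gradient mode), TV
$\alpha = 5\times 10^{-4}$ with $\beta = 10\alpha$, and for PnP-BM4D the
configuration returned by `qsmpnp_pnp_reference_params()` — $\mu = 1$,
$\beta = 0.05$ (fidelity-dominated splitting), fixed
$\sigma = 5\times$ the field-noise level (the empirical artifact scale of
the $\chi$-iterates), the Wiener second stage, and binary-mask fidelity
weighting via warm-started CG. The masked fidelity matters: with identity
weighting the model demands a vanishing field outside the brain, which
measurably distorts boundary structures. The adding-noise-back step is
left at its default $\lambda = 0$ in this study — on this phantom it
traded accuracy for sharpness unfavourably — but remains available and
tested. Every stochastic step (phantom geometry,
texture, observation noise) is a pure function of an integer seed, and
`run_pipeline()` writes a manifest (config + seed + versions) sufficient
to reproduce any output bundle bit for bit.

## Known limitations

* Circular convolution wraps sources that touch the boundary; use the
  padded forward mode for phantoms near the edge.
* The slice-wise blur metric needs slices of at least $11 \times 11$
  voxels and skips smaller or constant slices.
* The PnP loop offers no convergence guarantee for non-expansive-ness
  violating denoisers (none is claimed in the literature for this class);
  the residual history in the returned fit object is the practical
  diagnostic, and `autoplot()` displays it.
* MEDI- and TGV-family solvers, multi-orientation (COSMOS/STI)
  reconstruction, phase preprocessing and brain extraction are out of
  scope; reconstructions here start from a local field map.
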