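# qsmpnp — plug-and-play ADMM dipole inversion for QSM

Quantitative susceptibility mapping (QSM) estimates the tissue magnetic
susceptibility distribution χ (ppm) from the local magnetic field map φ
measured by gradient-echo MRI phase. The field is a dipole convolution of
the susceptibility, diagonal in the Fourier domain:

    Fφ = D·Fχ + Fn,    D(k) = 1/3 − (k·b̂₀)² / |k|²

`D` vanishes on the magic-angle cone (≈54.7° to B0), so inverting a
single-orientation acquisition is ill-posed and needs regularization.
Classical choices (Tikhonov, total variation) impose smoothness and blur
the fine structure — vessels, cortical folds, textured deep gray matter —
that clinicians actually look at.

This package implements **plug-and-play (PnP) ADMM** dipole inversion for
R users: the ADMM splitting χ = v turns the regularizer update into a
proximal step, and the PnP idea replaces that step with one application of
an arbitrary denoiser D<sub>σ</sub>:

    χ ← argmin (β/2)‖χ − v + u‖² + (μ/2)‖M(F<sup>H</sup>DFχ − φ)‖²   (Fourier or CG solve)
    v ← D_σ(χ + u)                                                   (any denoiser)
    u ← u + χ − v                                                    (multiplier)

Any denoiser registered with `register_denoiser()` plugs in without
touching the solver. Shipped denoisers: volumetric block-matching
collaborative filtering (`bm4d`, with optional Wiener second stage), its
slice-wise 2D variant (`bm3d_slices`), nonlocal PCA (`nlpca`), nonlocal
means (`nlm`), and a Gaussian baseline. Baselines: closed-form Tikhonov
(`l2_closed_form`), total-variation ADMM (`tv_admm`), truncated k-space
division (`tkd_invert`). An optional *adding-noise-back* step feeds a
fraction of the data residual back into the observation each iteration to
counter over-smoothing.

Also included: a synthetic phantom generator with an analytic sphere-field
oracle and a brain-like labeled phantom; the standard QSM image-quality
panel (normalized RMSE, HFEN, 3D SSIM, cross correlation, mutual
information, no-reference blur); ROI statistics with linear regression and
Bland–Altman summaries; NIfTI I/O and radians↔ppm conversion; and a
`qsm` command-line tool (`exec/qsm`) with `simulate`, `reconstruct`,
`eval`, `denoise` and `benchmark` subcommands.

Who it is for: researchers prototyping QSM regularizers/denoisers who want
a self-contained, tested R implementation with honest synthetic ground
truth — not a clinical pipeline (phase unwrapping, background-field
removal and brain extraction are upstream and out of scope).

## Worked example

Simulate a brain-like phantom, reconstruct it three ways, and compare
against the known truth:

```r
library(qsmpnp)

shape  <- c(96, 96, 96)
ph     <- make_brainlike_phantom(seed = 1, shape = shape)
kernel <- dipole_kernel(shape, ph$chi$voxel_size)
phi    <- simulate_observation(ph$chi, kernel, sigma = 0.004, seed = 2)

rec_l2 <- l2_closed_form(phi, kernel, alpha = 0.03)
fit_tv <- tv_admm(phi, kernel, admm_params(mu = 1, alpha = 5e-4, beta = 5e-3,
                                           max_iters = 50, rel_tol = 5e-4))
fit_pnp <- pnp_admm(phi, kernel, qsmpnp_pnp_reference_params(0.004))

m <- ph$mask$data
rbind(
  l2  = unlist(metrics_report(rec_l2$data * m,      ph$chi, m)[c("rmse","hfen","ssim")]),
  tv  = unlist(metrics_report(fit_tv$chi$data * m,  ph$chi, m)[c("rmse","hfen","ssim")]),
  pnp = unlist(metrics_report(fit_pnp$chi$data * m, ph$chi, m)[c("rmse","hfen","ssim")]))
```

```
       rmse    hfen   ssim
l2  57.9179 50.8632 0.6253
tv  30.3499 23.9029 0.7202
pnp 29.6480 22.4137 0.7404
```

RMSE/HFEN are in the ×100 normalized convention (100 = error as large as
the reference); SSIM is in [−1, 1]. The PnP-BM4D reconstruction improves
on the Tikhonov baseline on all three metrics and preserves the thin
vessels and intra-tissue texture that TV flattens.

ROI agreement of the PnP map with the ground truth:

```r
roi <- roi_analysis(fit_pnp$chi, ph$chi, ph$labels)
glance(roi)
```

```
  slope intercept r_squared  p_value     bias two_sigma n_roi
1 0.891  -0.00162     0.995 3.28e-08 -0.00726    0.0159     8
```

i.e. the per-ROI means regress onto the truth with slope β close to 1,
R² near 1 and negligible Bland–Altman bias. `tidy(fit_pnp)` returns the
per-iteration residual history and `autoplot(fit_pnp)` plots it;
`autoplot(roi)` draws the regression scatter.

The same pipeline from the shell:

```sh
exec/qsm simulate --out phantom_dir --seed 7
exec/qsm reconstruct --field phantom_dir/phi.nii.gz --mask phantom_dir/mask.nii.gz \
        --truth phantom_dir/chi.nii.gz --labels phantom_dir/labels.nii.gz \
        --solver pnp --denoiser bm4d --out recon_dir
exec/qsm eval --test recon_dir/chi.nii.gz --reference phantom_dir/chi.nii.gz \
        --mask phantom_dir/mask.nii.gz --out eval_dir
```

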