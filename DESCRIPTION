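Package: qsmpnp
Title: Plug-and-Play ADMM Dipole Inversion for Quantitative Susceptibility Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative susceptibility mapping (QSM) reconstruction by
    Fourier-domain dipole inversion. Implements the plug-and-play (PnP)
    alternating direction method of multipliers in which the regularizer's
    proximal step is replaced by an interchangeable patch-based denoiser
    (volumetric and slice-wise block-matching collaborative filtering,
    nonlocal PCA, nonlocal means, Gaussian), alongside closed-form Tikhonov,
    total-variation ADMM and truncated k-space division baselines. Includes
    a synthetic phantom generator with an analytic sphere-field oracle,
    image-quality metrics (RMSE, HFEN, SSIM, mutual information, cross
    correlation, perceptual blur), region-of-interest statistics with linear
    regression and Bland-Altman summaries, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
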