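#' Specify a denoiser for the plug-and-play prior
#'
#' A `denoiser_spec` names a registered denoiser and carries its strength
#' (the assumed noise standard deviation `sigma`, in image units) together
#' with the patch and grouping parameters of the block-matching family.
#' The callable contract is v <- D_sigma(chi + u): the v-subproblem of the
#' ADMM splitting is replaced by one application of the denoiser.
#'
#' Registered denoisers:
#' \describe{
#'   \item{identity}{returns its input; useful for solver diagnostics.}
#'   \item{gaussian}{separable Gaussian smoothing; `sigma` doubles as the
#'     spatial bandwidth in voxels for this baseline.}
#'   \item{nlm}{nonlocal means with noise-compensated patch weights.}
#'   \item{bm3d_slices}{block-matching collaborative filtering with 2D
#'     patches, applied independently per axial slice.}
#'   \item{bm4d}{volumetric block matching: 3D patches grouped into a 4th
#'     dimension, separable orthonormal cosine transform, hard threshold at
#'     `hard_threshold_factor * sigma` (group DC retained), weighted
#'     aggregation, optional empirical-Wiener second stage.}
#'   \item{nlpca}{nonlocal principal-component denoiser: matched patch
#'     groups are decomposed along principal axes and components with
#'     variance below sigma^2 are discarded. An approximation in the
#'     spirit of texture-adaptive nonlocal-PCA methods, not a
#'     reimplementation of any published codebase.}
#' }
#'
#' @param name denoiser name; see Details.
#' @param sigma assumed noise standard deviation (> 0), image units.
#' @param patch_size patch edge length in voxels (>= 2).
#' @param search_radius block-matching search radius in voxels.
#' @param max_group_size maximum number of patches per group (>= 1).
#' @param hard_threshold_factor threshold in units of sigma (default 2.7,
#'   the classic collaborative-filtering value).
#' @param wiener_stage run an empirical-Wiener second pass using the
#'   hard-threshold output as pilot (default off).
#' @return An object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(name, sigma, patch_size = 4L, search_radius = 4L,
                          max_group_size = 16L, hard_threshold_factor = 2.7,
                          wiener_stage = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  patch_size <- as.integer(patch_size)
  max_group_size <- as.integer(max_group_size)
  if (patch_size < 2L) stop("`patch_size` must be >= 2", call. = FALSE)
  if (max_group_size < 1L) stop("`max_group_size` must be >= 1", call. = FALSE)
  name <- as.character(name)
  if (!name %in% registered_denoisers())
    stop(sprintf("unknown denoiser '%s'; registered: %s", name,
                 paste(registered_denoisers(), collapse = ", ")),
         call. = FALSE)
  structure(list(name = name, sigma = sigma, patch_size = patch_size,
                 search_radius = as.integer(search_radius),
                 max_group_size = max_group_size,
                 hard_threshold_factor = hard_threshold_factor,
                 wiener_stage = isTRUE(wiener_stage)),
            class = "denoiser_spec")
}

.denoiser_registry <- new.env(parent = emptyenv())

#' Register a denoiser under a name
#'
#' The registry is what makes the ADMM loop plug-and-play: any function
#' with signature `function(arr, spec)` returning an array of the same
#' shape can be plugged into [pnp_admm()] without touching the solver.
#'
#' @param name registry key.
#' @param fn function of (3D array, `denoiser_spec`) returning a 3D array.
#' @export
register_denoiser <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .denoiser_registry)
  invisible(name)
}

#' @rdname register_denoiser
#' @export
registered_denoisers <- function() sort(ls(.denoiser_registry))

#' Apply a denoiser to a volume
#'
#' Dispatches to the registered denoiser named in `spec`. If the volume
#' carries a mask, denoising is restricted to the bounding box of the mask
#' (padded by one patch) and voxels outside that box are passed through
#' unchanged.
#'
#' @param volume `volume_grid` or 3D array.
#' @param spec `denoiser_spec`.
#' @return A `volume_grid` with the same metadata.
#' @export
denoise <- function(volume, spec) {
  volume <- as_volume_grid(volume)
  stopifnot(inherits(spec, "denoiser_spec"))
  if (!all(is.finite(volume$data)))
    stop("`volume` contains non-finite values", call. = FALSE)
  fn <- get(spec$name, envir = .denoiser_registry)
  arr <- volume$data
  if (!is.null(volume$mask) && any(volume$mask == 0)) {
    idx <- which(volume$mask > 0, arr.ind = TRUE)
    p <- spec$patch_size
    lo <- pmax(apply(idx, 2, min) - p, 1L)
    hi <- pmin(apply(idx, 2, max) + p, dim(arr))
    sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- fn(sub, spec)
  } else {
    arr <- fn(arr, spec)
  }
  vg_with_data(volume, arr)
}

#' Find the patches most similar to a reference patch
#'
#' Scans all patch corners within `search_radius` of the reference corner
#' and returns the corners of the at most `max_group_size` patches with
#' smallest mean-squared distance to the reference patch. The reference is
#' always first; ties are broken by lexicographic corner order.
#'
#' @param volume `volume_grid` or 3D array.
#' @param corner 1-based (x, y, z) corner of the reference patch, which
#'   must lie fully inside the volume.
#' @param spec `denoiser_spec` supplying `patch_size`, `search_radius`,
#'   `max_group_size`.
#' @param patch optional length-3 patch shape overriding
#'   `spec$patch_size^3` (e.g. `c(p, p, 1)` for slice-wise 2D patches).
#' @return Integer matrix of 1-based corners, one row per matched patch.
#' @export
block_match <- function(volume, corner, spec, patch = NULL) {
  arr <- as.array(as_volume_grid(volume))
  if (is.null(patch)) patch <- rep(spec$patch_size, 3L)
  patch <- as.integer(patch)
  corner <- as.integer(corner)
  if (any(patch > dim(arr)))
    stop("patch larger than volume", call. = FALSE)
  if (any(corner < 1L) || any(corner + patch - 1L > dim(arr)))
    stop("reference patch not fully inside the volume", call. = FALSE)
  out <- cpp_block_match(as.vector(arr), dim(arr), corner - 1L, patch,
                         rep(as.integer(spec$search_radius), 3L),
                         spec$max_group_size)
  out + 1L
}

# orthonormal DCT-II matrix (R mirror of the C++ one)
dct_mat <- function(n) {
  k <- seq_len(n) - 1
  j <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * j + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}

#' Collaborative filtering of a patch group
#'
#' Applies the separable orthonormal cosine transform across the patch
#' dimensions and the grouping dimension, hard-thresholds every
#' coefficient at `hard_threshold_factor * sigma` (the group-wide DC is
#' always retained), inverts the transform, and reports the aggregation
#' weight 1 / (1 + N_retained).
#'
#' @param group numeric array of stacked patches, dim
#'   `c(n_patches, px, py, pz)`.
#' @param spec `denoiser_spec`.
#' @return List with `filtered` (same shape as `group`), `weight`, and
#'   `n_retained`.
#' @export
collaborative_filter <- function(group, spec) {
  stopifnot(is.array(group), length(dim(group)) == 4L, dim(group)[1] >= 1L)
  g <- dim(group)[1]
  pd <- dim(group)[-1]
  pvox <- prod(pd)
  G <- matrix(group, nrow = g)                      # g x pvox, x fastest
  Tp <- dct_mat(pd[3]) %x% dct_mat(pd[2]) %x% dct_mat(pd[1])
  Cg <- dct_mat(g)
  coefs <- Cg %*% G %*% t(Tp)
  thr <- spec$hard_threshold_factor * spec$sigma
  keep <- abs(coefs) >= thr
  keep[1, 1] <- TRUE                                # group DC retained
  n_retained <- sum(coefs != 0 & keep)
  coefs[!keep] <- 0
  filt <- t(Cg) %*% coefs %*% Tp
  list(filtered = array(filt, dim = dim(group)),
       weight = 1 / (1 + n_retained),
       n_retained = n_retained)
}

#' Weighted aggregation of filtered patch groups
#'
#' Recomposes a volume from overlapping patch estimates as the per-voxel
#' weighted average. With identity filtering this is an exact partition of
#' unity: the input volume is reproduced wherever it was covered.
#'
#' @param corners list of integer matrices of 1-based patch corners
#'   (one matrix per group, rows = patches).
#' @param groups list of patch-stack arrays, dim `c(n_patches, px, py, pz)`.
#' @param weights numeric vector, one aggregation weight per group.
#' @param shape output volume shape.
#' @return 3D array. Errors if any voxel is left uncovered (the stride
#'   contract guarantees coverage in the denoising pipelines).
#' @export
aggregate_patches <- function(corners, groups, weights, shape) {
  stopifnot(length(corners) == length(groups),
            length(weights) == length(groups))
  num <- array(0, shape)
  den <- array(0, shape)
  for (k in seq_along(groups)) {
    pd <- dim(groups[[k]])[-1]
    w <- weights[k]
    cm <- corners[[k]]
    for (j in seq_len(nrow(cm))) {
      xi <- cm[j, 1]:(cm[j, 1] + pd[1] - 1L)
      yi <- cm[j, 2]:(cm[j, 2] + pd[2] - 1L)
      zi <- cm[j, 3]:(cm[j, 3] + pd[3] - 1L)
      num[xi, yi, zi] <- num[xi, yi, zi] + w * groups[[k]][j, , , ]
      den[xi, yi, zi] <- den[xi, yi, zi] + w
    }
  }
  if (any(den == 0))
    stop("internal error: uncovered voxels in aggregation (stride contract violated)",
         call. = FALSE)
  num / den
}

# reference-corner sequence matching the C++ corner_seq (1-based)
corner_seq_r <- function(n, p, s) {
  cs <- seq.int(0L, n - p, by = s)
  if (cs[length(cs)] != n - p) cs <- c(cs, n - p)
  cs + 1L
}

# pure-R block-matching collaborative-filtering pass; reference
# implementation cross-checked against the C++ fast path in the tests
bm_denoise_reference <- function(arr, spec, patch = rep(spec$patch_size, 3L)) {
  d <- dim(arr)
  stride <- pmax(patch %/% 2L, 1L)
  search <- rep(as.integer(spec$search_radius), 3L)
  if (patch[3] == 1L) search[3] <- 0L
  corners <- expand.grid(x = corner_seq_r(d[1], patch[1], stride[1]),
                         y = corner_seq_r(d[2], patch[2], stride[2]),
                         z = corner_seq_r(d[3], patch[3], stride[3]))
  all_corners <- list(); all_groups <- list(); all_w <- numeric(0)
  for (i in seq_len(nrow(corners))) {
    cm <- block_match(arr, unlist(corners[i, ]), spec, patch = patch)
    grp <- array(0, c(nrow(cm), patch))
    for (j in seq_len(nrow(cm)))
      grp[j, , , ] <- arr[cm[j, 1]:(cm[j, 1] + patch[1] - 1L),
                          cm[j, 2]:(cm[j, 2] + patch[2] - 1L),
                          cm[j, 3]:(cm[j, 3] + patch[3] - 1L)]
    cf <- collaborative_filter(grp, spec)
    all_corners[[i]] <- cm
    all_groups[[i]] <- cf$filtered
    all_w[i] <- cf$weight
  }
  aggregate_patches(all_corners, all_groups, all_w, d)
}

#' Nonlocal-PCA patch denoiser
#'
#' For each reference patch: gather the matched group, remove the mean
#' patch, decompose the centered patch matrix along its principal axes,
#' retain the components whose variance exceeds the noise floor of a pure
#' sigma-noise patch matrix (the Marchenko-Pastur edge
#' sigma^2 (sqrt(g - 1) + sqrt(p))^2 / (g - 1) for g patches of p voxels),
#' reconstruct, and aggregate with weight 1 / (1 + n_components). Groups
#' smaller than 2 patches are passed through unchanged. As sigma tends to
#' 0 every component is retained and the input is reproduced.
#'
#' @inheritParams denoise
#' @return A `volume_grid`.
#' @export
nlpca_denoise <- function(volume, spec) {
  volume <- as_volume_grid(volume)
  vg_with_data(volume, nlpca_core(volume$data, spec))
}

nlpca_core <- function(arr, spec) {
  d <- dim(arr)
  p <- rep(spec$patch_size, 3L)
  stride <- pmax(p %/% 2L, 1L)
  rows <- cpp_match_all(as.vector(arr), d, p, stride,
                        rep(as.integer(spec$search_radius), 3L),
                        spec$max_group_size)
  # 0-based flat offsets of the voxels inside one patch
  off <- as.vector(outer(outer(0:(p[1] - 1), d[1] * (0:(p[2] - 1)), "+"),
                         d[1] * d[2] * (0:(p[3] - 1)), "+"))
  num <- array(0, d); den <- array(0, d)
  s2 <- spec$sigma^2
  for (r in seq_len(nrow(rows))) {
    cs <- rows[r, ]
    cs <- cs[cs >= 0L]
    g <- length(cs)
    X <- vapply(cs, function(cc) arr[cc + off + 1L], numeric(length(off)))
    X <- t(X)                                  # g x pvox
    if (g < 2L) {
      Xr <- X
      w <- 1
    } else {
      mu <- colMeans(X)
      Xc <- sweep(X, 2L, mu)
      sv <- svd(Xc)
      # per-component noise floor of a g x pvox i.i.d. Gaussian matrix
      # (Marchenko-Pastur edge): components below it carry no signal
      keep <- sv$d^2 > s2 * (sqrt(g - 1) + sqrt(length(off)))^2
      nk <- sum(keep)
      Xr <- if (nk == 0L) matrix(mu, nrow = g, ncol = length(mu), byrow = TRUE)
      else sweep(sv$u[, keep, drop = FALSE] %*%
                   (sv$d[keep] * t(sv$v[, keep, drop = FALSE])),
                 2L, mu, "+")
      w <- 1 / (1 + nk)
    }
    for (j in seq_len(g)) {
      ii <- cs[j] + off + 1L
      num[ii] <- num[ii] + w * Xr[j, ]
      den[ii] <- den[ii] + w
    }
  }
  out <- num / den
  out[den == 0] <- arr[den == 0]
  out
}

# --- registered denoiser implementations -------------------------------

denoiser_identity <- function(arr, spec) arr

denoiser_gaussian <- function(arr, spec) {
  sd_vox <- spec$sigma            # baseline: sigma doubles as bandwidth
  r <- ceiling(4 * sd_vox)
  if (r < 1) return(arr)
  k <- exp(-((-r):r)^2 / (2 * sd_vox^2))
  k <- k / sum(k)
  d <- dim(arr)
  # circular separable convolution via FFT (unit DC gain)
  kern_axis <- function(n) {
    kk <- numeric(n)
    idx <- ((-r):r) %% n + 1L
    for (i in seq_along(idx)) kk[idx[i]] <- kk[idx[i]] + k[i]
    Re(stats::fft(kk))
  }
  G <- array(kern_axis(d[1]), dim = d) *
    array(rep(kern_axis(d[2]), each = d[1]), dim = d) *
    array(rep(kern_axis(d[3]), each = d[1] * d[2]), dim = d)
  Re(ifft3(G * fft3(arr)))
}

denoiser_nlm <- function(arr, spec) {
  pr <- max(1L, spec$patch_size %/% 2L)
  h <- 0.75 * spec$sigma
  # nonlocal means visits every voxel, so its window is capped at radius 3
  sr <- min(as.integer(spec$search_radius), 3L)
  cpp_nlm(as.vector(arr), dim(arr), pr, sr, h, spec$sigma)
}

denoiser_bm4d <- function(arr, spec) {
  p <- rep(spec$patch_size, 3L)
  stride <- pmax(p %/% 2L, 1L)
  thr <- spec$hard_threshold_factor * spec$sigma
  out <- cpp_bm_denoise(as.vector(arr), dim(arr), p, stride,
                        rep(as.integer(spec$search_radius), 3L),
                        spec$max_group_size, thr, spec$sigma)
  if (spec$wiener_stage)
    out <- cpp_bm_denoise(as.vector(arr), dim(arr), p, stride,
                          rep(as.integer(spec$search_radius), 3L),
                          spec$max_group_size, thr, spec$sigma,
                          pilot_ = as.vector(out))
  out
}

denoiser_bm3d_slices <- function(arr, spec) {
  d <- dim(arr)
  p <- c(spec$patch_size, spec$patch_size, 1L)
  stride <- c(pmax(p[1:2] %/% 2L, 1L), 1L)
  search <- c(rep(as.integer(spec$search_radius), 2L), 0L)
  thr <- spec$hard_threshold_factor * spec$sigma
  out <- arr
  for (z in seq_len(d[3])) {
    sl <- arr[, , z, drop = FALSE]
    flt <- cpp_bm_denoise(as.vector(sl), c(d[1], d[2], 1L), p, stride,
                          search, spec$max_group_size, thr, spec$sigma)
    if (spec$wiener_stage)
      flt <- cpp_bm_denoise(as.vector(sl), c(d[1], d[2], 1L), p, stride,
                            search, spec$max_group_size, thr, spec$sigma,
                            pilot_ = as.vector(flt))
    out[, , z] <- flt
  }
  out
}

denoiser_nlpca <- function(arr, spec) nlpca_core(arr, spec)

register_builtin_denoisers <- function() {
  register_denoiser("identity", denoiser_identity)
  register_denoiser("gaussian", denoiser_gaussian)
  register_denoiser("nlm", denoiser_nlm)
  register_denoiser("bm4d", denoiser_bm4d)
  register_denoiser("bm3d_slices", denoiser_bm3d_slices)
  register_denoiser("nlpca", denoiser_nlpca)
}

#' Peak signal-to-noise ratio
#'
#' 10 log10(peak^2 / MSE) with `peak` the dynamic range of the reference
#' (max - min), optionally restricted to a mask.
#'
#' @param test,reference `volume_grid` or arrays of identical shape.
#' @param mask optional 0/1 array.
#' @return PSNR in dB.
#' @export
psnr <- function(test, reference, mask = NULL) {
  t <- as.array(as_volume_grid(test))
  r <- as.array(as_volume_grid(reference))
  stopifnot_same_shape(t, r)
  sel <- if (is.null(mask)) TRUE else as.array(as_volume_grid(mask)) > 0
  e <- (t - r)[sel]
  peak <- diff(range(r[sel]))
  10 * log10(peak^2 / mean(e^2))
}
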