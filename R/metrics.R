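# circular convolution of a 3D array with a small centered kernel,
# evaluated via the FFT; `offsets` are the kernel tap positions
conv3_centered <- function(arr, taps, offsets) {
  d <- dim(arr)
  K <- array(0, d)
  flat <- (offsets[[1]] %% d[1]) + d[1] * (offsets[[2]] %% d[2]) +
    d[1] * d[2] * (offsets[[3]] %% d[3])
  agg <- rowsum(taps, flat)          # collisions only if kernel wraps
  K[as.integer(rownames(agg)) + 1L] <- agg
  Re(ifft3(fft3(K) * fft3(arr)))
}

log_kernel_3d <- function(size = 15L, sigma = 1.5) {
  r <- (size - 1L) %/% 2L
  o <- -r:r
  G <- exp(-outer(outer(o^2, o^2, "+"), o^2, "+") / (2 * sigma^2))
  G <- G / sum(G)
  R2 <- outer(outer(o^2, o^2, "+"), o^2, "+")
  H <- G * (R2 - 3 * sigma^2) / sigma^4
  H - mean(H)   # zero DC response
}

gauss_kernel_3d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) %/% 2L
  o <- -r:r
  G <- exp(-outer(outer(o^2, o^2, "+"), o^2, "+") / (2 * sigma^2))
  G / sum(G)
}

prep_pair <- function(test, reference, mask) {
  t <- as.array(as_volume_grid(test))
  r <- as.array(as_volume_grid(reference))
  stopifnot_same_shape(t, r, "test and reference")
  m <- if (is.null(mask)) {
    rv <- as_volume_grid(reference)
    if (!is.null(rv$mask)) rv$mask else array(1, dim(r))
  } else as.array(as_volume_grid(mask))
  stopifnot_same_shape(m, r, "mask and reference")
  if (sum(m) == 0) stop("empty mask", call. = FALSE)
  list(t = t, r = r, m = m > 0)
}

#' Normalized root-mean-squared error
#'
#' 100 * ||test - reference||_2 / ||reference||_2 over mask voxels — the
#' reconstruction-challenge convention, so 100 means an error as large as
#' the reference itself.
#'
#' @param test,reference `volume_grid` or arrays of identical shape.
#' @param mask optional 0/1 array; defaults to the reference's own mask,
#'   else all voxels.
#' @return Non-negative scalar (percent).
#' @export
qsm_rmse <- function(test, reference, mask = NULL) {
  p <- prep_pair(test, reference, mask)
  rn <- sqrt(sum(p$r[p$m]^2))
  if (rn == 0) stop("reference is identically zero in the mask", call. = FALSE)
  100 * sqrt(sum((p$t[p$m] - p$r[p$m])^2)) / rn
}

#' High-frequency error norm
#'
#' 100 * ||LoG(test) - LoG(reference)||_2 / ||LoG(reference)||_2 over the
#' mask, with a Laplacian-of-Gaussian filter of kernel size 15 and
#' sigma = 1.5 voxels (the reconstruction-challenge convention). Because
#' LoG suppresses slowly varying content, HFEN is sensitive to the loss
#' of fine structure that global RMSE barely registers.
#'
#' @inheritParams qsm_rmse
#' @export
qsm_hfen <- function(test, reference, mask = NULL) {
  p <- prep_pair(test, reference, mask)
  H <- log_kernel_3d()
  o <- list(-7:7, -7:7, -7:7)
  lt <- conv3_centered(p$t * p$m, as.vector(H), expand_offsets(o))
  lr <- conv3_centered(p$r * p$m, as.vector(H), expand_offsets(o))
  rn <- sqrt(sum(lr[p$m]^2))
  if (rn == 0) stop("reference is identically zero in the mask", call. = FALSE)
  100 * sqrt(sum((lt[p$m] - lr[p$m])^2)) / rn
}

# expand per-axis offsets to the full tap grid (x fastest)
expand_offsets <- function(o) {
  nx <- length(o[[1]]); ny <- length(o[[2]]); nz <- length(o[[3]])
  list(rep(o[[1]], times = ny * nz),
       rep(rep(o[[2]], each = nx), times = nz),
       rep(o[[3]], each = nx * ny))
}

conv3_kernel <- function(arr, K) {
  r <- (dim(K) - 1L) %/% 2L
  o <- list(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3])
  conv3_centered(arr, as.vector(K), expand_offsets(o))
}

#' Structural similarity index (3D)
#'
#' Mean local SSIM with an 11-point Gaussian window (sigma 1.5 voxels)
#' and the standard constants K1 = 0.01, K2 = 0.03; the dynamic range is
#' the reference's max - min over the mask. When a dimension is smaller
#' than the window, the window shrinks to the largest odd size that fits.
#'
#' @inheritParams qsm_rmse
#' @return Scalar in \[-1, 1\].
#' @export
ssim_metric <- function(test, reference, mask = NULL) {
  p <- prep_pair(test, reference, mask)
  L <- diff(range(p$r[p$m]))
  if (L == 0) stop("constant reference: SSIM undefined", call. = FALSE)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  wsz <- min(11L, (min(dim(p$r)) %/% 2L) * 2L - 1L)
  K <- gauss_kernel_3d(size = wsz)
  x <- p$t * p$m; y <- p$r * p$m
  mx <- conv3_kernel(x, K); my <- conv3_kernel(y, K)
  sxx <- conv3_kernel(x * x, K) - mx^2
  syy <- conv3_kernel(y * y, K) - my^2
  sxy <- conv3_kernel(x * y, K) - mx * my
  smap <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(smap[p$m])
}

#' Pearson cross correlation over the mask
#' @inheritParams qsm_rmse
#' @export
cross_correlation <- function(test, reference, mask = NULL) {
  p <- prep_pair(test, reference, mask)
  if (stats::sd(p$r[p$m]) == 0)
    stop("constant reference: correlation undefined", call. = FALSE)
  stats::cor(p$t[p$m], p$r[p$m])
}

#' Mutual information over the mask
#'
#' Shannon mutual information of the joint intensity histogram (each
#' variable binned uniformly over its own range within the mask), in
#' nats. A degenerate (constant) histogram yields 0.
#'
#' @inheritParams qsm_rmse
#' @param bins number of histogram bins per axis (default 64).
#' @export
mutual_information <- function(test, reference, mask = NULL, bins = 64L) {
  p <- prep_pair(test, reference, mask)
  tv <- p$t[p$m]; rv <- p$r[p$m]
  bin_of <- function(x) {
    rg <- range(x)
    if (diff(rg) == 0) return(NULL)
    pmin(pmax(findInterval(x, seq(rg[1], rg[2], length.out = bins + 1L),
                           rightmost.closed = TRUE), 1L), bins)
  }
  bt <- bin_of(tv); br <- bin_of(rv)
  if (is.null(bt) || is.null(br)) return(0)
  joint <- table(factor(bt, levels = seq_len(bins)),
                 factor(br, levels = seq_len(bins)))
  pj <- joint / sum(joint)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

#' No-reference perceptual blur metric
#'
#' Per-axial-slice blur estimation by comparing neighboring-pixel
#' variation before and after a fixed 9-tap low-pass: a sharp image loses
#' much of its local variation when blurred (score near 0 means sharp,
#' near 1 means already blurred). Slices that do not intersect the mask,
#' or have no variation, are skipped; the slice scores are averaged.
#'
#' @param volume `volume_grid` or 3D array.
#' @param mask optional 0/1 array.
#' @return Scalar in \[0, 1\].
#' @export
blur_metric <- function(volume, mask = NULL) {
  vg <- as_volume_grid(volume)
  arr <- vg$data
  m <- if (!is.null(mask)) as.array(as_volume_grid(mask)) else
    if (!is.null(vg$mask)) vg$mask else array(1, dim(arr))
  stopifnot_same_shape(m, arr, "mask and volume")
  if (sum(m) == 0) stop("empty mask", call. = FALSE)
  arr <- arr * (m > 0)   # mask-external voxels must not influence the score
  scores <- c()
  for (z in seq_len(dim(arr)[3])) {
    if (sum(m[, , z]) == 0) next
    s <- blur_slice(arr[, , z])
    if (!is.na(s)) scores <- c(scores, s)
  }
  if (length(scores) == 0) stop("no usable slices in mask", call. = FALSE)
  mean(scores)
}

blur_slice <- function(F) {
  n <- dim(F)
  if (any(n < 11)) return(NA_real_)
  k <- rep(1 / 9, 9)
  Bv <- apply(F, 2, function(col) stats::filter(col, k, sides = 2))
  Bh <- t(apply(F, 1, function(row) stats::filter(row, k, sides = 2)))
  i <- 6:(n[1] - 5); j <- 6:(n[2] - 5)  # interior where the filter is valid
  dFv <- abs(F[i, j] - F[i - 1, j]);  dBv <- abs(Bv[i, j] - Bv[i - 1, j])
  dFh <- abs(F[i, j] - F[i, j - 1]);  dBh <- abs(Bh[i, j] - Bh[i, j - 1])
  sFv <- sum(dFv); sFh <- sum(dFh)
  if (sFv == 0 || sFh == 0) return(NA_real_)
  bv <- (sFv - sum(pmax(dFv - dBv, 0))) / sFv
  bh <- (sFh - sum(pmax(dFh - dBh, 0))) / sFh
  max(bv, bh)
}

#' Full image-quality metric panel
#'
#' Computes RMSE, HFEN, SSIM, cross correlation, mutual information and
#' the no-reference blur of the test volume, over the mask.
#'
#' @inheritParams mutual_information
#' @param test_id,reference_id free-text identifiers recorded in the report.
#' @return One-row tibble with columns `test_id`, `reference_id`, `rmse`,
#'   `hfen`, `ssim`, `cc`, `mi`, `blur`, `mask_voxels`.
#' @export
metrics_report <- function(test, reference, mask = NULL, bins = 64L,
                           test_id = "test", reference_id = "reference") {
  p <- prep_pair(test, reference, mask)
  tibble::tibble(
    test_id = test_id, reference_id = reference_id,
    rmse = qsm_rmse(test, reference, mask),
    hfen = qsm_hfen(test, reference, mask),
    ssim = ssim_metric(test, reference, mask),
    cc = cross_correlation(test, reference, mask),
    mi = mutual_information(test, reference, mask, bins = bins),
    blur = blur_metric(test, if (is.null(mask)) p$m * 1 else mask),
    mask_voxels = as.integer(sum(p$m)))
}

#' Region-of-interest agreement analysis
#'
#' Per-ROI mean susceptibilities of test and reference, compared by
#' ordinary least-squares regression (test mean on reference mean, with
#' intercept; reported as slope beta and R^2) and a Bland-Altman summary
#' (bias = mean of per-ROI differences, limits of agreement +/- 2 sigma).
#'
#' @param test,reference susceptibility volumes.
#' @param labels integer-valued label volume; ids > 0 are ROIs (at least
#'   two required).
#' @return An object of class `roi_table`: `$table` (tibble of per-ROI
#'   means), `$regression` (slope, intercept, r_squared, p_value),
#'   `$bland_altman` (bias, two_sigma). Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
roi_analysis <- function(test, reference, labels) {
  t <- as.array(as_volume_grid(test))
  r <- as.array(as_volume_grid(reference))
  l <- as.array(as_volume_grid(labels))
  stopifnot_same_shape(t, r, "test and reference")
  stopifnot_same_shape(l, r, "labels and reference")
  ids <- sort(unique(as.vector(l[l > 0])))
  if (length(ids) < 2L)
    stop("at least two ROIs are required for regression", call. = FALSE)
  rows <- lapply(ids, function(id) {
    sel <- l == id
    tibble::tibble(label = as.integer(id),
                   mean_chi_test = mean(t[sel]),
                   mean_chi_reference = mean(r[sel]),
                   n_voxels = as.integer(sum(sel)))
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(mean_chi_test ~ mean_chi_reference, data = tab)
  sm <- summary(fit)
  d <- tab$mean_chi_test - tab$mean_chi_reference
  structure(list(
    table = tab,
    regression = list(slope = unname(coef(fit)[2]),
                      intercept = unname(coef(fit)[1]),
                      r_squared = sm$r.squared,
                      p_value = unname(sm$coefficients[2, 4])),
    bland_altman = list(bias = mean(d), two_sigma = 2 * stats::sd(d))),
    class = "roi_table")
}

#' @export
print.roi_table <- function(x, ...) {
  cat(sprintf("<roi_table> %d ROIs\n", nrow(x$table)))
  cat(sprintf("  regression: slope = %.3f, intercept = %.4f, R^2 = %.3f\n",
              x$regression$slope, x$regression$intercept,
              x$regression$r_squared))
  cat(sprintf("  Bland-Altman: bias = %.4f +/- %.4f (2 sigma)\n",
              x$bland_altman$bias, x$bland_altman$two_sigma))
  print(x$table)
  invisible(x)
}

#' @export
tidy.roi_table <- function(x, ...) x$table

#' @export
glance.roi_table <- function(x, ...) {
  tibble::tibble(slope = x$regression$slope,
                 intercept = x$regression$intercept,
                 r_squared = x$regression$r_squared,
                 p_value = x$regression$p_value,
                 bias = x$bland_altman$bias,
                 two_sigma = x$bland_altman$two_sigma,
                 n_roi = nrow(x$table))
}

#' @export
autoplot.roi_table <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = mean_chi_reference,
                                    y = mean_chi_test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference ROI mean (ppm)", y = "test ROI mean (ppm)",
                  title = sprintf("slope = %.2f, R^2 = %.2f",
                                  object$regression$slope,
                                  object$regression$r_squared))
}
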