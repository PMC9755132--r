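# 3D FFT helpers. stats::fft is n-dimensional on arrays; the inverse is
# unnormalized, so divide by the number of voxels.
fft3 <- function(x) stats::fft(x)
ifft3 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# fftfreq-style index frequencies for axis of length n (cycles per sample)
fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(floor(n / 2)):-1)
  if (n == 1) k <- 0
  k / n
}

#' Fourier-domain magnetic dipole kernel
#'
#' Builds the unit dipole kernel D(k) = 1/3 - (k . b0)^2 / |k|^2 on the
#' unshifted FFT grid of the given shape. D relates susceptibility to the
#' measured local field in the Fourier domain, F phi = D F chi; it vanishes
#' on the magic-angle cone (about 54.7 degrees to B0), which is what makes
#' single-orientation dipole inversion ill-posed.
#'
#' Frequencies are physical (cycles/mm), so anisotropic voxels scale the
#' cone correctly. The value at k = 0 is undefined by the formula and is
#' set to `dc_value`; the default 0 enforces a zero-mean field response,
#' the standard QSM convention.
#'
#' @param shape integer length-3 grid shape, each dimension >= 4.
#' @param voxel_size voxel edge lengths in mm, all > 0.
#' @param b0_dir B0 direction; normalized if not unit length.
#' @param dc_value value assigned at the k = 0 bin (default 0).
#' @return An object of class `dipole_kernel` with fields `values` (3D real
#'   array, every value in \[-2/3, 1/3\]), `shape`, `voxel_size`, `b0_dir`
#'   and `dc_value`.
#' @examples
#' K <- dipole_kernel(c(16, 16, 16))
#' range(K$values)
#' @export
dipole_kernel <- function(shape, voxel_size = c(1, 1, 1), b0_dir = c(0, 0, 1),
                          dc_value = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("`shape` must be three integers, each >= 4", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("invalid geometry: voxel sizes must be strictly positive", call. = FALSE)
  b0_dir <- as.numeric(b0_dir)
  nb <- sqrt(sum(b0_dir^2))
  if (!is.finite(nb) || nb == 0)
    stop("`b0_dir` must be a non-zero finite vector", call. = FALSE)
  if (abs(nb - 1) > 1e-9) {
    warning("normalizing non-unit b0_dir", call. = FALSE)
    b0_dir <- b0_dir / nb
  }

  fx <- fft_freq(shape[1]) / voxel_size[1]
  fy <- fft_freq(shape[2]) / voxel_size[2]
  fz <- fft_freq(shape[3]) / voxel_size[3]
  KX <- array(fx, dim = shape)
  KY <- array(rep(fy, each = shape[1]), dim = shape)
  KZ <- array(rep(fz, each = shape[1] * shape[2]), dim = shape)
  K2 <- KX^2 + KY^2 + KZ^2
  KPAR <- KX * b0_dir[1] + KY * b0_dir[2] + KZ * b0_dir[3]
  D <- 1 / 3 - KPAR^2 / K2
  D <- pmin(pmax(D, -2 / 3), 1 / 3)   # clamp 1-ulp rounding to the true range
  D[K2 == 0] <- dc_value

  structure(
    list(values = D, shape = shape, voxel_size = voxel_size,
         b0_dir = b0_dir, dc_value = dc_value),
    class = "dipole_kernel"
  )
}

#' @export
print.dipole_kernel <- function(x, ...) {
  cat(sprintf("<dipole_kernel> %s grid, voxels %s mm, b0 (%.3g, %.3g, %.3g), D(0) = %g\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              x$b0_dir[1], x$b0_dir[2], x$b0_dir[3], x$dc_value))
  invisible(x)
}

check_kernel_shape <- function(vg, kernel) {
  if (!inherits(kernel, "dipole_kernel"))
    stop("`kernel` must be a dipole_kernel", call. = FALSE)
  if (!identical(dim(vg$data), kernel$shape))
    stop(sprintf("volume shape %s does not match kernel shape %s",
                 paste(dim(vg$data), collapse = "x"),
                 paste(kernel$shape, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

# core spectral multiply: real part of F^H { D . F x }
apply_kernel <- function(x, D) Re(ifft3(D * fft3(x)))

#' Forward dipole convolution: susceptibility to local field
#'
#' Computes phi = F^H \{ D F chi \}, the circular dipole convolution of a
#' susceptibility map. Optionally zero-pads the grid by a factor of two per
#' axis (and trims after the transform) to suppress wrap-around for sources
#' near the boundary.
#'
#' @param chi `volume_grid` (or 3D array) of susceptibility in ppm.
#' @param kernel `dipole_kernel` matching the grid shape.
#' @param pad logical; pad by 2x per axis before the convolution.
#' @return A `volume_grid` of the simulated local field, same metadata as
#'   `chi`, units inherited.
#' @seealso [adjoint_field()], [dipole_kernel()], [analytic_sphere_field()]
#' @export
forward_field <- function(chi, kernel, pad = FALSE) {
  chi <- as_volume_grid(chi)
  check_kernel_shape(chi, kernel)
  if (pad) {
    sh <- kernel$shape
    big <- array(0, 2L * sh)
    big[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])] <- chi$data
    Kbig <- dipole_kernel(2L * sh, kernel$voxel_size, kernel$b0_dir,
                          kernel$dc_value)
    out <- apply_kernel(big, Kbig$values)
    out <- out[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])]
  } else {
    out <- apply_kernel(chi$data, kernel$values)
  }
  vg_with_data(chi, out)
}

#' Adjoint of the forward dipole operator
#'
#' The dipole kernel is real and even, so the forward operator is
#' self-adjoint: the adjoint is the same spectral multiplication
#' F^H \{ D F phi \}. Exposed separately because the conjugate-gradient
#' data-consistency solver is written against a forward/adjoint pair.
#'
#' @inheritParams forward_field
#' @param phi `volume_grid` (or 3D array) of the local field.
#' @return A `volume_grid`.
#' @export
adjoint_field <- function(phi, kernel) {
  phi <- as_volume_grid(phi)
  check_kernel_shape(phi, kernel)
  vg_with_data(phi, apply_kernel(phi$data, kernel$values))
}

#' Truncated k-space division (TKD) inversion
#'
#' Direct dipole inversion with the kernel magnitude clipped away from
#' zero: chi_hat = F^H \{ F phi / D_trunc \} with D_trunc = D where
#' |D| >= threshold, else sign(D) * threshold (sign(0) taken as +1).
#' Fast, but underestimates susceptibility and amplifies noise near the
#' magic-angle cone; used here as a baseline and a round-trip oracle.
#'
#' @param phi `volume_grid` of the local field.
#' @param kernel `dipole_kernel`.
#' @param threshold truncation level, strictly inside (0, 2/3).
#' @return A `volume_grid` of estimated susceptibility.
#' @export
tkd_invert <- function(phi, kernel, threshold = 0.19) {
  phi <- as_volume_grid(phi)
  check_kernel_shape(phi, kernel)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 2 / 3)
    stop("`threshold` must lie strictly inside (0, 2/3)", call. = FALSE)
  D <- kernel$values
  sgn <- ifelse(D >= 0, 1, -1)   # sign(0) -> +1
  Dt <- ifelse(abs(D) >= threshold, D, sgn * threshold)
  out <- Re(ifft3(fft3(phi$data) / Dt))
  vg_with_data(phi, out)
}
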