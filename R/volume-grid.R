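#' 3D scalar volume with voxel geometry
#'
#' `volume_grid` is the carrier object for every 3D scalar field in the
#' package: susceptibility maps (chi, ppm), local tissue field maps (phi,
#' ppm of B0), magnitude images and integer label volumes. It bundles the
#' data array with the voxel size in mm, the main-field direction, an
#' optional binary mask, and a free-text units label.
#'
#' Axis order is fixed to (x, y, z); world coordinates via a NIfTI affine
#' are handled only at the I/O boundary ([read_volume()]/[write_volume()]).
#'
#' @param data 3D numeric array.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param b0_dir numeric length-3, direction of the static field B0.
#'   Normalized to unit length; a non-unit input is accepted with a warning.
#' @param mask optional 3D array of 0/1 (or logical), same shape as `data`.
#' @param units free-text units label, e.g. `"ppm"` or `"normalized field"`.
#' @return An object of class `volume_grid`.
#' @examples
#' vg <- volume_grid(array(0, c(8, 8, 8)))
#' dim(vg)
#' @export
volume_grid <- function(data, voxel_size = c(1, 1, 1), b0_dir = c(0, 0, 1),
                        mask = NULL, units = "ppm") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("invalid geometry: voxel sizes must be three strictly positive numbers",
         call. = FALSE)
  b0_dir <- as.numeric(b0_dir)
  if (length(b0_dir) != 3L || any(!is.finite(b0_dir)))
    stop("`b0_dir` must be a finite length-3 vector", call. = FALSE)
  nb <- sqrt(sum(b0_dir^2))
  if (nb == 0) stop("`b0_dir` must be non-zero", call. = FALSE)
  if (abs(nb - 1) > 1e-9) {
    warning("normalizing non-unit b0_dir", call. = FALSE)
    b0_dir <- b0_dir / nb
  }
  if (!is.null(mask)) {
    if (is.logical(mask)) { mode(mask) <- "double" }
    if (!is.array(mask) || !identical(dim(mask), dim(data)))
      stop("`mask` must be an array with the same shape as `data`", call. = FALSE)
    if (!all(mask %in% c(0, 1)))
      stop("`mask` values must be 0 or 1", call. = FALSE)
    storage.mode(mask) <- "double"
  }
  structure(
    list(data = data, voxel_size = voxel_size, b0_dir = b0_dir,
         mask = mask, units = units),
    class = "volume_grid"
  )
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
as.array.volume_grid <- function(x, ...) x$data

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm [%s]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$units))
  cat(sprintf("  b0_dir: (%.3g, %.3g, %.3g)   mask: %s\n",
              x$b0_dir[1], x$b0_dir[2], x$b0_dir[3],
              if (is.null(x$mask)) "none"
              else sprintf("%d voxels", as.integer(sum(x$mask)))))
  rng <- range(x$data)
  cat(sprintf("  data range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

# replace the data array, keeping grid metadata
vg_with_data <- function(vg, data, units = vg$units) {
  vg$data <- data
  vg$units <- units
  vg
}

# coerce array-or-volume_grid input to volume_grid, inheriting metadata
as_volume_grid <- function(x, template = NULL) {
  if (inherits(x, "volume_grid")) return(x)
  if (!is.null(template))
    return(vg_with_data(template, x))
  volume_grid(x)
}

vg_mask_or_ones <- function(vg) {
  if (is.null(vg$mask)) array(1, dim(vg$data)) else vg$mask
}

stopifnot_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
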