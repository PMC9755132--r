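# voxel-center world coordinates (mm): voxel i (1-based) sits at (i - 0.5) * dx
grid_coords <- function(shape, voxel_size) {
  list(x = (seq_len(shape[1]) - 0.5) * voxel_size[1],
       y = (seq_len(shape[2]) - 0.5) * voxel_size[2],
       z = (seq_len(shape[3]) - 0.5) * voxel_size[3])
}

# logical membership array for one inclusion, by center-of-voxel test
inclusion_membership <- function(kind, center, size, shape, voxel_size) {
  co <- grid_coords(shape, voxel_size)
  dx <- array(co$x - center[1], dim = shape)
  dy <- array(rep(co$y - center[2], each = shape[1]), dim = shape)
  dz <- array(rep(co$z - center[3], each = shape[1] * shape[2]), dim = shape)
  switch(kind,
    sphere = {
      r <- if (length(size) == 1) size else size[1]
      dx^2 + dy^2 + dz^2 <= r^2
    },
    ellipsoid = {
      s <- rep(size, length.out = 3) / 2  # size = full axes lengths (mm)
      (dx / s[1])^2 + (dy / s[2])^2 + (dz / s[3])^2 <= 1
    },
    cuboid = {
      s <- rep(size, length.out = 3) / 2
      abs(dx) <= s[1] & abs(dy) <= s[2] & abs(dz) <= s[3]
    },
    stop(sprintf("unknown inclusion kind '%s'", kind), call. = FALSE)
  )
}

#' Specify a synthetic susceptibility phantom
#'
#' A phantom is a background susceptibility plus a list of geometric
#' inclusions (spheres, ellipsoids, cuboids), each with its own
#' susceptibility in ppm and a unique positive label id. Geometry is given
#' in mm in the grid's world frame (voxel i centered at (i - 0.5) * dx).
#'
#' @param shape integer length-3 grid shape.
#' @param voxel_size voxel size in mm.
#' @param inclusions list of lists with fields `kind` ("sphere",
#'   "ellipsoid" or "cuboid"), `center` (mm), `size` (radius for spheres,
#'   full edge/axis lengths otherwise, mm), `chi` (ppm), `label`
#'   (unique integer > 0).
#' @param background susceptibility of the support outside inclusions (ppm).
#' @param texture_amplitude amplitude (ppm) of an optional smooth random
#'   field added outside the labeled inclusions; 0 disables it.
#' @param support optional inclusion-like list defining the mask support;
#'   default is the whole grid.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size = c(1, 1, 1), inclusions = list(),
                         background = 0, texture_amplitude = 0,
                         support = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  labels <- vapply(inclusions, function(i) as.integer(i$label), integer(1))
  if (anyDuplicated(labels) || any(labels <= 0))
    stop("inclusion labels must be unique integers > 0", call. = FALSE)
  extent <- shape * voxel_size
  for (inc in inclusions) {
    if (any(inc$center < 0) || any(inc$center > extent))
      stop("inclusion center outside the grid", call. = FALSE)
  }
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 inclusions = inclusions, background = background,
                 texture_amplitude = texture_amplitude, support = support),
            class = "phantom_spec")
}

# smooth zero-mean random field: white noise low-passed with a Gaussian in k
smooth_random_field <- function(shape, fwhm_vox = 8) {
  w <- array(stats::rnorm(prod(shape)), dim = shape)
  sig <- fwhm_vox / 2.355
  g <- function(n) exp(-2 * (pi * fft_freq(n) * sig)^2)
  G <- array(g(shape[1]), dim = shape) *
    array(rep(g(shape[2]), each = shape[1]), dim = shape) *
    array(rep(g(shape[3]), each = shape[1] * shape[2]), dim = shape)
  f <- Re(ifft3(G * fft3(w)))
  f <- f - mean(f)
  f / max(stats::sd(f), .Machine$double.eps)
}

#' Serialize a phantom specification to YAML
#'
#' `write_phantom_spec()` writes a [phantom_spec()] as a YAML file and
#' `read_phantom_spec()` reads it back, so phantom definitions can travel
#' with a reconstruction config (`qsm simulate --spec phantom.yaml`).
#'
#' @param spec a `phantom_spec`.
#' @param path YAML file path.
#' @return `write_phantom_spec()` returns `path` invisibly;
#'   `read_phantom_spec()` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("spec not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  inc <- lapply(raw$inclusions, function(i)
    list(kind = i$kind, center = as.numeric(i$center),
         size = as.numeric(i$size), chi = as.numeric(i$chi),
         label = as.integer(i$label)))
  sup <- if (is.null(raw$support)) NULL else
    list(kind = raw$support$kind, center = as.numeric(raw$support$center),
         size = as.numeric(raw$support$size))
  phantom_spec(shape = as.integer(raw$shape),
               voxel_size = as.numeric(raw$voxel_size),
               inclusions = inc,
               background = as.numeric(raw$background %||% 0),
               texture_amplitude = as.numeric(raw$texture_amplitude %||% 0),
               support = sup)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelize a phantom specification
#'
#' Rasterizes a [phantom_spec()] by center-of-voxel membership (no
#' antialiasing, so per-label means are exact). Overlapping inclusions are
#' resolved in list order: the later inclusion wins, with a warning.
#'
#' @param spec a `phantom_spec`.
#' @param seed RNG seed for the optional texture field.
#' @return A list with `volume_grid` components `chi` (ppm), `labels`
#'   (integer ids, 0 = unlabeled) and `mask`.
#' @examples
#' sp <- phantom_spec(c(32, 32, 32), inclusions = list(
#'   list(kind = "sphere", center = c(16, 16, 16), size = 6,
#'        chi = 0.1, label = 1L)))
#' ph <- make_phantom(sp)
#' sort(unique(as.vector(ph$chi$data)))
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  support <- if (is.null(spec$support)) array(TRUE, shape) else
    inclusion_membership(spec$support$kind, spec$support$center,
                         spec$support$size, shape, spec$voxel_size)
  chi <- array(0, shape)
  chi[support] <- spec$background
  labels <- array(0L, shape)
  claimed <- array(FALSE, shape)
  for (inc in spec$inclusions) {
    mem <- inclusion_membership(inc$kind, inc$center, inc$size, shape,
                                spec$voxel_size)
    if (any(mem & claimed))
      warning("overlapping inclusions: later inclusion wins in the overlap",
              call. = FALSE)
    chi[mem] <- inc$chi
    labels[mem] <- as.integer(inc$label)
    claimed <- claimed | mem
  }
  if (spec$texture_amplitude > 0) {
    # smooth intra-tissue texture over the whole support; re-centered per
    # labeled ROI so that per-label means remain exactly the assigned values
    tex <- with_preserved_seed(seed, smooth_random_field(shape))
    tex <- spec$texture_amplitude * tex
    for (inc in spec$inclusions) {
      sel <- labels == inc$label
      if (any(sel)) tex[sel] <- tex[sel] - mean(tex[sel])
    }
    chi[support] <- chi[support] + tex[support]
  }
  mask <- array(0, shape)
  mask[support | claimed] <- 1
  vs <- spec$voxel_size
  list(
    chi = volume_grid(chi, vs, mask = mask, units = "ppm"),
    labels = volume_grid(array(as.double(labels), shape), vs, mask = mask,
                         units = "label"),
    mask = volume_grid(mask, vs, units = "mask")
  )
}

# run expr under a fixed RNG seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Analytic field of a uniformly magnetized sphere
#'
#' Point-wise closed form for the field of a sphere of susceptibility
#' contrast `delta_chi` in an infinite medium: outside,
#' (delta_chi / 3) (a / r)^3 (3 cos^2 theta - 1) with theta measured from
#' the B0 direction; inside, 0 (the Lorentz-corrected internal field).
#' Serves as the independent oracle for the discrete dipole convolution.
#'
#' @param shape,voxel_size grid geometry.
#' @param center sphere center in mm.
#' @param radius sphere radius in mm (at least 2 voxels).
#' @param delta_chi susceptibility contrast in ppm.
#' @param b0_dir B0 direction.
#' @return A `volume_grid` of the analytic field (ppm).
#' @export
analytic_sphere_field <- function(shape, voxel_size, center, radius,
                                  delta_chi, b0_dir = c(0, 0, 1)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (radius < 2 * min(voxel_size))
    stop("`radius` must be at least 2 voxels", call. = FALSE)
  extent <- shape * voxel_size
  if (any(center < 0) || any(center > extent))
    stop("sphere center outside the grid", call. = FALSE)
  b0_dir <- b0_dir / sqrt(sum(b0_dir^2))
  co <- grid_coords(shape, voxel_size)
  dx <- array(co$x - center[1], dim = shape)
  dy <- array(rep(co$y - center[2], each = shape[1]), dim = shape)
  dz <- array(rep(co$z - center[3], each = shape[1] * shape[2]), dim = shape)
  r2 <- dx^2 + dy^2 + dz^2
  rpar <- dx * b0_dir[1] + dy * b0_dir[2] + dz * b0_dir[3]
  cos2 <- ifelse(r2 > 0, rpar^2 / r2, 0)
  r <- sqrt(r2)
  fld <- ifelse(r > radius,
                (delta_chi / 3) * (radius / r)^3 * (3 * cos2 - 1),
                0)
  volume_grid(fld, voxel_size, b0_dir, units = "ppm")
}

#' Simulate a noisy local-field observation
#'
#' phi = forward_field(chi) + n with n i.i.d. Gaussian of standard
#' deviation `sigma` (same units as the field). Deterministic under a
#' fixed seed. If `chi` carries a mask, the observation is masked to its
#' support.
#'
#' @param chi `volume_grid` of true susceptibility.
#' @param kernel `dipole_kernel`.
#' @param sigma field-noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @param pad passed to [forward_field()].
#' @return A `volume_grid` of the observed field.
#' @export
simulate_observation <- function(chi, kernel, sigma = 0, seed = 1L,
                                 pad = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  phi <- forward_field(chi, kernel, pad = pad)
  if (sigma > 0) {
    n <- with_preserved_seed(seed,
      array(stats::rnorm(length(phi$data), sd = sigma), dim = dim(phi$data)))
    phi$data <- phi$data + n
  }
  if (!is.null(chi$mask)) {
    phi$data <- phi$data * chi$mask
    phi$mask <- chi$mask
  }
  phi
}

#' Brain-like labeled phantom
#'
#' A reproducible in-silico stand-in for a brain susceptibility map: an
#' ellipsoidal support containing eight labeled structures whose
#' susceptibilities span roughly -0.05 to 0.15 ppm (the physiologic range
#' of deep gray matter, white matter and CSF), plus thin cylindrical
#' "vessels" 2-3 voxels across to probe how a reconstruction preserves
#' fine paramagnetic features, and a low-amplitude smooth intra-tissue
#' texture across the whole support (re-centered within each ROI so the
#' per-label means stay exact). Structure centers and sizes are jittered
#' by the seed, so different seeds give different geometries while the
#' per-label mean susceptibilities stay exactly the assigned values.
#'
#' @param seed integer RNG seed.
#' @param shape grid shape (default 96^3).
#' @param voxel_size voxel size in mm.
#' @return As [make_phantom()]: list with `chi`, `labels`, `mask`, plus
#'   `roi_chi`, the named vector of assigned ROI susceptibilities.
#' @export
make_brainlike_phantom <- function(seed = 1L, shape = c(96, 96, 96),
                                   voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  ext <- shape * voxel_size
  c0 <- ext / 2
  sc <- min(ext) / 96   # structure sizes scale with the grid
  roi_chi <- c(globus_pallidus = 0.15, putamen_l = 0.09, putamen_r = 0.10,
               caudate_l = 0.06, caudate_r = 0.055, thalamus = 0.02,
               white_matter = -0.045, csf = -0.015)

  jit <- with_preserved_seed(seed, stats::runif(3 * length(roi_chi),
                                                -1.5, 1.5)) * sc
  jm <- matrix(jit, ncol = 3, byrow = TRUE)

  ell <- function(center, size, chi, label)
    list(kind = "ellipsoid", center = center, size = size, chi = chi,
         label = label)
  inc <- list(
    ell(c0 + c(0, -8, 8) * sc + jm[1, ],   c(13, 9, 9) * sc,   roi_chi[[1]], 1L),
    ell(c0 + c(-18, 4, 2) * sc + jm[2, ],  c(10, 16, 10) * sc, roi_chi[[2]], 2L),
    ell(c0 + c(18, 4, 2) * sc + jm[3, ],   c(10, 16, 10) * sc, roi_chi[[3]], 3L),
    ell(c0 + c(-11, 26, 8) * sc + jm[4, ], c(8, 12, 8) * sc,   roi_chi[[4]], 4L),
    ell(c0 + c(11, 26, 8) * sc + jm[5, ],  c(8, 12, 8) * sc,   roi_chi[[5]], 5L),
    ell(c0 + c(0, 14, -12) * sc + jm[6, ], c(18, 12, 10) * sc, roi_chi[[6]], 6L),
    ell(c0 + c(0, -24, -8) * sc + jm[7, ], c(22, 14, 12) * sc, roi_chi[[7]], 7L),
    ell(c0 + c(0, 30, -14) * sc + jm[8, ], c(10, 8, 6) * sc,   roi_chi[[8]], 8L)
  )
  spec <- phantom_spec(shape, voxel_size, inclusions = inc, background = 0,
                       texture_amplitude = 0.008,
                       support = list(kind = "ellipsoid", center = c0,
                                      size = 0.9 * ext))
  ph <- make_phantom(spec, seed = seed)

  # thin cylindrical veins (unlabeled, chi = 0.30 ppm: deoxygenated blood)
  vess <- with_preserved_seed(seed + 1L, {
    co <- grid_coords(shape, voxel_size)
    X <- array(co$x, dim = shape)
    Y <- array(rep(co$y, each = shape[1]), dim = shape)
    Z <- array(rep(co$z, each = shape[1] * shape[2]), dim = shape)
    v <- array(FALSE, shape)
    for (i in seq_len(4)) {
      p0 <- c0 + stats::runif(3, -0.25, 0.25) * ext
      dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      rad <- stats::runif(1, 1.0, 1.5) * max(voxel_size)  # 2-3 voxel diameter
      dxl <- X - p0[1]; dyl <- Y - p0[2]; dzl <- Z - p0[3]
      t <- dxl * dirv[1] + dyl * dirv[2] + dzl * dirv[3]
      d2 <- (dxl - t * dirv[1])^2 + (dyl - t * dirv[2])^2 +
        (dzl - t * dirv[3])^2
      v <- v | (d2 <= rad^2 & abs(t) <= 0.3 * min(ext))
    }
    v
  })
  vess <- vess & ph$mask$data > 0 & ph$labels$data == 0
  ph$chi$data[vess] <- 0.30
  ph$roi_chi <- roi_chi
  ph
}
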