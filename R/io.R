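# mean proton gyromagnetic ratio, Hz/T
GAMMA_BAR_HZ_PER_T <- 42.577478518e6

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [volume_grid()]: voxel sizes come from the
#' header, the data array keeps the stored (x, y, z) axis order, and the
#' full NIfTI header is retained so that [write_volume()] round-trips the
#' affine. 4D files are accepted only when the fourth dimension is a
#' singleton.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param b0_dir B0 direction to record on the volume (default +z).
#' @param mask optional 0/1 array or `volume_grid` to attach.
#' @param units units label to record.
#' @return A `volume_grid` with the NIfTI header stored in
#'   `attr(, "nifti_header")`.
#' @export
read_volume <- function(path, b0_dir = c(0, 0, 1), mask = NULL,
                        units = "ppm") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[4] != 1L)
      stop("4D input with a non-singleton fourth dimension is not supported",
           call. = FALSE)
    img2 <- array(as.vector(img)[seq_len(prod(d[1:3]))], dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.vector(img), dim = d)
  } else {
    stop("input must be a 3D volume", call. = FALSE)
  }
  vs <- RNifti::pixdim(img)[1:3]
  if (!is.null(mask)) mask <- as.array(as_volume_grid(mask))
  vg <- volume_grid(img2, voxel_size = vs, b0_dir = b0_dir, mask = mask,
                    units = units)
  attr(vg, "nifti_header") <- RNifti::niftiHeader(img)
  vg
}

#' Write a volume as NIfTI
#'
#' Writes the data as float32. If the volume carries a NIfTI header from
#' [read_volume()], its affine is preserved; otherwise a diagonal affine
#' from the voxel sizes is used. The units label goes into the NIfTI
#' description field.
#'
#' @param volume `volume_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  hdr <- attr(volume, "nifti_header")
  img <- if (!is.null(hdr)) {
    RNifti::asNifti(volume$data, reference = hdr)
  } else {
    RNifti::asNifti(volume$data,
                    reference = list(pixdim = c(1, volume$voxel_size, 0, 0, 0, 0)))
  }
  img <- RNifti::asNifti(img, descrip = substr(volume$units, 1, 79),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert a field map between radians and ppm
#'
#' phi_ppm = phi_rad / (2 pi gamma_bar B0 TE) * 1e6 with
#' gamma_bar = 42.577478518 MHz/T. The inverse, [ppm_to_radians()], is
#' exact.
#'
#' @param field `volume_grid` or array of phase (radians) accumulated at
#'   echo time TE.
#' @param te_ms echo time in milliseconds (> 0).
#' @param b0_t main field strength in tesla (> 0).
#' @return A `volume_grid` in ppm.
#' @export
radians_to_ppm <- function(field, te_ms, b0_t) {
  check_te_b0(te_ms, b0_t)
  vg <- as_volume_grid(field)
  scale <- 2 * pi * GAMMA_BAR_HZ_PER_T * b0_t * (te_ms / 1000) * 1e-6
  vg_with_data(vg, vg$data / scale, units = "ppm")
}

#' @rdname radians_to_ppm
#' @export
ppm_to_radians <- function(field, te_ms, b0_t) {
  check_te_b0(te_ms, b0_t)
  vg <- as_volume_grid(field)
  scale <- 2 * pi * GAMMA_BAR_HZ_PER_T * b0_t * (te_ms / 1000) * 1e-6
  vg_with_data(vg, vg$data * scale, units = "radians")
}

check_te_b0 <- function(te_ms, b0_t) {
  if (!is.numeric(te_ms) || te_ms <= 0) stop("`te_ms` must be > 0", call. = FALSE)
  if (!is.numeric(b0_t) || b0_t <= 0) stop("`b0_t` must be > 0", call. = FALSE)
  invisible(TRUE)
}

default_run_config <- function() {
  list(
    field = NULL, mask = NULL, magnitude = NULL, labels = NULL, truth = NULL,
    solver = "pnp", denoiser = "bm4d", denoiser_sigma = NULL,
    patch_size = 4L, search_radius = 4L, max_group_size = 16L,
    hard_threshold_factor = 2.7, wiener_stage = FALSE,
    mu = 1, alpha = 1e-3, beta = 1, max_iters = 50L, rel_tol = 1e-3,
    sigma_mode = "proximal", noise_back_lambda = 0,
    fidelity_weight = "mask", tkd_threshold = 0.19, l2_mode = "gradient",
    input_units = "ppm", te_ms = NULL, b0_t = NULL, b0_dir = c(0, 0, 1),
    seed = 1L, output_dir = "qsm_out"
  )
}

#' Assemble a reconstruction run configuration
#'
#' Merges user settings over the package defaults. Accepts either a named
#' list or a YAML file path via [read_run_config()]. Input paths are
#' checked when the pipeline runs.
#'
#' @param ... configuration fields overriding the defaults (see
#'   [run_pipeline()] for the field list).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file of configuration fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

config_to_params <- function(cfg) {
  dn <- if (cfg$solver == "pnp") {
    sig <- if (is.null(cfg$denoiser_sigma))
      max(sqrt(cfg$alpha / cfg$beta), 1e-6) else cfg$denoiser_sigma
    denoiser_spec(cfg$denoiser, sigma = sig, patch_size = cfg$patch_size,
                  search_radius = cfg$search_radius,
                  max_group_size = cfg$max_group_size,
                  hard_threshold_factor = cfg$hard_threshold_factor,
                  wiener_stage = cfg$wiener_stage)
  } else NULL
  admm_params(mu = cfg$mu, alpha = cfg$alpha, beta = cfg$beta,
              max_iters = cfg$max_iters, rel_tol = cfg$rel_tol,
              denoiser = dn,
              sigma_mode = if (is.null(cfg$denoiser_sigma)) cfg$sigma_mode
                           else "fixed",
              fidelity_weight_M = cfg$fidelity_weight,
              noise_back_lambda = cfg$noise_back_lambda)
}

#' Run the full reconstruction pipeline
#'
#' Reads the local field (and optional mask, truth and label volumes),
#' converts radians to ppm when `input_units = "radians"` (requires
#' `te_ms` and `b0_t`), reconstructs with the configured solver
#' (`"pnp"`, `"tv"`, `"l2"` or `"tkd"`), and writes to `output_dir`:
#' the susceptibility map (`chi.nii.gz`, ppm), the per-iteration residual
#' log (`residuals.csv`, iterative solvers), the metric panel
#' (`metrics.csv`, when truth is given), the ROI table (`roi.csv`, when
#' labels are given) and a reproducibility manifest
#' (`manifest.json`: config, seed, package and R versions).
#'
#' @param cfg a `run_config`, or a named list / YAML path coercible to one.
#' @return Invisibly, a list with the reconstruction (`fit` or `chi`),
#'   report tibbles and output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  if (is.null(cfg$field)) stop("`field` input path is required", call. = FALSE)

  mask <- if (!is.null(cfg$mask))
    as.array(read_volume(cfg$mask, units = "mask")) else NULL
  if (!is.null(mask)) mask <- (mask > 0) * 1
  phi <- read_volume(cfg$field, b0_dir = cfg$b0_dir, mask = mask,
                     units = cfg$input_units)
  if (identical(cfg$input_units, "radians")) {
    if (is.null(cfg$te_ms) || is.null(cfg$b0_t))
      stop("radians input requires `te_ms` and `b0_t`", call. = FALSE)
    phi <- radians_to_ppm(phi, cfg$te_ms, cfg$b0_t)
  }
  kernel <- dipole_kernel(dim(phi), phi$voxel_size, cfg$b0_dir)
  params <- config_to_params(cfg)

  fit <- NULL
  chi <- switch(cfg$solver,
    pnp = { fit <- pnp_admm(phi, kernel, params); fit$chi },
    tv = { fit <- tv_admm(phi, kernel, params); fit$chi },
    l2 = l2_closed_form(phi, kernel, alpha = max(cfg$alpha,
                                                 .Machine$double.eps),
                        mode = cfg$l2_mode),
    tkd = tkd_invert(phi, kernel, threshold = cfg$tkd_threshold),
    stop(sprintf("unknown solver '%s' (use pnp, tv, l2 or tkd)", cfg$solver),
         call. = FALSE))
  if (!is.null(phi$mask)) chi$data <- chi$data * phi$mask
  attr(chi, "nifti_header") <- attr(phi, "nifti_header")

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(chi = file.path(cfg$output_dir, "chi.nii.gz"))
  write_volume(chi, paths$chi)

  if (!is.null(fit)) {
    paths$residuals <- file.path(cfg$output_dir, "residuals.csv")
    utils::write.csv(fit$residuals, paths$residuals, row.names = FALSE)
  }
  metrics <- roi <- NULL
  if (!is.null(cfg$truth)) {
    truth <- read_volume(cfg$truth)
    metrics <- metrics_report(chi, truth, mask = phi$mask,
                              test_id = cfg$solver, reference_id = "truth")
    paths$metrics <- file.path(cfg$output_dir, "metrics.csv")
    utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  }
  if (!is.null(cfg$labels) && !is.null(cfg$truth)) {
    labels <- read_volume(cfg$labels, units = "label")
    roi <- roi_analysis(chi, read_volume(cfg$truth), labels)
    paths$roi <- file.path(cfg$output_dir, "roi.csv")
    utils::write.csv(tidy(roi), paths$roi, row.names = FALSE)
  }

  paths$manifest <- file.path(cfg$output_dir, "manifest.json")
  manifest <- list(
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("qsmpnp")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(chi = chi, fit = fit, metrics = metrics, roi = roi,
                 paths = paths))
}

#' Write a phantom to NIfTI files
#'
#' Convenience wrapper used by the `simulate` CLI subcommand: builds the
#' brain-like phantom, simulates a noisy observation and writes
#' `chi.nii.gz`, `phi.nii.gz`, `mask.nii.gz`, `labels.nii.gz` to `dir`.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param shape grid shape (brain-like phantom only).
#' @param noise_sigma field-noise standard deviation in ppm.
#' @param spec optional [phantom_spec()] (or YAML path readable by
#'   [read_phantom_spec()]) replacing the default brain-like phantom.
#' @return Invisibly, the list of written paths.
#' @export
simulate_to_dir <- function(dir, seed = 1L, shape = c(96, 96, 96),
                            noise_sigma = 0.002, spec = NULL) {
  ph <- if (is.null(spec)) {
    make_brainlike_phantom(seed, shape = shape)
  } else {
    if (is.character(spec)) spec <- read_phantom_spec(spec)
    make_phantom(spec, seed = seed)
  }
  shape <- dim(ph$chi$data)
  kernel <- dipole_kernel(shape, ph$chi$voxel_size, ph$chi$b0_dir)
  phi <- simulate_observation(ph$chi, kernel, sigma = noise_sigma,
                              seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(chi = file.path(dir, "chi.nii.gz"),
                phi = file.path(dir, "phi.nii.gz"),
                mask = file.path(dir, "mask.nii.gz"),
                labels = file.path(dir, "labels.nii.gz"))
  write_volume(ph$chi, paths$chi)
  write_volume(phi, paths$phi)
  write_volume(ph$mask, paths$mask)
  write_volume(ph$labels, paths$labels)
  invisible(paths)
}

#' Metric panel for an external reference dataset
#'
#' Benchmark harness: given locally available NIfTI paths for a field
#' map, brain mask and a reference susceptibility volume (for example a
#' multi-orientation reconstruction), runs the L2, QSM-TV and PnP
#' solvers and returns the metric panel for each. No data is downloaded;
#' all inputs are caller-supplied files.
#'
#' @param field,mask,reference NIfTI paths.
#' @param labels optional ROI label NIfTI path.
#' @param alpha_l2,alpha_tv,alpha_pnp per-solver regularization weights.
#' @param max_iters iteration cap for the iterative solvers.
#' @param ... further fields passed to [run_config()] (e.g. `te_ms`,
#'   `b0_t`, `input_units`).
#' @return A list with `metrics` (tibble, one row per solver) and `roi`
#'   (list of `roi_table`s, if labels were given).
#' @export
qsm_benchmark <- function(field, mask, reference, labels = NULL,
                          alpha_l2 = 0.05, alpha_tv = 0.002,
                          alpha_pnp = 4e-4, max_iters = 30L, ...) {
  out_root <- tempfile("qsm_benchmark_")
  solvers <- list(
    l2 = list(solver = "l2", alpha = alpha_l2),
    tv = list(solver = "tv", alpha = alpha_tv),
    pnp = list(solver = "pnp", alpha = alpha_pnp))
  metrics <- list(); roi <- list()
  for (nm in names(solvers)) {
    cfg <- do.call(run_config, c(
      list(field = field, mask = mask, truth = reference, labels = labels,
           max_iters = max_iters,
           output_dir = file.path(out_root, nm)),
      solvers[[nm]], list(...)))
    res <- run_pipeline(cfg)
    metrics[[nm]] <- res$metrics
    if (!is.null(res$roi)) roi[[nm]] <- res$roi
  }
  list(metrics = do.call(rbind, metrics), roi = roi)
}
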