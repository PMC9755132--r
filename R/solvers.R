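# squared spectra of the forward-difference gradient operators, periodic
# boundary, voxel-size scaled: |E_i(k)|^2 = (2 sin(pi f_i) / dx_i)^2
gradient_spectra_sq <- function(shape, voxel_size) {
  e2 <- function(n, dx) (2 * sin(pi * fft_freq(n)) / dx)^2
  array(e2(shape[1], voxel_size[1]), dim = shape) +
    array(rep(e2(shape[2], voxel_size[2]), each = shape[1]), dim = shape) +
    array(rep(e2(shape[3], voxel_size[3]), each = shape[1] * shape[2]),
          dim = shape)
}

# circular shift of a 3D array along one axis
shift3 <- function(x, axis, by) {
  n <- dim(x)[axis]
  idx <- ((seq_len(n) - 1 + by) %% n) + 1
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

grad_axis <- function(x, axis, dx) (shift3(x, axis, 1L) - x) / dx
grad_axis_adj <- function(y, axis, dx) (shift3(y, axis, -1L) - y) / dx

#' Elementwise soft threshold
#'
#' `sign(x) * max(|x| - t, 0)`; the shrinkage operator behind the
#' total-variation gradient subproblem.
#'
#' @param x numeric vector or array.
#' @param t threshold (>= 0).
#' @export
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' ADMM solver parameters
#'
#' Tunable weights and controls shared by [pnp_admm()] and [tv_admm()].
#' `mu` weighs data fidelity, `beta` the variable-splitting penalty, and
#' `alpha` the regularizer; in the plug-and-play solver `alpha` enters
#' only through the default denoiser strength sigma = sqrt(alpha / beta).
#' The defaults are plain starting points on the phantom (ppm) scale and
#' are meant to be tuned per dataset, as is standard for regularized QSM.
#'
#' @param mu data-fidelity weight (> 0).
#' @param alpha regularization weight (>= 0).
#' @param beta splitting penalty (> 0).
#' @param max_iters maximum outer iterations (0 returns the initial map).
#' @param rel_tol stop when the relative change of chi drops below this.
#' @param denoiser `denoiser_spec` (plug-and-play solver only).
#' @param sigma_mode denoiser strength schedule: `"proximal"` uses
#'   sqrt(alpha / beta) (the proximal-operator correspondence of the
#'   splitting), `"fixed"` uses the spec's own sigma, `"decay"` applies a
#'   geometric decay `sigma_decay^n` to the proximal value.
#' @param sigma_decay geometric decay rate for `sigma_mode = "decay"`.
#' @param fidelity_weight_M `NULL` for identity, the string `"mask"` to
#'   use the observation's binary mask, or a weight array (e.g.
#'   magnitude-derived); non-identity weights are handled by an inner
#'   conjugate-gradient solver.
#' @param tv_weight_W `NULL` (identity) or an edge-weight array for the
#'   TV term.
#' @param noise_back_lambda adding-noise-back mixing factor in \[0, 1\];
#'   0 disables the step.
#' @param cg_iters,cg_tol inner conjugate-gradient controls.
#' @return An object of class `admm_params`.
#' @export
admm_params <- function(mu = 1, alpha = 1e-3, beta = 1, max_iters = 50L,
                        rel_tol = 1e-3, denoiser = NULL,
                        sigma_mode = c("proximal", "fixed", "decay"),
                        sigma_decay = 0.95, fidelity_weight_M = NULL,
                        tv_weight_W = NULL, noise_back_lambda = 0,
                        cg_iters = 30L, cg_tol = 1e-6) {
  sigma_mode <- match.arg(sigma_mode)
  if (!is.numeric(mu) || mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  max_iters <- as.integer(max_iters)
  if (max_iters < 0L) stop("`max_iters` must be >= 0", call. = FALSE)
  if (noise_back_lambda < 0 || noise_back_lambda > 1)
    stop("`noise_back_lambda` must lie in [0, 1]", call. = FALSE)
  if (!is.null(denoiser) && !inherits(denoiser, "denoiser_spec"))
    stop("`denoiser` must be a denoiser_spec", call. = FALSE)
  structure(list(mu = mu, alpha = alpha, beta = beta, max_iters = max_iters,
                 rel_tol = rel_tol, denoiser = denoiser,
                 sigma_mode = sigma_mode, sigma_decay = sigma_decay,
                 fidelity_weight_M = fidelity_weight_M,
                 tv_weight_W = tv_weight_W,
                 noise_back_lambda = noise_back_lambda,
                 cg_iters = as.integer(cg_iters), cg_tol = cg_tol),
            class = "admm_params")
}

# resolve the fidelity weight M to an array or NULL (identity)
resolve_M <- function(params, phi) {
  M <- params$fidelity_weight_M
  if (is.null(M)) return(NULL)
  if (identical(M, "identity")) return(NULL)
  if (identical(M, "mask")) {
    if (is.null(phi$mask)) return(NULL)
    return(phi$mask)
  }
  M <- as.array(as_volume_grid(M))
  stopifnot_same_shape(M, phi$data, "fidelity weight and field")
  M
}

#' Closed-form Tikhonov (L2) reconstruction
#'
#' chi_hat = F^H \[ D F phi / (D^2 + alpha P) \] with P = 1 (identity
#' mode) or the squared spectrum of the 3D gradient operator (gradient
#' mode, the default): zeroth- vs first-order Tikhonov regularization.
#' The fastest baseline, but it smooths fine structure.
#'
#' @param phi `volume_grid` of the observed local field.
#' @param kernel `dipole_kernel`.
#' @param alpha regularization weight (> 0).
#' @param mode `"gradient"` or `"identity"`.
#' @return A `volume_grid` of estimated susceptibility.
#' @export
l2_closed_form <- function(phi, kernel, alpha, mode = c("gradient", "identity")) {
  mode <- match.arg(mode)
  phi <- as_volume_grid(phi)
  check_kernel_shape(phi, kernel)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  D <- kernel$values
  P <- if (mode == "identity") 1 else
    gradient_spectra_sq(kernel$shape, kernel$voxel_size)
  denom <- D^2 + alpha * P
  filt <- ifelse(denom > 0, D / denom, 0)   # k = 0: zero-mean solution
  out <- Re(ifft3(filt * fft3(phi$data)))
  vg_with_data(phi, out, units = "ppm")
}

#' Data-consistency (chi) subproblem of the ADMM splitting
#'
#' Minimizes (beta/2) ||chi - v + u||^2 + (mu/2) ||M (F^H D F chi - phi)||^2.
#' With identity M the solution is diagonal in the Fourier domain:
#' chi = F^H \[ (beta F(v - u) + mu D F phi) / (beta + mu D^2) \].
#' With a mask or weight M, the normal equations
#' (beta I + mu A^H M^2 A) chi = beta (v - u) + mu A^H M^2 phi are solved
#' by conjugate gradients, warm-started from `chi_warm`.
#'
#' @param v,u current splitting variable and scaled multiplier (arrays or
#'   `volume_grid`s).
#' @param phi observed field.
#' @param kernel `dipole_kernel`.
#' @param params `admm_params` (uses `mu`, `beta`, `fidelity_weight_M`,
#'   `cg_iters`, `cg_tol`).
#' @param chi_warm optional warm-start array for the CG path.
#' @return A `volume_grid`.
#' @export
chi_subproblem <- function(v, u, phi, kernel, params, chi_warm = NULL) {
  phi <- as_volume_grid(phi)
  check_kernel_shape(phi, kernel)
  v <- if (inherits(v, "volume_grid")) v$data else v
  u <- if (inherits(u, "volume_grid")) u$data else u
  M <- resolve_M(params, phi)
  D <- kernel$values
  mu <- params$mu; beta <- params$beta
  if (is.null(M)) {
    out <- Re(ifft3((beta * fft3(v - u) + mu * D * fft3(phi$data)) /
                      (beta + mu * D^2)))
  } else {
    M2 <- M^2
    Aop <- function(x) apply_kernel(x, D)
    lhs <- function(x) beta * x + mu * Aop(M2 * Aop(x))
    rhs <- beta * (v - u) + mu * Aop(M2 * phi$data)
    x <- if (is.null(chi_warm)) array(0, dim(rhs)) else chi_warm
    r <- rhs - lhs(x)
    p <- r
    rs <- sum(r^2)
    rhs_n <- sqrt(sum(rhs^2))
    tol2 <- (params$cg_tol * max(rhs_n, .Machine$double.eps))^2
    it <- 0L
    while (rs > tol2 && it < params$cg_iters) {
      Ap <- lhs(p)
      a <- rs / sum(p * Ap)
      x <- x + a * p
      r <- r - a * Ap
      rs_new <- sum(r^2)
      p <- r + (rs_new / rs) * p
      rs <- rs_new
      it <- it + 1L
    }
    if (rs > tol2)
      warning(sprintf(
        "chi-subproblem CG stopped at %d iterations, residual %.3e",
        it, sqrt(rs) / rhs_n), call. = FALSE)
    out <- x
  }
  vg_with_data(phi, out, units = "ppm")
}

#' Adding-noise-back field update
#'
#' phi_used = phi + lambda (phi - forward_field(chi)); mixing a fraction
#' of the data residual back into the observation counters the progressive
#' over-smoothing of iterated denoising. `lambda = 0` disables the step.
#'
#' @param phi_original observed field (`volume_grid`).
#' @param chi_current current susceptibility estimate.
#' @param kernel `dipole_kernel`.
#' @param lambda mixing factor in \[0, 1\].
#' @return A `volume_grid`.
#' @export
add_noise_back <- function(phi_original, chi_current, kernel, lambda) {
  if (lambda < 0 || lambda > 1)
    stop("`lambda` must lie in [0, 1]", call. = FALSE)
  phi <- as_volume_grid(phi_original)
  if (lambda == 0) return(phi)
  pred <- forward_field(as_volume_grid(chi_current, template = phi), kernel)
  vg_with_data(phi, phi$data + lambda * (phi$data - pred$data))
}

new_qsm_fit <- function(chi, phi, method, params, history, converged) {
  structure(list(chi = chi, method = method, params = params,
                 residuals = history, iterations = nrow(history),
                 converged = converged, state = NULL),
            class = "qsm_fit")
}

#' @export
print.qsm_fit <- function(x, ...) {
  cat(sprintf("<qsm_fit> %s: %d iterations (%s)\n", x$method, x$iterations,
              if (x$converged) "converged" else "max iterations"))
  if (x$iterations > 0) {
    h <- x$residuals[x$iterations, ]
    cat(sprintf("  final primal residual %.3e, data residual %.3e\n",
                h$primal, h$data))
  }
  invisible(x)
}

#' @export
tidy.qsm_fit <- function(x, ...) x$residuals

#' @export
glance.qsm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, iterations = x$iterations, converged = x$converged,
    final_primal = if (x$iterations) x$residuals$primal[x$iterations] else NA_real_,
    final_data = if (x$iterations) x$residuals$data[x$iterations] else NA_real_)
}

#' @export
autoplot.qsm_fit <- function(object, ...) {
  h <- object$residuals
  df <- tibble::tibble(
    iteration = rep(h$iteration, 2),
    residual = c(h$primal, h$data),
    type = rep(c("primal ||chi - v||", "data ||M(A chi - phi)||"),
               each = nrow(h)))
  ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = residual,
                                   colour = type)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = sprintf("%s convergence", object$method),
                  x = "iteration", y = "residual (log scale)",
                  colour = NULL)
}

residual_row <- function(iter, chi, v, phi, kernel, M, rel_change) {
  pred <- apply_kernel(chi, kernel$values)
  res <- pred - phi
  if (!is.null(M)) res <- M * res
  tibble::tibble(iteration = iter,
                 primal = sqrt(sum((chi - v)^2)),
                 data = sqrt(sum(res^2)),
                 rel_change = rel_change)
}

#' Plug-and-play ADMM dipole inversion
#'
#' The central solver: ADMM variable splitting chi = v with scaled
#' multiplier u, in which the regularizer's proximal step is replaced by
#' one application of a denoiser,
#' \enumerate{
#'   \item chi-update: data-consistency subproblem ([chi_subproblem()]);
#'   \item v-update: v = D_sigma(chi + u);
#'   \item multiplier: u = u + chi - v.
#' }
#' Iterations stop at `max_iters` or when the relative change of chi
#' falls below `rel_tol`. Any registered denoiser plugs in unchanged.
#' When `noise_back_lambda > 0` the observation is refreshed once per
#' outer iteration by [add_noise_back()] before the chi-update.
#'
#' @param phi `volume_grid` of the observed local field.
#' @param kernel `dipole_kernel`.
#' @param params `admm_params` with a non-`NULL` `denoiser`.
#' @param initial_chi optional starting susceptibility (array or
#'   `volume_grid`); default zeros.
#' @return A `qsm_fit` with the estimated susceptibility in `$chi`
#'   (masked if the observation carries a mask), the per-iteration
#'   residual history as a tibble in `$residuals`, and the final ADMM
#'   state in `$state`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
pnp_admm <- function(phi, kernel, params, initial_chi = NULL) {
  phi <- as_volume_grid(phi)
  check_kernel_shape(phi, kernel)
  stopifnot(inherits(params, "admm_params"))
  if (is.null(params$denoiser))
    stop("`params$denoiser` must be a denoiser_spec for pnp_admm",
         call. = FALSE)
  M <- resolve_M(params, phi)
  dn <- params$denoiser
  sigma0 <- switch(params$sigma_mode,
                   fixed = dn$sigma,
                   proximal = ,
                   decay = {
                     s <- sqrt(params$alpha / params$beta)
                     if (s <= 0) dn$sigma else s
                   })

  shape <- kernel$shape
  chi <- if (is.null(initial_chi)) array(0, shape) else
    as.array(as_volume_grid(initial_chi))
  stopifnot_same_shape(chi, phi$data, "initial_chi and field")
  v <- chi
  u <- array(0, shape)
  phi_work <- phi
  history <- residual_row(0L, chi, v, phi$data, kernel, M, NA_real_)[0, ]
  converged <- FALSE

  if (params$max_iters == 0L) {
    fit <- new_qsm_fit(mask_fit_output(chi, phi), phi, "pnp_admm", params,
                       history, FALSE)
    fit$state <- list(chi = chi, v = v, u = u)
    return(fit)
  }

  for (it in seq_len(params$max_iters)) {
    if (params$noise_back_lambda > 0)
      phi_work <- add_noise_back(phi, chi, kernel, params$noise_back_lambda)
    chi_new <- chi_subproblem(v, u, phi_work, kernel, params,
                              chi_warm = chi)$data
    dn$sigma <- if (params$sigma_mode == "decay")
      sigma0 * params$sigma_decay^(it - 1) else sigma0
    v <- denoise(volume_grid(chi_new + u, phi$voxel_size, phi$b0_dir,
                             mask = phi$mask), dn)$data
    u <- u + chi_new - v
    if (any(!is.finite(chi_new)) || any(!is.finite(v)))
      stop(sprintf("non-finite iterate at iteration %d (primal %.3e)", it,
                   sqrt(sum((chi_new - v)^2))), call. = FALSE)
    rel <- sqrt(sum((chi_new - chi)^2)) /
      max(sqrt(sum(chi^2)), .Machine$double.eps)
    history <- rbind(history,
                     residual_row(it, chi_new, v, phi_work$data, kernel, M, rel))
    chi <- chi_new
    if (rel < params$rel_tol) { converged <- TRUE; break }
  }

  fit <- new_qsm_fit(mask_fit_output(chi, phi), phi, "pnp_admm", params,
                     history, converged)
  fit$state <- list(chi = chi, v = v, u = u)
  fit
}

mask_fit_output <- function(chi, phi) {
  out <- chi
  if (!is.null(phi$mask)) out <- out * phi$mask
  volume_grid(out, phi$voxel_size, phi$b0_dir, mask = phi$mask,
              units = "ppm")
}

#' Reference solver configurations for the phantom study
#'
#' The solver settings used by the package's bundled brain-phantom
#' comparison (tests, acceptance script, README example): each method is
#' tuned on its own terms, as is standard when benchmarking regularized
#' reconstructions. `qsmpnp_pnp_reference_params()` returns the PnP-BM4D
#' configuration: fidelity-dominated splitting (mu = 1, beta = 0.05),
#' fixed denoiser strength of five times the field-noise level (the
#' empirical artifact scale of the chi-iterates), the empirical-Wiener
#' second stage of the collaborative filter, and binary-mask fidelity
#' weighting solved by warm-started conjugate gradients.
#'
#' @param noise_sigma field-noise standard deviation of the observation
#'   (ppm).
#' @param max_iters outer iteration cap.
#' @return An `admm_params`.
#' @export
qsmpnp_pnp_reference_params <- function(noise_sigma = 0.004,
                                        max_iters = 20L) {
  admm_params(mu = 1, beta = 0.05, alpha = 0.05 * (5 * noise_sigma)^2,
              max_iters = max_iters, rel_tol = 5e-4,
              denoiser = denoiser_spec("bm4d", sigma = 5 * noise_sigma,
                                       search_radius = 3,
                                       wiener_stage = TRUE),
              sigma_mode = "fixed", fidelity_weight_M = "mask",
              cg_iters = 10L, cg_tol = 1e-3)
}

#' Total-variation regularized dipole inversion (QSM-TV)
#'
#' Solves the TV-regularized problem
#' (mu/2) ||M(F^H D F chi - phi)||^2 + alpha ||W grad chi||_1
#' by ADMM with splitting on the gradient field z = grad chi: the
#' z-subproblem is isotropic soft-thresholding (shrinkage) at
#' alpha W / beta, and the chi-update is diagonal in the Fourier domain
#' because both D^2 and the gradient spectra are. Identity fidelity
#' weighting is used in the chi-update; the observation should be masked
#' beforehand if needed.
#'
#' @inheritParams pnp_admm
#' @return A `qsm_fit`.
#' @export
tv_admm <- function(phi, kernel, params) {
  phi <- as_volume_grid(phi)
  check_kernel_shape(phi, kernel)
  stopifnot(inherits(params, "admm_params"))
  if (params$alpha <= 0) stop("`alpha` must be > 0 for tv_admm", call. = FALSE)
  D <- kernel$values
  vs <- kernel$voxel_size
  mu <- params$mu; beta <- params$beta
  W <- if (is.null(params$tv_weight_W)) 1 else
    as.array(as_volume_grid(params$tv_weight_W))
  E2 <- gradient_spectra_sq(kernel$shape, vs)
  denom <- mu * D^2 + beta * E2
  denom[denom == 0] <- beta * .Machine$double.eps  # k = 0 bin: chi mean 0
  rhs_data <- mu * D * fft3(phi$data)

  shape <- kernel$shape
  chi <- array(0, shape)
  z <- u <- list(array(0, shape), array(0, shape), array(0, shape))
  history <- tibble::tibble(iteration = integer(0), primal = numeric(0),
                            data = numeric(0), rel_change = numeric(0))
  converged <- FALSE
  thr <- params$alpha * W / beta

  for (it in seq_len(params$max_iters)) {
    s <- grad_axis_adj(z[[1]] - u[[1]], 1L, vs[1]) +
      grad_axis_adj(z[[2]] - u[[2]], 2L, vs[2]) +
      grad_axis_adj(z[[3]] - u[[3]], 3L, vs[3])
    chi_new <- Re(ifft3((rhs_data + beta * fft3(s)) / denom))
    g <- list(grad_axis(chi_new, 1L, vs[1]), grad_axis(chi_new, 2L, vs[2]),
              grad_axis(chi_new, 3L, vs[3]))
    w1 <- g[[1]] + u[[1]]; w2 <- g[[2]] + u[[2]]; w3 <- g[[3]] + u[[3]]
    mag <- sqrt(w1^2 + w2^2 + w3^2)
    fac <- pmax(1 - thr / pmax(mag, .Machine$double.eps), 0)
    z <- list(fac * w1, fac * w2, fac * w3)
    u <- list(w1 - z[[1]], w2 - z[[2]], w3 - z[[3]])
    rel <- sqrt(sum((chi_new - chi)^2)) /
      max(sqrt(sum(chi^2)), .Machine$double.eps)
    primal <- sqrt(sum((g[[1]] - z[[1]])^2 + (g[[2]] - z[[2]])^2 +
                         (g[[3]] - z[[3]])^2))
    datar <- sqrt(sum((apply_kernel(chi_new, D) - phi$data)^2))
    row <- tibble::tibble(iteration = it, primal = primal, data = datar,
                          rel_change = rel)
    history <- if (is.null(history)) row else rbind(history, row)
    chi <- chi_new
    if (rel < params$rel_tol) { converged <- TRUE; break }
  }

  fit <- new_qsm_fit(mask_fit_output(chi, phi), phi, "tv_admm", params,
                     history, converged)
  fit$state <- list(chi = chi, z = z, u = u)
  fit
}
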