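test_that("closed-form L2 solves the single-bin spectral identity", {
  sh <- c(16, 16, 16)
  K <- dipole_kernel(sh)
  expect_identical(max(abs(l2_closed_form(array(0, sh), K, 0.1)$data)), 0)

  # phi = pure cosine at one frequency pair: chi_hat = D0/(D0^2+alpha) phi
  x <- (0:15)
  phi <- array(cos(2 * pi * 2 * x / 16), sh)   # kx = 2 bins, D = 1/3
  D0 <- 1 / 3; al <- 0.05
  rec <- l2_closed_form(phi, K, alpha = al, mode = "identity")$data
  expect_equal(rec, D0 / (D0^2 + al) * phi, tolerance = 1e-10)
  expect_error(l2_closed_form(phi, K, alpha = 0), "positive")
})

test_that("gradient-penalty L2 keeps more high-frequency detail", {
  fx <- brain48()
  m <- fx$ph$mask$data
  g <- l2_closed_form(fx$phi, fx$kernel, alpha = 0.01, mode = "gradient")$data
  i <- l2_closed_form(fx$phi, fx$kernel, alpha = 0.03, mode = "identity")$data
  expect_lt(qsm_hfen(g * m, fx$ph$chi$data, m),
            qsm_hfen(i * m, fx$ph$chi$data, m))
})

test_that("chi-subproblem collapses correctly in its limits", {
  sh <- c(16, 16, 16)
  K <- dipole_kernel(sh)
  zero <- array(0, sh)
  p <- admm_params(mu = 1, beta = 1)
  expect_lt(max(abs(chi_subproblem(zero, zero, zero, K, p)$data)), 1e-14)

  v <- rand_vol(sh, seed = 40); u <- rand_vol(sh, seed = 41)
  p0 <- admm_params(mu = 0, beta = 1)
  expect_equal(chi_subproblem(v, u, zero, K, p0)$data, v - u,
               tolerance = 1e-12)
})

test_that("closed-form and conjugate-gradient chi-updates agree when M is 1", {
  sh <- c(24, 24, 24)
  K <- dipole_kernel(sh)
  phi <- forward_field(rand_vol(sh, seed = 42), K)
  v <- rand_vol(sh, seed = 43); u <- 0.1 * rand_vol(sh, seed = 44)
  cf <- chi_subproblem(v, u, phi, K, admm_params(mu = 2, beta = 0.7))
  cg <- chi_subproblem(v, u, phi, K,
                       admm_params(mu = 2, beta = 0.7,
                                   fidelity_weight_M = array(1, sh),
                                   cg_iters = 200L, cg_tol = 1e-10))
  expect_lt(rel_l2(cg$data, cf$data), 1e-6)
})

test_that("conjugate gradients handle a binary fidelity mask", {
  fx <- brain48()
  p <- admm_params(mu = 1, beta = 0.5, fidelity_weight_M = fx$ph$mask$data,
                   cg_iters = 50L)
  out <- chi_subproblem(array(0, dim(fx$phi$data)), array(0, dim(fx$phi$data)),
                        fx$phi, fx$kernel, p)
  expect_true(all(is.finite(out$data)))
  # solves the masked normal equations: residual far below the naive guess
  M2 <- fx$ph$mask$data
  lhs <- function(x) 0.5 * x + qsmpnp:::apply_kernel(
    M2 * qsmpnp:::apply_kernel(x, fx$kernel$values), fx$kernel$values)
  rhs <- qsmpnp:::apply_kernel(M2 * fx$phi$data, fx$kernel$values)
  expect_lt(sqrt(sum((lhs(out$data) - rhs)^2)) / sqrt(sum(rhs^2)), 1e-4)
})

test_that("plug-and-play ADMM recovers cone-free data exactly", {
  sh <- c(32, 32, 32)
  K <- dipole_kernel(sh)
  chi0 <- rand_vol(sh, seed = 45)
  S <- stats::fft(chi0); S[abs(K$values) < 0.2] <- 0
  chi0 <- Re(stats::fft(S, inverse = TRUE)) / prod(sh)
  phi <- forward_field(chi0, K)
  p <- admm_params(mu = 100, beta = 1, max_iters = 50L, rel_tol = 0,
                   denoiser = denoiser_spec("identity", sigma = 1),
                   sigma_mode = "fixed")
  fit <- pnp_admm(phi, K, p)
  expect_lt(rel_l2(fit$chi$data, chi0), 1e-4)
  expect_s3_class(fit, "qsm_fit")
})

test_that("zero iterations return the initial map unchanged", {
  sh <- c(16, 16, 16)
  K <- dipole_kernel(sh)
  phi <- volume_grid(rand_vol(sh, seed = 46))
  p <- admm_params(max_iters = 0L,
                   denoiser = denoiser_spec("identity", sigma = 1))
  expect_identical(max(abs(pnp_admm(phi, K, p)$chi$data)), 0)
  init <- rand_vol(sh, seed = 47)
  expect_identical(pnp_admm(phi, K, p, initial_chi = init)$chi$data, init)
})

test_that("a consistent fixed point does not move", {
  sh <- c(32, 32, 32)
  K <- dipole_kernel(sh)
  chi0 <- rand_vol(sh, seed = 48)
  S <- stats::fft(chi0); S[abs(K$values) < 0.2] <- 0
  chi0 <- Re(stats::fft(S, inverse = TRUE)) / prod(sh)
  phi <- forward_field(chi0, K)
  p <- admm_params(mu = 100, beta = 1, max_iters = 5L, rel_tol = 0,
                   denoiser = denoiser_spec("identity", sigma = 1),
                   sigma_mode = "fixed")
  fit <- pnp_admm(phi, K, p, initial_chi = chi0)
  expect_lt(rel_l2(fit$chi$data, chi0), 1e-10)
})

test_that("primal residual is non-increasing with the identity denoiser", {
  sh <- c(24, 24, 24)
  K <- dipole_kernel(sh)
  chi0 <- rand_vol(sh, seed = 49)
  S <- stats::fft(chi0); S[abs(K$values) < 0.2] <- 0
  chi0 <- Re(stats::fft(S, inverse = TRUE)) / prod(sh)
  phi <- forward_field(chi0, K)
  p <- admm_params(mu = 10, beta = 1, max_iters = 12L, rel_tol = 0,
                   denoiser = denoiser_spec("identity", sigma = 1),
                   sigma_mode = "fixed")
  fit <- pnp_admm(phi, K, p)
  pr <- fit$residuals$primal
  expect_true(all(diff(pr[-1]) <= 1e-12))
})

test_that("soft threshold shrinks magnitudes and zeroes at the threshold", {
  expect_equal(soft_threshold(c(-3, -1, 0, 1, 3), 1), c(-2, 0, 0, 0, 2))
  expect_identical(soft_threshold(2, 2), 0)
})

test_that("TV reconstruction reduces total variation relative to L2", {
  fx <- brain48()
  m <- fx$ph$mask$data
  tv_norm <- function(x) {
    sum(sqrt(qsmpnp:::grad_axis(x, 1L, 1)^2 +
               qsmpnp:::grad_axis(x, 2L, 1)^2 +
               qsmpnp:::grad_axis(x, 3L, 1)^2))
  }
  l2 <- l2_closed_form(fx$phi, fx$kernel, alpha = 0.03)$data * m
  p <- admm_params(mu = 1, alpha = 5e-4, beta = 5e-3, max_iters = 40L,
                   rel_tol = 1e-4)
  tv <- tv_admm(fx$phi, fx$kernel, p)$chi$data * m
  expect_lt(tv_norm(tv), tv_norm(l2))
})

test_that("TV with vanishing regularization approaches data consistency", {
  sh <- c(24, 24, 24)
  K <- dipole_kernel(sh)
  sp <- phantom_spec(sh, inclusions = list(
    list(kind = "sphere", center = c(12, 12, 12), size = 4, chi = 0.1,
         label = 1L)))
  chi0 <- make_phantom(sp)$chi$data
  phi <- volume_grid(forward_field(chi0, dipole_kernel(sh))$data)
  p <- admm_params(mu = 1, alpha = 1e-9, beta = 1e-8, max_iters = 80L,
                   rel_tol = 0)
  fit <- tv_admm(phi, K, p)
  res <- forward_field(fit$chi$data, K)$data - phi$data
  expect_lt(sqrt(sum(res^2)) / sqrt(sum(phi$data^2)), 1e-3)
})

test_that("adding-noise-back mixes the data residual as specified", {
  sh <- c(16, 16, 16)
  K <- dipole_kernel(sh)
  chi <- rand_vol(sh, seed = 50)
  phi <- forward_field(chi, K)
  expect_identical(add_noise_back(phi, array(0, sh), K, 0)$data, phi$data)
  expect_equal(add_noise_back(phi, chi, K, 1)$data, phi$data,
               tolerance = 1e-12)  # consistent estimate: no change
  expect_equal(add_noise_back(phi, array(0, sh), K, 1)$data, 2 * phi$data,
               tolerance = 1e-14)
  expect_error(add_noise_back(phi, chi, K, 2), "lambda")
})

test_that("fit objects expose tidy, glance and autoplot", {
  sh <- c(16, 16, 16)
  K <- dipole_kernel(sh)
  phi <- forward_field(rand_vol(sh, seed = 51), K)
  p <- admm_params(mu = 10, beta = 1, max_iters = 4L, rel_tol = 0,
                   denoiser = denoiser_spec("identity", sigma = 1),
                   sigma_mode = "fixed")
  fit <- pnp_admm(phi, K, p)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 4L)
  expect_true(all(c("iteration", "primal", "data", "rel_change") %in%
                    names(td)))
  gl <- glance(fit)
  expect_identical(gl$iterations, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("admm_params validates its inputs", {
  expect_error(admm_params(beta = 0), "beta")
  expect_error(admm_params(alpha = -1), "alpha")
  expect_error(admm_params(noise_back_lambda = 1.5), "0, 1")
  expect_error(admm_params(denoiser = "bm4d"), "denoiser_spec")
  expect_error(pnp_admm(volume_grid(array(0, c(8, 8, 8))),
                        dipole_kernel(c(8, 8, 8)), admm_params()),
               "denoiser")
})
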