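# Shared fixtures, built once per test run and memoised here. Everything
# is generated in code under fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# piecewise-constant multi-shape phantom: the canonical denoiser test bed
pc_phantom <- function(shape = c(32L, 32L, 32L)) {
  s <- shape / 32
  phantom_spec(shape, inclusions = list(
    list(kind = "sphere", center = c(12, 12, 12) * s, size = 5 * s[1],
         chi = 0.1, label = 1L),
    list(kind = "cuboid", center = c(22, 22, 20) * s, size = c(8, 8, 8) * s,
         chi = -0.05, label = 2L),
    list(kind = "ellipsoid", center = c(20, 10, 24) * s,
         size = c(9, 5, 4) * s, chi = 0.06, label = 3L)))
}

noisy_pc_64 <- function() memo("noisy_pc_64", function() {
  ph <- make_phantom(pc_phantom(c(64L, 64L, 64L)))
  sigma <- 0.02
  noisy <- ph$chi$data +
    qsmpnp:::with_preserved_seed(11L, array(stats::rnorm(64^3, sd = sigma),
                                            c(64, 64, 64)))
  list(clean = ph$chi$data, noisy = noisy, sigma = sigma)
})

brain48 <- function() memo("brain48", function() {
  ph <- make_brainlike_phantom(7L, shape = c(48, 48, 48))
  kernel <- dipole_kernel(c(48, 48, 48), ph$chi$voxel_size)
  phi <- simulate_observation(ph$chi, kernel, sigma = 0.004, seed = 7L)
  list(ph = ph, kernel = kernel, phi = phi, sigma = 0.004)
})

rand_vol <- function(shape, seed = 1L, sd = 1) {
  qsmpnp:::with_preserved_seed(seed,
    array(stats::rnorm(prod(shape), sd = sd), dim = shape))
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
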