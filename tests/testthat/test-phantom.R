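test_that("voxelized phantoms carry exact piecewise-constant values", {
  sp <- phantom_spec(c(32, 32, 32), inclusions = list(
    list(kind = "sphere", center = c(16, 16, 16), size = 6, chi = 0.1,
         label = 1L)))
  ph <- make_phantom(sp)
  expect_setequal(unique(as.vector(ph$chi$data)), c(0, 0.1))
  expect_true(all(ph$labels$data %in% c(0, 1)))

  # empty inclusion list: background everywhere in the mask
  bg <- make_phantom(phantom_spec(c(16, 16, 16), background = 0.02))
  expect_true(all(bg$chi$data[bg$mask$data > 0] == 0.02))

  # two disjoint spheres: per-label means exact
  sp2 <- phantom_spec(c(32, 32, 32), inclusions = list(
    list(kind = "sphere", center = c(10, 10, 10), size = 4, chi = 0.1,
         label = 1L),
    list(kind = "sphere", center = c(24, 24, 24), size = 4, chi = -0.03,
         label = 2L)))
  ph2 <- make_phantom(sp2)
  expect_identical(mean(ph2$chi$data[ph2$labels$data == 1]), 0.1)
  expect_identical(mean(ph2$chi$data[ph2$labels$data == 2]), -0.03)
})

test_that("overlapping inclusions warn and the later one wins", {
  sp <- phantom_spec(c(24, 24, 24), inclusions = list(
    list(kind = "sphere", center = c(12, 12, 12), size = 5, chi = 0.1,
         label = 1L),
    list(kind = "sphere", center = c(14, 12, 12), size = 5, chi = 0.2,
         label = 2L)))
  expect_warning(ph <- make_phantom(sp), "later inclusion wins")
  expect_identical(mean(ph$chi$data[ph$labels$data == 2]), 0.2)
})

test_that("phantom specs validate labels and geometry", {
  expect_error(phantom_spec(c(16, 16, 16), inclusions = list(
    list(kind = "sphere", center = c(8, 8, 8), size = 3, chi = 1, label = 1L),
    list(kind = "sphere", center = c(4, 4, 4), size = 2, chi = 1, label = 1L))),
    "unique")
  expect_error(phantom_spec(c(16, 16, 16), inclusions = list(
    list(kind = "sphere", center = c(40, 8, 8), size = 3, chi = 1,
         label = 1L))), "outside")
})

test_that("analytic sphere field matches the closed form point-wise", {
  dchi <- 0.12; a <- 4
  ctr <- c(16.5, 16.5, 16.5)   # voxel (17,17,17) center
  fld <- analytic_sphere_field(c(32, 32, 32), c(1, 1, 1), ctr, a, dchi)$data
  # on-axis point at r = 2a: (dchi/3)(1/8)(3 - 1) = dchi/12
  expect_equal(fld[17, 17, 25], dchi / 12, tolerance = 1e-14)
  # equatorial point at r = 2a: (dchi/3)(1/8)(-1) = -dchi/24
  expect_equal(fld[25, 17, 17], -dchi / 24, tolerance = 1e-14)
  # magic angle: offset (4,4,4) has cos^2 = 1/3, so the field vanishes
  expect_equal(fld[21, 21, 21], 0)
  # interior is zero
  expect_identical(fld[17, 17, 18], 0)
  expect_error(analytic_sphere_field(c(32, 32, 32), c(1, 1, 1),
                                     c(64, 16, 16), a, dchi), "outside")
  expect_error(analytic_sphere_field(c(32, 32, 32), c(1, 1, 1),
                                     c(16, 16, 16), 1, dchi), "2 voxels")
})

test_that("simulated observations are exact at sigma 0 and seeded otherwise", {
  sh <- c(32, 32, 32)
  sp <- phantom_spec(sh, inclusions = list(
    list(kind = "sphere", center = c(16, 16, 16), size = 5, chi = 0.1,
         label = 1L)))
  ph <- make_phantom(sp)
  K <- dipole_kernel(sh)
  expect_equal(simulate_observation(ph$chi, K, sigma = 0)$data,
               (forward_field(ph$chi, K)$data) * ph$mask$data)
  a <- simulate_observation(ph$chi, K, sigma = 0.01, seed = 42L)
  b <- simulate_observation(ph$chi, K, sigma = 0.01, seed = 42L)
  expect_identical(a$data, b$data)
  expect_error(simulate_observation(ph$chi, K, sigma = -1), "non-negative")
})

test_that("observation noise has the requested standard deviation", {
  sh <- c(64, 64, 64)
  chi <- volume_grid(array(0, sh))   # no mask: noise everywhere
  K <- dipole_kernel(sh)
  phi <- simulate_observation(chi, K, sigma = 0.01, seed = 3L)
  expect_lt(abs(stats::sd(phi$data) - 0.01) / 0.01, 0.02)
})

test_that("brain-like phantom meets its structural contract", {
  ph <- brain48()$ph
  lab <- ph$labels$data
  ids <- sort(unique(lab[lab > 0]))
  expect_gte(length(ids), 6)
  for (id in ids)
    expect_equal(mean(ph$chi$data[lab == id]), ph$roi_chi[[id]],
                 tolerance = 1e-14)
  # assigned susceptibilities span the physiologic range
  expect_lt(min(ph$roi_chi), -0.04)
  expect_gt(max(ph$roi_chi), 0.14)
  # vessels are thin: < 2% of the mask volume
  vess <- ph$chi$data == 0.30 & ph$mask$data > 0
  expect_lt(sum(vess) / sum(ph$mask$data), 0.02)
  expect_gt(sum(vess), 0)
})

test_that("phantom specs round-trip through YAML", {
  sp <- phantom_spec(c(24, 24, 24), voxel_size = c(1, 1, 2),
                     inclusions = list(
                       list(kind = "sphere", center = c(12, 12, 24), size = 4,
                            chi = 0.1, label = 1L),
                       list(kind = "cuboid", center = c(6, 6, 12),
                            size = c(4, 4, 6), chi = -0.02, label = 2L)),
                     background = 0.01, texture_amplitude = 0.005,
                     support = list(kind = "ellipsoid",
                                    center = c(12, 12, 24),
                                    size = c(22, 22, 44)))
  path <- file.path(tempdir(), "spec.yaml")
  write_phantom_spec(sp, path)
  back <- read_phantom_spec(path)
  expect_identical(make_phantom(back, seed = 3L)$chi$data,
                   make_phantom(sp, seed = 3L)$chi$data)
})

test_that("brain-like phantom is seed-reproducible and seed-sensitive", {
  a <- make_brainlike_phantom(3L, shape = c(48, 48, 48))
  b <- make_brainlike_phantom(3L, shape = c(48, 48, 48))
  c <- make_brainlike_phantom(4L, shape = c(48, 48, 48))
  expect_identical(a$chi$data, b$chi$data)
  expect_false(identical(a$chi$data, c$chi$data))
})
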