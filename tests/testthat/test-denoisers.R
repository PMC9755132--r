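test_that("denoiser specs validate their parameters", {
  expect_error(denoiser_spec("bm4d", sigma = 0), "positive")
  expect_error(denoiser_spec("bm4d", sigma = -1), "positive")
  expect_error(denoiser_spec("bm4d", sigma = 0.1, patch_size = 1), ">= 2")
  expect_error(denoiser_spec("bm4d", sigma = 0.1, max_group_size = 0), ">= 1")
  err <- tryCatch(denoiser_spec("nope", sigma = 0.1), error = identity)
  expect_match(conditionMessage(err), "bm4d")   # lists registered denoisers
  expect_true(all(c("identity", "gaussian", "nlm", "bm4d", "bm3d_slices",
                    "nlpca") %in% registered_denoisers()))
})

test_that("constant volumes are fixed points of every registered denoiser", {
  cvol <- array(0.37, c(16, 16, 16))
  for (nm in registered_denoisers()) {
    spec <- denoiser_spec(nm, sigma = 0.01, patch_size = 4,
                          search_radius = 3, max_group_size = 8)
    out <- denoise(cvol, spec)$data
    expect_lt(max(abs(out - 0.37)), 1e-12)
  }
})

test_that("gaussian denoiser tends to the identity as sigma -> 0", {
  x <- rand_vol(c(12, 12, 12), seed = 8)
  out <- denoise(x, denoiser_spec("gaussian", sigma = 1e-4))$data
  expect_lt(max(abs(out - x)), 1e-12)
})

test_that("block matching finds planted copies (brute-force cross-check)", {
  set.seed(21)
  arr <- array(stats::rnorm(24^3), c(24, 24, 24))
  B <- array(stats::rnorm(64), c(4, 4, 4))
  put <- function(corner) arr[corner[1]:(corner[1] + 3),
                              corner[2]:(corner[2] + 3),
                              corner[3]:(corner[3] + 3)] <<- B
  corners <- list(c(8, 8, 8), c(12, 9, 8), c(9, 13, 10))
  for (cc in corners) put(cc)
  spec <- denoiser_spec("bm4d", sigma = 0.1, patch_size = 4,
                        search_radius = 6, max_group_size = 3)
  got <- block_match(arr, c(8, 8, 8), spec)
  expect_identical(nrow(got), 3L)
  expect_identical(got[1, ], c(8L, 8L, 8L))   # reference first
  expect_setequal(apply(got, 1, paste, collapse = ","),
                  vapply(corners, paste, "", collapse = ","))

  # brute-force oracle: scan every corner in the window
  ref <- arr[8:11, 8:11, 8:11]
  best <- Inf; nbest <- 0
  for (x in 2:14) for (y in 2:14) for (z in 2:14) {
    if (x == 8 && y == 8 && z == 8) next
    d <- sum((arr[x:(x + 3), y:(y + 3), z:(z + 3)] - ref)^2)
    if (d < best) best <- d
  }
  expect_equal(best, 0)   # the planted copies are the closest patches
})

test_that("block matching honors group size and lexicographic tie-breaks", {
  cvol <- array(1, c(12, 12, 12))
  spec1 <- denoiser_spec("bm4d", sigma = 0.1, patch_size = 4,
                         search_radius = 3, max_group_size = 1)
  expect_identical(block_match(cvol, c(5, 5, 5), spec1),
                   matrix(c(5L, 5L, 5L), 1))
  spec4 <- denoiser_spec("bm4d", sigma = 0.1, patch_size = 4,
                         search_radius = 2, max_group_size = 4)
  got <- block_match(cvol, c(5, 5, 5), spec4)
  # all distances tie: reference first, then lexicographic (x, y, z) order
  expect_identical(got[1, ], c(5L, 5L, 5L))
  expect_identical(got[2:4, ], rbind(c(3L, 3L, 3L), c(3L, 3L, 4L),
                                     c(3L, 3L, 5L)))
  expect_error(block_match(array(0, c(3, 3, 3)), c(1, 1, 1), spec4),
               "larger than")
})

test_that("collaborative filtering preserves constants and shrinks energy", {
  spec <- denoiser_spec("bm4d", sigma = 0.05)
  grp <- array(0.42, c(4, 4, 4, 4))
  out <- collaborative_filter(grp, spec)
  expect_equal(out$filtered, grp, tolerance = 1e-12)
  expect_identical(out$n_retained, 1L)      # only the group DC survives
  expect_equal(out$weight, 1 / 2)

  set.seed(9)
  grp2 <- array(stats::rnorm(2 * 64), c(2, 4, 4, 4))
  out2 <- collaborative_filter(grp2, spec)
  expect_lte(sum(out2$filtered^2), sum(grp2^2) + 1e-12)

  # sigma -> Inf: everything except the group DC is zeroed
  hard <- collaborative_filter(grp2, denoiser_spec("bm4d", sigma = 1e6))
  expect_equal(hard$filtered, array(mean(grp2), dim(grp2)), tolerance = 1e-10)
})

test_that("aggregation with identity filtering reproduces the input", {
  set.seed(10)
  arr <- array(stats::rnorm(12^3), c(12, 12, 12))
  p <- c(4L, 4L, 4L)
  cs <- qsmpnp:::corner_seq_r(12L, 4L, 2L)
  corners <- list(); groups <- list(); w <- numeric(0)
  i <- 0
  for (x in cs) for (y in cs) for (z in cs) {
    i <- i + 1
    corners[[i]] <- matrix(c(x, y, z), 1)
    g <- array(0, c(1, p))
    g[1, , , ] <- arr[x:(x + 3), y:(y + 3), z:(z + 3)]
    groups[[i]] <- g
    w[i] <- stats::runif(1, 0.5, 2)   # weights differ; estimates agree
  }
  expect_equal(aggregate_patches(corners, groups, w, c(12, 12, 12)), arr,
               tolerance = 1e-10)
})

test_that("aggregation averages overlapping estimates and flags gaps", {
  one <- array(1, c(1, 2, 2, 2)); three <- array(3, c(1, 2, 2, 2))
  out <- aggregate_patches(list(matrix(c(1L, 1L, 1L), 1),
                                matrix(c(2L, 1L, 1L), 1)),
                           list(one, three), c(1, 1), c(3, 2, 2))
  expect_equal(out[2, 1, 1], 2)   # equal weights: arithmetic mean
  expect_equal(out[1, 1, 1], 1)
  expect_equal(out[3, 1, 1], 3)
  expect_error(aggregate_patches(list(matrix(c(1L, 1L, 1L), 1)),
                                 list(one), 1, c(4, 2, 2)), "uncovered")
})

test_that("pure-R reference pipeline matches the compiled fast path", {
  set.seed(12)
  arr <- array(stats::rnorm(16^3, sd = 0.1), c(16, 16, 16))
  spec <- denoiser_spec("bm4d", sigma = 0.1, patch_size = 4,
                        search_radius = 2, max_group_size = 8)
  fast <- denoise(arr, spec)$data
  slow <- qsmpnp:::bm_denoise_reference(arr, spec)
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("volumetric denoiser gains at least 3 dB on noisy structure", {
  fx <- noisy_pc_64()
  spec <- denoiser_spec("bm4d", sigma = fx$sigma)
  out <- denoise(fx$noisy, spec)$data
  gain <- psnr(out, fx$clean) - psnr(fx$noisy, fx$clean)
  expect_gte(gain, 3)
})

test_that("every nontrivial denoiser beats the identity on the brain phantom", {
  fx <- brain48()
  noisy <- fx$ph$chi$data +
    qsmpnp:::with_preserved_seed(13L,
      array(stats::rnorm(48^3, sd = 0.01), c(48, 48, 48)))
  base <- psnr(noisy, fx$ph$chi$data, fx$ph$mask$data)
  gains <- c()
  for (nm in c("nlm", "bm3d_slices", "bm4d", "nlpca")) {
    spec <- denoiser_spec(nm, sigma = 0.01, search_radius = 3)
    out <- denoise(noisy, spec)$data
    gains[nm] <- psnr(out, fx$ph$chi$data, fx$ph$mask$data) - base
    expect_gt(gains[[nm]], 0)
  }
  # 3D grouping exploits through-plane redundancy
  expect_gte(gains[["bm4d"]], gains[["bm3d_slices"]])
})

test_that("denoising is deterministic and mask-aware", {
  fx <- noisy_pc_64()
  sub <- fx$noisy[1:24, 1:24, 1:24]
  spec <- denoiser_spec("bm4d", sigma = fx$sigma, search_radius = 3)
  expect_identical(denoise(sub, spec)$data, denoise(sub, spec)$data)

  mask <- array(0, c(24, 24, 24)); mask[6:14, 6:14, 6:14] <- 1
  vg <- volume_grid(sub, mask = mask)
  out <- denoise(vg, spec)$data
  expect_identical(out[22:24, 22:24, 22:24], sub[22:24, 22:24, 22:24])
  expect_false(identical(out[6:14, 6:14, 6:14], sub[6:14, 6:14, 6:14]))
})

test_that("nonlocal PCA keeps a rank-1 patch population rank-1", {
  # period-2 tiling: every even-corner patch is identical (rank-1 population)
  set.seed(14)
  base <- array(stats::rnorm(8), c(2, 2, 2))
  arr <- array(0, c(16, 16, 16))
  for (x in 1:16) for (y in 1:16) for (z in 1:16)
    arr[x, y, z] <- base[(x - 1) %% 2 + 1, (y - 1) %% 2 + 1, (z - 1) %% 2 + 1]
  noisy <- arr + array(stats::rnorm(16^3, sd = 0.02), c(16, 16, 16))
  spec <- denoiser_spec("nlpca", sigma = 0.02, patch_size = 4,
                        search_radius = 2, max_group_size = 8)
  out <- denoise(noisy, spec)$data
  cs <- seq(1, 13, by = 2)
  X <- t(vapply(cs, function(x) as.vector(out[x:(x + 3), 5:8, 5:8]),
                numeric(64)))
  sv <- svd(X)$d
  expect_lt(sv[2], 0.05 * sv[1])

  # sigma -> 0 retains every component: identity within 1e-8
  tiny <- denoiser_spec("nlpca", sigma = 1e-9, patch_size = 4,
                        search_radius = 2, max_group_size = 8)
  expect_lt(max(abs(denoise(noisy, tiny)$data - noisy)), 1e-8)
})

test_that("the registry accepts user denoisers for the plug-and-play loop", {
  register_denoiser("halve", function(arr, spec) arr / 2)
  on.exit(rm("halve", envir = qsmpnp:::.denoiser_registry))
  spec <- denoiser_spec("halve", sigma = 1)
  x <- array(2, c(8, 8, 8))
  expect_equal(denoise(x, spec)$data, array(1, c(8, 8, 8)))
})
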