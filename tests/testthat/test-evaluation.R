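test_that("CIELAB conversion hits the reference points", {
  expect_equal(as.vector(rgb_to_lab(array(1, c(1, 1, 3)))), c(100, 0, 0),
               tolerance = 1e-6)
  expect_equal(as.vector(rgb_to_lab(array(0, c(1, 1, 3)))), c(0, 0, 0),
               tolerance = 1e-6)
  ## mid-gray against the closed-form sRGB -> XYZ -> Lab path
  srgb_lin <- ((0.5 + 0.055) / 1.055)^2.4
  L_expect <- 116 * srgb_lin^(1 / 3) - 16
  lab <- as.vector(rgb_to_lab(array(0.5, c(1, 1, 3))))
  expect_equal(lab, c(L_expect, 0, 0), tolerance = 1e-6)
  expect_warning(out <- rgb_to_lab(array(1.4, c(1, 1, 3))), "clipped")
  expect_equal(as.vector(out), c(100, 0, 0), tolerance = 1e-6)
})

test_that("SSIM satisfies its identities and bounds", {
  withr::with_seed(77, x <- matrix(runif(400), 20, 20))
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  withr::with_seed(78, y <- matrix(runif(400), 20, 20))
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_true(ssim(x, y) >= -1 && ssim(x, y) <= 1)
  ## anticorrelated structure scores negative
  checker <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_lt(ssim(checker, 1 - checker), 0)
  expect_error(ssim(x, y[1:10, 1:10]), "share shape")
})

test_that("SSIM agrees with the brute-force per-window oracle", {
  for (trial in 1:100) {
    withr::with_seed(2000 + trial, {
      a <- matrix(runif(256), 16, 16)
      b <- matrix(runif(256), 16, 16)
    })
    expect_equal(ssim(a, b), ssim_brute(a, b), tolerance = 1e-8)
  }
})

test_that("RMSE follows its arithmetic identities", {
  withr::with_seed(80, x <- array(runif(96), c(4, 8, 3)))
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 0.21), 0.21, tolerance = 1e-12)
  a <- array(0, c(2, 1, 3))
  b <- array(c(3, 3, 4, 4, 0, 0), c(2, 1, 3))
  expect_equal(rmse(a, b), sqrt(mean(c(3, 3, 4, 4, 0, 0)^2)))
  expect_error(rmse(x, array(0, c(4, 8, 2))), "share shape")
})

test_that("identical images evaluate to SSIM 1 and RMSE 0", {
  s <- local_phantom()
  rep1 <- evaluate_pair(s$he_true, s$he_true, n_patches = 20, patch_px = 64,
                        seed = 5)
  expect_equal(rep1$ssim_mean, 1, tolerance = 1e-9)
  expect_equal(rep1$ssim_sd, 0, tolerance = 1e-9)
  expect_equal(rep1$rmse_mean, 0, tolerance = 1e-9)
  expect_equal(rep1$n_patches, 20L)
})

test_that("patch sampling is seeded and deterministic", {
  s <- local_phantom()
  noisy <- s$he_true
  withr::with_seed(31, {
    noisy$rgb <- pmin(pmax(noisy$rgb + rnorm(length(noisy$rgb), 0, 0.02), 0), 1)
  })
  r1 <- evaluate_pair(noisy, s$he_true, n_patches = 30, patch_px = 64, seed = 8)
  r2 <- evaluate_pair(noisy, s$he_true, n_patches = 30, patch_px = 64, seed = 8)
  expect_identical(r1, r2)
  r3 <- evaluate_pair(noisy, s$he_true, n_patches = 30, patch_px = 64, seed = 9)
  expect_false(identical(r1$rmse_mean, r3$rmse_mean))
})

test_that("RMSE under additive noise matches a Monte-Carlo oracle", {
  ## keep intensities away from the clip boundary so noise is unclipped
  withr::with_seed(90, base <- 0.3 + 0.4 * array(runif(96 * 96 * 3), c(96, 96, 3)))
  sigma <- 0.02
  noisy1 <- base + withr::with_seed(91, array(rnorm(length(base), 0, sigma),
                                              dim(base)))
  rep1 <- evaluate_pair(noisy1, base, n_patches = 60, patch_px = 48, seed = 3)
  ## oracle: independent noise realization, direct whole-image Lab RMSE
  noisy2 <- base + withr::with_seed(92, array(rnorm(length(base), 0, sigma),
                                              dim(base)))
  oracle <- rmse(rgb_to_lab(noisy2), rgb_to_lab(base))
  expect_lt(abs(rep1$rmse_mean - oracle) / oracle, 0.05)
})

test_that("RMSE grows monotonically with added independent noise", {
  withr::with_seed(95, base <- 0.3 + 0.4 * array(runif(64 * 64 * 3), c(64, 64, 3)))
  sigmas <- c(0.005, 0.02, 0.05)
  vals <- vapply(seq_along(sigmas), function(i) {
    noisy <- base + withr::with_seed(95 + i, array(rnorm(length(base), 0,
                                                         sigmas[i]), dim(base)))
    noisy <- pmin(pmax(noisy, 0), 1)
    rmse(rgb_to_lab(noisy), rgb_to_lab(base))
  }, 0)
  expect_true(all(diff(vals) > 0))
})
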