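test_that("identical spec and seed reproduce the phantom bit-exactly", {
  sp <- phantom_spec(96, 96, seed = 11L)
  expect_identical(sample_phantom(sp), sample_phantom(sp))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(0, 64), "positive")
  expect_error(phantom_spec(64, -3), "positive")
  expect_error(phantom_spec(64, 64, noise_sd = -0.1), "nonnegative")
  expect_error(phantom_spec(64, 64, nuclei_density = -1), "nonnegative")
})

test_that("without nuclei and noise the non-radiative channel is pure cross-talk", {
  s <- sample_phantom(phantom_spec(96, 96, nuclei_density = 0, noise_sd = 0,
                                   seed = 5L), include_stream = FALSE)
  expect_true(all(s$concentration_maps$c_n == 0))
  ch1 <- s$contrast$channels[, , 1]
  expect_equal(ch1, pmin(0.09 * s$concentration_maps$c_e, 1), tolerance = 1e-12)
  expect_true(all(ch1[s$concentration_maps$c_e == 0] == 0))
})

test_that("nucleus counts follow the requested Poisson density", {
  ## density 5 per 100x100 px on a 200x200 field: mean count 20
  counts <- vapply(seq_len(1000), function(i) {
    s <- sample_phantom(phantom_spec(200, 200, nuclei_density = 5,
                                     fiber_count = 0, vessel_count = 0,
                                     noise_sd = 0, warp_amplitude_px = 0,
                                     seed = 1000L + i),
                        include_stream = FALSE)
    nrow(s$nuclei)
  }, 0L)
  se <- sqrt(20 / 1000)
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("the nuclear map is positive exactly where nuclei were placed", {
  s <- local_phantom()
  cn <- s$concentration_maps$c_n
  expect_true(all(cn >= 0) && all(s$concentration_maps$c_e >= 0))
  if (nrow(s$nuclei) > 0) {
    centers <- round(cbind(s$nuclei$cy, s$nuclei$cx))
    inside <- centers[, 1] >= 1 & centers[, 1] <= nrow(cn) &
      centers[, 2] >= 1 & centers[, 2] <= ncol(cn)
    expect_true(all(cn[centers[inside, , drop = FALSE]] > 0))
  }
})

test_that("noise-free non-radiative contrast tracks the nuclear compartment", {
  s <- sample_phantom(phantom_spec(128, 128, noise_sd = 0, seed = 4L),
                      include_stream = FALSE)
  ch1 <- as.vector(s$contrast$channels[, , 1])
  expect_gt(cor(ch1, as.vector(s$concentration_maps$c_n)),
            cor(ch1, as.vector(s$concentration_maps$c_e)))
})

test_that("H&E rendering follows the Beer-Lambert closed form", {
  z <- matrix(0, 4, 4)
  ## zero absorbance everywhere: pure white
  expect_equal(render_he(z, z)$rgb, array(1, c(4, 4, 3)))
  ## unit nuclear concentration against an explicit stain vector
  sv <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  him <- render_he(z + 1, z, sv)
  expect_equal(him$rgb[1, 1, ], exp(-c(0.65, 0.70, 0.29)), tolerance = 1e-12)
  ## doubling concentration doubles the optical density exactly
  c_n <- matrix(runif(16, 0, 0.7), 4, 4)
  od1 <- -log(render_he(c_n, z, sv)$rgb)
  od2 <- -log(render_he(2 * c_n, z, sv)$rgb)
  expect_equal(od2, 2 * od1, tolerance = 1e-9)
})

test_that("rendered intensity never increases with concentration", {
  withr::with_seed(21, {
    c_n <- matrix(runif(64), 8, 8)
    c_e <- matrix(runif(64), 8, 8)
  })
  base <- render_he(c_n, c_e)$rgb
  up_n <- render_he(c_n + 0.3, c_e)$rgb
  up_e <- render_he(c_n, c_e + 0.3)$rgb
  expect_true(all(up_n <= base))
  expect_true(all(up_e <= base))
  expect_error(render_he(c_n - 2, c_e), "nonnegative")
})

test_that("zero-amplitude misregistration is the identity", {
  s <- local_phantom()
  mis <- apply_misregistration(s$he_true, 0, seed = 3L)
  expect_identical(mis$warped$rgb, s$he_true$rgb)
  expect_equal(mis$transform$family, "identity")
  expect_equal(mis$landmarks$x_mov, mis$landmarks$x_ref)
})

test_that("misregistration respects the amplitude bound and is invertible", {
  s <- local_phantom()
  a <- 5
  mis <- apply_misregistration(s$he_true, a, seed = 9L)
  disp <- sqrt((mis$landmarks$x_mov - mis$landmarks$x_ref)^2 +
                 (mis$landmarks$y_mov - mis$landmarks$y_ref)^2)
  expect_true(all(disp <= a + 1e-9))
  ## warping the moving copy with the true transform recovers the
  ## original up to interpolation error away from the border
  back <- warp_image(mis$warped, mis$transform, dim(s$he_true$rgb)[1:2])
  inner <- 16:112
  expect_lt(mean(abs(back$rgb[inner, inner, ] - s$he_true$rgb[inner, inner, ])),
            0.01)
})

test_that("scan streams enumerate pixel centres in raster order", {
  s <- local_phantom()
  st <- s$pulse_stream
  h <- 128; w <- 128
  expect_equal(nrow(st), h * w)
  pitch_um <- 0.25
  expect_equal(st$x_um[1:3], (1:3 - 0.5) * pitch_um)
  expect_equal(st$y_um[1:3], rep(0.5 * pitch_um, 3))
  ## row-major: second row starts after w records
  expect_equal(st$y_um[w + 1], 1.5 * pitch_um)
})

test_that("jittered records still bin to their source pixel", {
  s <- local_phantom()
  st <- emit_scan_stream(s$contrast, jitter_px = 0.4, seed = 2L)
  rec <- reconstruct_grid(st)
  expect_identical(rec$channels, s$contrast$channels)
  expect_true(all(rec$mask))
})
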