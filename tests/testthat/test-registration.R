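test_that("field-of-view matching rescales to the reference pitch", {
  s <- local_phantom()
  same <- match_fov(s$contrast, s$he_true)
  expect_identical(same$rgb, s$he_true$rgb)
  coarse <- stained_image(s$he_true$rgb, pixel_pitch_nm = 500)
  matched <- match_fov(s$contrast, coarse)
  expect_equal(dim(matched$rgb)[1:2], 2L * dim(s$he_true$rgb)[1:2])
  expect_equal(matched$pixel_pitch_nm, 250)
  ## round trip restores the dimensions
  back <- match_fov(contrast_stack(array(0.5, c(10, 10, 3)),
                                   pixel_pitch_nm = 500), matched)
  expect_equal(dim(back$rgb)[1:2], dim(s$he_true$rgb)[1:2])
  bad <- s$he_true; bad$pixel_pitch_nm <- NULL
  expect_error(match_fov(s$contrast, bad), "metadata")
})

test_that("landmark refinement recovers a known integer translation", {
  ref <- smooth_random_image(96, 96, seed = 31)
  ## moving = reference shifted by (dx, dy) = (3, -2)
  dx <- 3; dy <- -2
  src_r <- pmin(pmax(1:96 - dy, 1), 96)
  src_c <- pmin(pmax(1:96 - dx, 1), 96)
  mov <- ref[src_r, src_c]
  lm <- landmark_set(c(30, 60, 40), c(30, 40, 66), c(30, 60, 40), c(30, 40, 66))
  ref_fine <- refine_landmarks(ref, mov, lm, window_px = 8, search_px = 5,
                               subpixel = FALSE)
  expect_equal(ref_fine$x_mov, lm$x_ref + dx)
  expect_equal(ref_fine$y_mov, lm$y_ref + dy)
  ## identical images: peak at zero shift
  same <- refine_landmarks(ref, ref, lm, window_px = 8, search_px = 4,
                           subpixel = FALSE)
  expect_equal(same$x_mov, lm$x_mov)
  ## zero search radius is the identity
  expect_identical(refine_landmarks(ref, mov, lm, search_px = 0), lm)
})

test_that("flat correlation windows are left unchanged with a warning", {
  flat <- matrix(0.5, 64, 64)
  lm <- landmark_set(32, 32, 32, 32)
  expect_warning(out <- refine_landmarks(flat, flat, lm, window_px = 6,
                                         search_px = 3),
                 "zero variance")
  expect_identical(unclass(out), unclass(lm))
})

test_that("affine fits recover generating parameters exactly", {
  withr::with_seed(17, {
    p <- cbind(runif(12, 1, 100), runif(12, 1, 100))
  })
  A <- rbind(c(4, -2), c(1.2, 0.8), c(-0.3, 1.1))  # [intercept; x; y]
  v <- cbind(1, p) %*% A
  lm <- landmark_set(p[, 1], p[, 2], v[, 1], v[, 2])
  tf <- fit_transform(lm, family = "affine")
  expect_equal(tf$coef, A, tolerance = 1e-9, ignore_attr = TRUE)
  ## identity pairs give zero residual
  id <- fit_transform(landmark_set(p[, 1], p[, 2], p[, 1], p[, 2]),
                      family = "affine")
  expect_equal(transform_points(id, p), p, tolerance = 1e-9)
})

test_that("thin-plate splines interpolate their landmarks exactly", {
  for (trial in 1:20) {
    withr::with_seed(300 + trial, {
      n <- sample(5:15, 1)
      p <- cbind(runif(n, 1, 200), runif(n, 1, 200))
      v <- p + matrix(rnorm(2 * n, 0, 4), n, 2)
    })
    lm <- landmark_set(p[, 1], p[, 2], v[, 1], v[, 2])
    tf <- fit_transform(lm)
    expect_equal(transform_points(tf, p), v, tolerance = 1e-6)
  }
})

test_that("degenerate landmark configurations are named in errors", {
  expect_error(fit_transform(landmark_set(c(1, 1, 5, 9), c(2, 2, 5, 9),
                                          1:4, 1:4)),
               "duplicated")
  expect_error(fit_transform(landmark_set(c(1, 2, 3), c(2, 4, 6),
                                          c(1, 2, 3), c(2, 4, 6)),
                             family = "affine"),
               "collinear")
  expect_error(fit_transform(landmark_set(1:3, c(1, 5, 2), 1:3, c(1, 5, 2))),
               "at least 4")
})

test_that("warping honors the inverse-mapping convention", {
  s <- local_phantom()
  id <- fit_transform(NULL, family = "identity")
  expect_equal(warp_image(s$he_true, id, c(128, 128))$rgb, s$he_true$rgb)
  ## pure +10 px translation in x: content shifts, right margin flagged
  tr <- structure(list(family = "affine",
                       coef = rbind(c(10, 0), c(1, 0), c(0, 1))),
                  class = "spatial_transform")
  w <- warp_image(s$he_true, tr, c(128, 128))
  expect_equal(w$rgb[, 1:118, ], s$he_true$rgb[, 11:128, ], tolerance = 1e-12)
  expect_true(all(!w$mask[, 120:128]))
  expect_true(all(w$rgb[, 120:128, ] == 1))  # white H&E background fill
})

test_that("landmark registration recovers a known smooth warp", {
  ## supported regime: warp amplitude up to 8 px
  res <- run_registration_demo(seed = 3, size = 512, warp_amplitude_px = 8)
  expect_lte(res$landmark_residual_px, 0.5)
  expect_lte(res$interior_mae_pct, 2)
})
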