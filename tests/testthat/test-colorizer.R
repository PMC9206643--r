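test_that("adversarial losses evaluate to their closed forms", {
  ## perfect discrimination drives the loss toward zero
  near0 <- discriminator_loss(matrix(1 - 1e-7, 4, 4), matrix(1e-7, 4, 4))
  expect_lt(near0, 1e-6)
  ## uninformative scores: sum of two mean BCE terms = 2 ln 2
  expect_equal(discriminator_loss(matrix(0.5, 4, 4), matrix(0.5, 4, 4)),
               2 * log(2), tolerance = 1e-12)
  ## permutation of pixels within a map leaves the mean unchanged
  withr::with_seed(5, {
    sr <- matrix(runif(16, 0.01, 0.99), 4, 4)
    sf <- matrix(runif(16, 0.01, 0.99), 4, 4)
  })
  expect_equal(discriminator_loss(sr, sf),
               discriminator_loss(matrix(sample(sr), 4, 4),
                                  matrix(sample(sf), 4, 4)))
  expect_error(discriminator_loss(matrix(0.5, 2, 2), matrix(0.5, 3, 3)),
               "shape")
})

test_that("generator loss combines adversarial and L1 terms", {
  img <- array(0.5, c(4, 4, 3))
  ## perfect fake scored real: both terms vanish
  expect_lt(generator_loss(matrix(1 - 1e-7, 2, 2), img, img, 100), 1e-6)
  ## lambda 0 reduces to the adversarial term
  withr::with_seed(6, other <- array(runif(48), c(4, 4, 3)))
  expect_equal(generator_loss(matrix(0.3, 2, 2), img, other, 0),
               parstain:::bce_loss(matrix(0.3, 2, 2), 1))
  ## worked closed form: ln 2 + 100 * 0.1
  expect_equal(generator_loss(matrix(0.5, 2, 2), img + 0.1, img, 100),
               log(2) + 10, tolerance = 1e-6)
  expect_error(generator_loss(matrix(0.5, 2, 2), img, array(0, c(2, 2, 3))),
               "shape")
})

## Small deterministic training task shared below: map a blurred ramp
## stack to a known color rendering.
tiny_pairs <- function(n = 6, px = 16, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    x <- array(runif(px * px * 3), c(px, px, 3))
    y <- array(0, c(px, px, 3))
    for (k in 1:3) y[, , k] <- (x[, , 1] + x[, , k]) / 2
    list(x = x, y = y)
  }))
}

test_that("training is bit-reproducible under a fixed seed", {
  cfg <- train_config(max_epochs = 3, patience_epochs = 5, batch_size = 2,
                      base_width = 4, depth = 2, seed = 9, val_fraction = 0.2)
  b1 <- train_colorizer(tiny_pairs(), config = cfg)
  b2 <- train_colorizer(tiny_pairs(), config = cfg)
  expect_identical(b1$history, b2$history)
  expect_identical(parstain:::net_flatten(b1$generator),
                   parstain:::net_flatten(b2$generator))
})

test_that("zero patience stops at the first non-improving epoch", {
  cfg <- train_config(max_epochs = 50, patience_epochs = 0, batch_size = 2,
                      base_width = 4, depth = 2, seed = 4, val_fraction = 0.2,
                      min_delta = 1e-4)
  b <- train_colorizer(tiny_pairs(), config = cfg)
  n <- nrow(b$history)
  if (n < 50) {
    ## every epoch but the last improved on the running best
    best <- Inf
    improved <- logical(n)
    for (i in seq_len(n)) {
      improved[i] <- b$history$monitor[i] < best - cfg$min_delta
      best <- min(best, b$history$monitor[i])
    }
    expect_true(all(improved[-n]))
    expect_false(improved[n])
  }
  expect_lte(b$best_epoch, n)
  expect_gte(nrow(b$history), 1)
  expect_lte(nrow(b$history), cfg$max_epochs)
})

test_that("the L1 term decreases when overfitting a small tile set", {
  cfg <- train_config(max_epochs = 40, patience_epochs = 40, batch_size = 4,
                      base_width = 8, depth = 2, seed = 2, lr = 2e-3,
                      val_fraction = 0)
  b <- train_colorizer(tiny_pairs(n = 8, px = 32, seed = 3), config = cfg)
  l1 <- b$history$g_l1
  expect_lt(l1[length(l1)], l1[1])
  ## trailing window is better than the opening window
  expect_lt(mean(utils::tail(l1, 5)), mean(utils::head(l1, 5)))
})

test_that("empty training sets and bad tiles are rejected", {
  expect_error(train_colorizer(list()), "empty")
  bad <- list(list(x = array(0, c(16, 12, 3)), y = array(0, c(16, 12, 3))))
  expect_error(train_colorizer(bad, config = train_config()), "square")
})

test_that("colorize stitches generator output at the input shape", {
  s <- local_phantom()
  prep <- prepare_input(s$contrast)
  cfg <- train_config(max_epochs = 1, batch_size = 4, base_width = 4,
                      depth = 2, seed = 3, val_fraction = 0)
  grid <- plan_tiles(c(128, 128), 32, 0)
  bundle <- train_colorizer(tile_pairs(prep, s$he_true, grid), config = cfg,
                            provenance = prep$provenance)
  out <- colorize(bundle, prep)
  expect_s3_class(out, "stained_image")
  expect_equal(dim(out$rgb), c(128, 128, 3))
  expect_true(all(out$rgb >= 0 & out$rgb <= 1))
  ## deterministic wiring: same bundle, same input, same output
  expect_identical(out$rgb, colorize(bundle, prep)$rgb)
  ## provenance mismatch warns
  prep2 <- prep
  prep2$provenance <- c(prep$provenance, "extra")
  expect_warning(colorize(bundle, prep2), "provenance")
})

test_that("bundles round-trip through serialization bit-exactly", {
  cfg <- train_config(max_epochs = 2, batch_size = 2, base_width = 4,
                      depth = 2, seed = 12, val_fraction = 0.2)
  b <- train_colorizer(tiny_pairs(), config = cfg, provenance = "minmax")
  dir <- withr::local_tempdir()
  save_bundle(b, dir)
  b2 <- load_bundle(dir)
  expect_identical(parstain:::net_flatten(b$generator),
                   parstain:::net_flatten(b2$generator))
  expect_identical(parstain:::net_flatten(b$discriminator),
                   parstain:::net_flatten(b2$discriminator))
  expect_equal(b$history, b2$history)
  expect_identical(b$provenance, b2$provenance)
  expect_identical(b$tile_px, b2$tile_px)
})
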