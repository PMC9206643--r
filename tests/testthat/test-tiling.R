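test_that("tile plans match the enumeration oracle", {
  ## one exact tile
  g1 <- plan_tiles(c(256, 256), 256, 0.5)
  expect_equal(nrow(g1$anchors), 1)
  expect_equal(unlist(g1$anchors[1, ]), c(row = 1, col = 1))
  ## 512 px, 50% overlap: anchors {1, 129, 257} per axis, 9 tiles
  g2 <- plan_tiles(c(512, 512), 256, 0.5)
  expect_equal(sort(unique(g2$anchors$row)), c(1, 129, 257))
  expect_equal(nrow(g2$anchors), 9)
  ## large raster: compare against brute-force anchor generation
  g3 <- plan_tiles(c(4000, 6500), 256, 0.5)
  rows <- anchors_brute(4000, 256, 128)
  cols <- anchors_brute(6500, 256, 128)
  expect_equal(sort(unique(g3$anchors$row)), rows)
  expect_equal(sort(unique(g3$anchors$col)), cols)
  expect_equal(nrow(g3$anchors), length(rows) * length(cols))
  ## random shapes against the oracle
  for (trial in 1:25) {
    withr::with_seed(600 + trial, {
      h <- sample(40:300, 1); w <- sample(40:300, 1)
      t_px <- sample(c(16, 32, 64), 1)
      ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    })
    g <- plan_tiles(c(h, w), t_px, ov)
    expect_equal(sort(unique(g$anchors$row)), anchors_brute(h, t_px, g$stride))
    expect_equal(sort(unique(g$anchors$col)), anchors_brute(w, t_px, g$stride))
    expect_false(any(duplicated(g$anchors)))
  }
  expect_error(plan_tiles(c(100, 100), 0), "positive integer")
  expect_error(plan_tiles(c(100, 100), 64, 1), "overlap_frac")
})

test_that("extracted tiles are the corresponding submatrices", {
  img <- matrix(seq_len(256 * 300), 256, 300)
  g <- plan_tiles(c(256, 300), 64, 0.5)
  tiles <- extract_tiles(img, g)
  i <- which(g$anchors$row == 129 & g$anchors$col == 129)
  expect_equal(tiles[[i]], img[129:192, 129:192])
  const <- extract_tiles(matrix(0.3, 256, 300), g)
  expect_true(all(vapply(const, function(t) all(t == 0.3), TRUE)))
  expect_error(extract_tiles(matrix(0, 10, 10), g), "does not match")
})

test_that("stitching is the exact inverse of extraction", {
  withr::with_seed(42, img <- array(runif(200 * 176 * 3), c(200, 176, 3)))
  g <- plan_tiles(c(200, 176), 64, 0.5)
  back <- stitch_tiles(extract_tiles(img, g), g)
  expect_lt(max(abs(back - img)), 1e-6)
  ## single tile passes through unchanged
  g1 <- plan_tiles(c(64, 64), 64, 0.5)
  tile <- matrix(runif(64 * 64), 64, 64)
  expect_equal(stitch_tiles(list(tile), g1), tile)
})

test_that("normalized stitch weights form a partition of unity", {
  for (shape in list(c(128, 128), c(200, 150), c(97, 130))) {
    g <- plan_tiles(shape, 64, 0.5)
    ones <- lapply(seq_len(nrow(g$anchors)), function(i) matrix(1, 64, 64))
    acc <- stitch_tiles(ones, g)
    expect_lt(max(abs(acc - 1)), 1e-9)
  }
})

test_that("stitching is invariant to tile processing order", {
  withr::with_seed(8, img <- matrix(runif(128 * 128), 128, 128))
  g <- plan_tiles(c(128, 128), 64, 0.5)
  tiles <- extract_tiles(img, g)
  ref <- stitch_tiles(tiles, g)
  perm <- withr::with_seed(9, sample.int(nrow(g$anchors)))
  g2 <- g
  g2$anchors <- g$anchors[perm, ]
  expect_equal(stitch_tiles(tiles[perm], g2), ref, tolerance = 1e-12)
})

test_that("overlapping constant tiles blend monotonically", {
  g <- plan_tiles(c(64, 96), 64, 0.5)  # two tiles overlapping 32 px in x
  expect_equal(nrow(g$anchors), 2)
  out <- stitch_tiles(list(matrix(0, 64, 64), matrix(1, 64, 64)), g)
  mid <- out[32, ]
  expect_equal(mid[1:32], rep(0, 32))          # only tile 1 covers
  expect_equal(mid[65:96], rep(1, 32))         # only tile 2 covers
  expect_true(all(diff(mid[32:66]) >= -1e-12)) # blended ramp is monotone
})

test_that("images smaller than a tile are reflect-padded to one tile", {
  img <- matrix(runif(40 * 50), 40, 50)
  g <- plan_tiles(c(40, 50), 64, 0.5)
  expect_equal(nrow(g$anchors), 1)
  tiles <- extract_tiles(img, g)
  expect_equal(dim(tiles[[1]]), c(64, 64))
  expect_equal(tiles[[1]][1:40, 1:50], img)
  back <- stitch_tiles(tiles, g)
  expect_equal(back, img, tolerance = 1e-12)
})
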