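## The network machinery is checked two ways: compiled kernels against
## the pure-R reference layouts, and analytic gradients against central
## finite differences.

test_that("compiled convolution kernels match the R reference layout", {
  withr::with_seed(50, {
    x <- array(rnorm(10 * 12 * 4 * 3), c(10, 12, 4, 3))
    W <- matrix(rnorm(9 * 4 * 5), 9 * 4, 5)
    b <- rnorm(5)
    dy <- array(rnorm(10 * 12 * 5 * 3), c(10, 12, 5, 3))
  })
  cols_ref <- parstain:::im2col_ref(x, 3L)
  expect_equal(parstain:::im2col_cpp(x, 3L), cols_ref, tolerance = 1e-14)
  ## forward: direct conv == im2col GEMM
  y_ref <- cols_ref %*% W
  y_ref <- y_ref + rep(b, each = nrow(y_ref))
  y_ref <- parstain:::hwnc_to_tensor(y_ref, 10L, 12L, 3L)
  expect_equal(parstain:::conv_fwd_cpp(x, W, b, 3L), y_ref, tolerance = 1e-12)
  ## backward: direct conv == im2col adjoint route
  dym <- parstain:::tensor_to_hwnc(dy)
  bk <- parstain:::conv_bwd_cpp(x, W, dy, 3L)
  expect_equal(bk$dW, crossprod(cols_ref, dym), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(bk$db, colSums(dym), tolerance = 1e-10, ignore_attr = TRUE)
  dx_ref <- parstain:::col2im_ref(tcrossprod(dym, W), 3L, 10L, 12L, 4L, 3L)
  expect_equal(bk$dx, dx_ref, tolerance = 1e-10)
  expect_equal(parstain:::col2im_cpp(tcrossprod(dym, W), 3L, 10L, 12L, 4L, 3L),
               dx_ref, tolerance = 1e-12)
})

## Flatten per-layer analytic gradients in net_flatten order.
flatten_grads <- function(net, grads) {
  unlist(lapply(seq_along(net$layers), function(i) {
    if (net$layers[[i]]$type == "conv") {
      c(as.vector(grads[[i]]$W), grads[[i]]$b)
    }
  }), use.names = FALSE)
}

test_that("backpropagation matches finite differences", {
  nf <- parstain:::net_forward
  nb <- parstain:::net_backward
  uf <- parstain:::net_unflatten
  for (case in c("generator", "discriminator")) {
    net <- if (case == "generator") {
      build_generator(base_width = 4, depth = 2, seed = 5)
    } else {
      build_discriminator(base_width = 4, seed = 6)
    }
    ch <- net$in_ch
    withr::with_seed(60, {
      x <- array(runif(8 * 8 * ch * 2), c(8, 8, ch, 2))
      y <- array(runif(length(nf(net, x)$out)), dim(nf(net, x)$out))
    })
    f <- nf(net, x, keep_cache = TRUE)
    bk <- nb(net, f$caches, 2 * (f$out - y) / length(y))
    ga <- flatten_grads(net, bk$grads)
    th <- parstain:::net_flatten(net)
    idx <- withr::with_seed(61, sample.int(length(th), 40))
    eps <- 1e-6
    gn <- vapply(idx, function(j) {
      tp <- th; tp[j] <- tp[j] + eps
      tm <- th; tm[j] <- tm[j] - eps
      (mean((nf(uf(net, tp), x)$out - y)^2) -
         mean((nf(uf(net, tm), x)$out - y)^2)) / (2 * eps)
    }, 0)
    expect_lt(max(abs(gn - ga[idx]) / pmax(abs(gn) + abs(ga[idx]), 1e-6)),
              1e-4)
    ## gradient with respect to the network input (drives the generator
    ## update through the discriminator)
    gxn <- vapply(c(11L, 73L), function(j) {
      xp <- x; xp[j] <- xp[j] + eps
      xm <- x; xm[j] <- xm[j] - eps
      (mean((nf(net, xp)$out - y)^2) - mean((nf(net, xm)$out - y)^2)) / (2 * eps)
    }, 0)
    expect_equal(bk$dx[c(11L, 73L)], gxn, tolerance = 1e-5)
  }
})

test_that("generator output is bounded and shape-preserving", {
  G <- build_generator(base_width = 4, depth = 3, seed = 2)
  withr::with_seed(3, x <- array(rnorm(16 * 16 * 3 * 2, sd = 50), c(16, 16, 3, 2)))
  out <- parstain:::net_forward(G, x)$out
  expect_equal(dim(out), dim(x))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("discriminator emits a strictly smaller probability map", {
  D <- build_discriminator(base_width = 4, seed = 2)
  x <- array(0.5, c(16, 16, 6, 1))
  out <- parstain:::net_forward(D, x)$out
  expect_equal(dim(out), c(4, 4, 1, 1))
  expect_true(all(out > 0 & out < 1))
})
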