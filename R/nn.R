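## Minimal convolutional-network machinery for the adversarial
## colorizer: BLAS-backed im2col convolutions, leaky-ReLU / sigmoid
## nonlinearities, 2x2 mean pooling, nearest-neighbour upsampling and
## skip-connection concatenation, with exact reverse-mode gradients and
## an Adam optimizer. Tensors are `H x W x C x N` arrays. Networks are
## flat layer sequences; U-Net skips are expressed with `push`/`popcat`
## layers operating on a LIFO stack, which keeps backpropagation a
## single reversed sweep. Gradient correctness is pinned against finite
## differences in the test suite.

## ---- layer constructors -------------------------------------------------

nn_conv <- function(out_ch, k = 3L) list(type = "conv", k = as.integer(k), out = as.integer(out_ch))
nn_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nn_sigmoid <- function() list(type = "sigmoid")
nn_pool <- function() list(type = "pool")
nn_up <- function() list(type = "up")
nn_push <- function() list(type = "push")
nn_popcat <- function() list(type = "popcat")

## Instantiate parameters. He-scaled normal init, fully seeded.
net_build <- function(arch, in_ch, seed = 1L) {
  with_seed(seed, {
    ch <- in_ch
    skip_ch <- integer(0)
    layers <- lapply(arch, function(spec) {
      if (spec$type == "conv") {
        fan_in <- spec$k^2 * ch
        spec$W <- matrix(rnorm(fan_in * spec$out, 0, sqrt(2 / fan_in)),
                         fan_in, spec$out)
        spec$b <- rep(0, spec$out)
        spec$in_ch <- ch
        ch <<- spec$out
      } else if (spec$type == "push") {
        skip_ch[length(skip_ch) + 1L] <<- ch
      } else if (spec$type == "popcat") {
        s <- skip_ch[length(skip_ch)]
        skip_ch <<- skip_ch[-length(skip_ch)]
        spec$main_ch <- ch
        spec$skip_ch <- s
        ch <<- ch + s
      }
      spec
    })
    structure(list(layers = layers, in_ch = as.integer(in_ch), out_ch = ch),
              class = "nn_net")
  })
}

## ---- im2col convolution -------------------------------------------------

## Reference (pure R) implementations of the neighbourhood unfolding and
## its adjoint; the compiled versions in src/conv_ops.cpp mirror these
## layouts exactly and the test suite asserts their equivalence. Row
## order is (pixel-within-image, image); column order is (offset,
## channel-within-offset).
im2col_ref <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, C, N))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  cols <- vector("list", k * k)
  i <- 1L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    slab <- xp[dy + seq_len(H), dx + seq_len(W), , , drop = FALSE]
    cols[[i]] <- matrix(aperm(slab, c(1, 2, 4, 3)), H * W * N, C)
    i <- i + 1L
  }
  do.call(cbind, cols)
}

## Adjoint of im2col: scatter-add column gradients back to input layout.
col2im_ref <- function(cols, k, H, W, C, N) {
  p <- (k - 1L) %/% 2L
  gp <- array(0, c(H + 2L * p, W + 2L * p, C, N))
  i <- 1L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    m <- cols[, ((i - 1L) * C + 1L):(i * C), drop = FALSE]
    slab <- aperm(array(m, c(H, W, N, C)), c(1, 2, 4, 3))
    ys <- dy + seq_len(H); xs <- dx + seq_len(W)
    gp[ys, xs, , ] <- gp[ys, xs, , , drop = FALSE] + slab
    i <- i + 1L
  }
  gp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

conv_forward <- function(layer, x) {
  list(out = conv_fwd_cpp(x, layer$W, layer$b, layer$k),
       cache = x)
}

conv_backward <- function(layer, cache, dy) {
  bk <- conv_bwd_cpp(cache, layer$W, dy, layer$k)
  list(dx = bk$dx, grads = list(W = bk$dW, b = bk$db))
}

## ---- other primitives ---------------------------------------------------

pool_forward <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1], by = 2L); e <- seq(1L, d[2], by = 2L)
  out <- 0.25 * (x[o, e, , , drop = FALSE] + x[o + 1L, e, , , drop = FALSE] +
                 x[o, e + 1L, , , drop = FALSE] + x[o + 1L, e + 1L, , , drop = FALSE])
  list(out = out, cache = d)
}

pool_backward <- function(dims, dy) {
  dx <- array(0, dims)
  o <- seq(1L, dims[1], by = 2L); e <- seq(1L, dims[2], by = 2L)
  g <- 0.25 * dy
  dx[o, e, , ] <- g; dx[o + 1L, e, , ] <- g
  dx[o, e + 1L, , ] <- g; dx[o + 1L, e + 1L, , ] <- g
  dx
}

up_forward <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  list(out = x[ri, ci, , , drop = FALSE], cache = d)
}

up_backward <- function(dims, dy) {
  o <- seq(1L, 2L * dims[1], by = 2L); e <- seq(1L, 2L * dims[2], by = 2L)
  dy[o, e, , , drop = FALSE] + dy[o + 1L, e, , , drop = FALSE] +
    dy[o, e + 1L, , , drop = FALSE] + dy[o + 1L, e + 1L, , , drop = FALSE]
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## ---- network execution --------------------------------------------------

## Forward pass. Returns the output tensor and, when `keep_cache`, the
## per-layer caches needed by `net_backward`.
net_forward <- function(net, x, keep_cache = FALSE) {
  stack <- list()
  caches <- if (keep_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      f <- conv_forward(l, x)
      x <- f$out
      if (keep_cache) caches[[i]] <- f$cache
    } else if (l$type == "lrelu") {
      mask <- x > 0
      x <- x * (mask + l$slope * !mask)
      if (keep_cache) caches[[i]] <- mask
    } else if (l$type == "sigmoid") {
      x <- 1 / (1 + exp(-x))
      if (keep_cache) caches[[i]] <- x
    } else if (l$type == "pool") {
      f <- pool_forward(x)
      x <- f$out
      if (keep_cache) caches[[i]] <- f$cache
    } else if (l$type == "up") {
      f <- up_forward(x)
      x <- f$out
      if (keep_cache) caches[[i]] <- f$cache
    } else if (l$type == "push") {
      stack[[length(stack) + 1L]] <- x
    } else if (l$type == "popcat") {
      s <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      x <- cat_channels(x, s)
    }
  }
  list(out = x, caches = caches)
}

## Reverse sweep: returns per-layer parameter gradients and the gradient
## with respect to the network input.
net_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$layers))
  gstack <- list()
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      bk <- conv_backward(l, caches[[i]], dy)
      grads[[i]] <- bk$grads
      dy <- bk$dx
    } else if (l$type == "lrelu") {
      m <- caches[[i]]
      dy <- dy * (m + l$slope * !m)
    } else if (l$type == "sigmoid") {
      y <- caches[[i]]
      dy <- dy * y * (1 - y)
    } else if (l$type == "pool") {
      dy <- pool_backward(caches[[i]], dy)
    } else if (l$type == "up") {
      dy <- up_backward(caches[[i]], dy)
    } else if (l$type == "push") {
      g <- gstack[[length(gstack)]]
      gstack[[length(gstack)]] <- NULL
      dy <- dy + g
    } else if (l$type == "popcat") {
      mc <- l$main_ch
      gstack[[length(gstack) + 1L]] <-
        dy[, , mc + seq_len(l$skip_ch), , drop = FALSE]
      dy <- dy[, , seq_len(mc), , drop = FALSE]
    }
  }
  list(grads = grads, dx = dy)
}

## ---- Adam optimizer -----------------------------------------------------

adam_init <- function(net) {
  list(t = 0L, m = lapply(net$layers, function(l) {
    if (l$type == "conv") list(W = l$W * 0, b = l$b * 0)
  }), v = lapply(net$layers, function(l) {
    if (l$type == "conv") list(W = l$W * 0, b = l$b * 0)
  }))
}

adam_step <- function(net, state, grads, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    if (net$layers[[i]]$type != "conv") next
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[p]] / bc1
      vhat <- state$v[[i]][[p]] / bc2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

## ---- parameter flattening (serialization, finite-difference tests) ------

net_flatten <- function(net) {
  unlist(lapply(net$layers, function(l) {
    if (l$type == "conv") c(as.vector(l$W), l$b)
  }), use.names = FALSE)
}

net_unflatten <- function(net, theta) {
  pos <- 0L
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type != "conv") next
    nw <- length(l$W)
    net$layers[[i]]$W <- matrix(theta[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    pos <- pos + nw
    nb <- length(l$b)
    net$layers[[i]]$b <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}
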