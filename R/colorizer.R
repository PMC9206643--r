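## Conditional adversarial colorizer. A U-Net generator maps a prepared
## 3-channel stack tile to an RGB H&E tile; a patch-level discriminator
## scores the channel-concatenation of input stack and (real or
## generated) RGB as a spatial map of real/fake probabilities. The two
## are trained simultaneously: the discriminator minimizes its
## classification error, the generator maximizes the discriminator's
## error while staying close to the real H&E in L1.

#' Training configuration for the colorizer
#'
#' @param max_epochs maximum training epochs (default 500).
#' @param patience_epochs epochs without validation improvement before
#'   early stop (default 20; 0 stops at the first non-improving epoch).
#' @param min_delta minimum decrease of the monitored loss that counts
#'   as an improvement.
#' @param lambda_l1 weight of the L1 reconstruction term (default 100).
#' @param lr learning rate of both Adam optimizers.
#' @param beta1,beta2 Adam moment coefficients (0.5 / 0.999).
#' @param batch_size tiles per update.
#' @param seed RNG seed covering initialization and shuffling.
#' @param val_fraction fraction of training tiles held out for the
#'   early-stopping monitor when no validation set is supplied.
#' @param base_width channels of the first encoder level.
#' @param depth number of resolution levels of the U-Net.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 500, patience_epochs = 20,
                         min_delta = 1e-4, lambda_l1 = 100, lr = 2e-4,
                         beta1 = 0.5, beta2 = 0.999, batch_size = 8,
                         seed = 1L, val_fraction = 0.15,
                         base_width = 16, depth = 3) {
  if (max_epochs < 1) stopf("`max_epochs` must be at least 1")
  if (lambda_l1 < 0) stopf("`lambda_l1` must be nonnegative")
  structure(
    list(max_epochs = as.integer(max_epochs),
         patience_epochs = as.integer(patience_epochs),
         min_delta = min_delta, lambda_l1 = lambda_l1, lr = lr,
         beta1 = beta1, beta2 = beta2, batch_size = as.integer(batch_size),
         seed = as.integer(seed), val_fraction = val_fraction,
         base_width = as.integer(base_width), depth = as.integer(depth)),
    class = "train_config"
  )
}

#' Build the U-Net generator
#'
#' Encoder-decoder with mirrored skip connections: each level is one
#' 3x3 convolution + leaky ReLU, levels are linked by 2x2 mean pooling
#' and nearest-neighbour upsampling, skips are concatenated, and a
#' final 3x3 convolution + sigmoid emits bounded 3-channel RGB.
#'
#' @param in_ch,out_ch input/output channels (3 and 3).
#' @param base_width channels at the first level; doubled per level.
#' @param depth number of resolution levels (input side must be
#'   divisible by `2^(depth-1)`).
#' @param seed RNG seed for initialization.
#' @return An `nn_net` generator.
#' @export
build_generator <- function(in_ch = 3, out_ch = 3, base_width = 16,
                            depth = 3, seed = 1L) {
  widths <- base_width * 2^(seq_len(depth) - 1)
  arch <- list()
  for (i in seq_len(depth - 1)) {
    arch <- c(arch, list(nn_conv(widths[i]), nn_lrelu(), nn_push(), nn_pool()))
  }
  arch <- c(arch, list(nn_conv(widths[depth]), nn_lrelu()))
  for (i in rev(seq_len(depth - 1))) {
    arch <- c(arch, list(nn_up(), nn_popcat(), nn_conv(widths[i]), nn_lrelu()))
  }
  arch <- c(arch, list(nn_conv(out_ch), nn_sigmoid()))
  net_build(arch, in_ch, seed = seed)
}

#' Build the patch-level discriminator
#'
#' Classifier on the channel-concatenation of the conditioning stack
#' and an RGB image (6 channels). Two conv + pool stages followed by a
#' 1-channel conv + sigmoid yield a spatial map of real/fake
#' probabilities, each score depending on a bounded receptive field.
#'
#' @param in_ch input channels (default 6: stack + RGB).
#' @param base_width channels of the first stage.
#' @param seed RNG seed.
#' @return An `nn_net` discriminator.
#' @export
build_discriminator <- function(in_ch = 6, base_width = 16, seed = 1L) {
  arch <- list(nn_conv(base_width), nn_lrelu(), nn_pool(),
               nn_conv(base_width * 2), nn_lrelu(), nn_pool(),
               nn_conv(1), nn_sigmoid())
  net_build(arch, in_ch, seed = seed)
}

## Clamped binary cross-entropy over a probability map.
bce_loss <- function(p, target) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_grad <- function(p, target) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  (-target / p + (1 - target) / (1 - p)) / length(p)
}

#' Discriminator loss
#'
#' Mean binary cross-entropy of the real-score map against target 1
#' plus the fake-score map against target 0.
#'
#' @param score_real,score_fake same-shape probability maps in `(0, 1)`.
#' @return A single nonnegative number.
#' @export
discriminator_loss <- function(score_real, score_fake) {
  if (!all(dim(score_real) == dim(score_fake)) ||
      length(score_real) != length(score_fake)) {
    stopf("score maps must share shape")
  }
  bce_loss(score_real, 1) + bce_loss(score_fake, 0)
}

#' Generator loss
#'
#' Adversarial term (cross-entropy of the fake-score map against target
#' 1, i.e. the generator tries to make fakes score real) plus
#' `lambda_l1` times the mean absolute error between generated and real
#' RGB.
#'
#' @param score_fake probability map of the discriminator on the fake.
#' @param fake_rgb,real_rgb same-shape image arrays.
#' @param lambda_l1 nonnegative L1 weight.
#' @return A single number.
#' @export
generator_loss <- function(score_fake, fake_rgb, real_rgb, lambda_l1 = 100) {
  if (!all(dim(fake_rgb) == dim(real_rgb)) ||
      length(fake_rgb) != length(real_rgb)) {
    stopf("images must share shape")
  }
  bce_loss(score_fake, 1) + lambda_l1 * mean(abs(fake_rgb - real_rgb))
}

## Stack a list of H x W x C tiles into an H x W x C x N tensor.
tiles_to_tensor <- function(tiles) {
  d <- dim(tiles[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(tiles)))
  for (i in seq_along(tiles)) out[, , , i] <- tiles[[i]]
  out
}

#' Train the adversarial colorizer
#'
#' Alternating discriminator/generator updates per batch, fully seeded.
#' After every epoch the generator loss (adversarial + L1) is measured
#' on the validation tiles; training stops at `max_epochs` or when that
#' loss has not improved by `min_delta` for more than `patience_epochs`
#' epochs, and the parameters of the best validation epoch are
#' returned.
#'
#' @param train_pairs list of pairs `list(x = H x W x 3 input tile,
#'   y = H x W x 3 RGB tile)`; all tiles square and equal-sized.
#' @param val_pairs optional validation pairs; when `NULL`, a
#'   `val_fraction` split of `train_pairs` is held out (if the fraction
#'   is 0 the training loss is monitored instead).
#' @param config a [train_config()].
#' @param provenance character vector recording the preprocessing that
#'   produced the input tiles (stored in the bundle and checked at
#'   inference).
#' @param verbose print per-epoch losses.
#' @return An object of class `model_bundle`.
#' @export
train_colorizer <- function(train_pairs, val_pairs = NULL,
                            config = train_config(),
                            provenance = character(0), verbose = FALSE) {
  if (length(train_pairs) == 0) stopf("empty training set")
  t_px <- dim(train_pairs[[1]]$x)[1]
  if (dim(train_pairs[[1]]$x)[2] != t_px) stopf("tiles must be square")
  if (t_px %% 2^(config$depth - 1) != 0) {
    stopf("tile size %d is not divisible by 2^(depth-1) = %d",
          t_px, 2^(config$depth - 1))
  }
  with_seed(config$seed, {
    if (is.null(val_pairs) && config$val_fraction > 0 && length(train_pairs) >= 4) {
      n_val <- max(1L, floor(config$val_fraction * length(train_pairs)))
      idx <- sample.int(length(train_pairs))
      val_pairs <- train_pairs[idx[seq_len(n_val)]]
      train_pairs <- train_pairs[idx[-seq_len(n_val)]]
    }
    X <- tiles_to_tensor(lapply(train_pairs, `[[`, "x"))
    Y <- tiles_to_tensor(lapply(train_pairs, `[[`, "y"))
    has_val <- length(val_pairs) > 0
    if (has_val) {
      Xv <- tiles_to_tensor(lapply(val_pairs, `[[`, "x"))
      Yv <- tiles_to_tensor(lapply(val_pairs, `[[`, "y"))
    }
    n <- dim(X)[4]
    G <- build_generator(base_width = config$base_width, depth = config$depth,
                         seed = config$seed + 101L)
    D <- build_discriminator(base_width = config$base_width,
                             seed = config$seed + 202L)
    oG <- adam_init(G)
    oD <- adam_init(D)
    history <- data.frame(epoch = integer(0), d_loss = numeric(0),
                          g_adv = numeric(0), g_l1 = numeric(0),
                          g_loss = numeric(0), monitor = numeric(0))
    best <- Inf
    best_G <- G
    best_epoch <- 0L
    stale <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ed <- ega <- el1 <- 0
      for (b in batches) {
        xb <- X[, , , b, drop = FALSE]
        yb <- Y[, , , b, drop = FALSE]
        ## --- discriminator step ---
        fake <- net_forward(G, xb)$out
        fr <- net_forward(D, cat_channels(xb, yb), keep_cache = TRUE)
        bk_r <- net_backward(D, fr$caches, bce_grad(fr$out, 1))
        ff <- net_forward(D, cat_channels(xb, fake), keep_cache = TRUE)
        bk_f <- net_backward(D, ff$caches, bce_grad(ff$out, 0))
        gD <- Map(function(a, b) if (is.null(a)) NULL else
          list(W = a$W + b$W, b = a$b + b$b), bk_r$grads, bk_f$grads)
        st <- adam_step(D, oD, gD, lr = config$lr, beta1 = config$beta1,
                        beta2 = config$beta2)
        D <- st$net; oD <- st$state
        d_loss <- bce_loss(fr$out, 1) + bce_loss(ff$out, 0)
        ## --- generator step ---
        fg <- net_forward(G, xb, keep_cache = TRUE)
        fake <- fg$out
        fd <- net_forward(D, cat_channels(xb, fake), keep_cache = TRUE)
        adv <- bce_loss(fd$out, 1)
        l1 <- mean(abs(fake - yb))
        dD <- net_backward(D, fd$caches, bce_grad(fd$out, 1))
        dfake <- dD$dx[, , 4:6, , drop = FALSE] +
          config$lambda_l1 * sign(fake - yb) / length(fake)
        bkG <- net_backward(G, fg$caches, dfake)
        st <- adam_step(G, oG, bkG$grads, lr = config$lr, beta1 = config$beta1,
                        beta2 = config$beta2)
        G <- st$net; oG <- st$state
        if (!is.finite(d_loss) || !is.finite(adv) || !is.finite(l1)) {
          stopf("non-finite loss at epoch %d (d = %g, adv = %g, l1 = %g); aborting",
                epoch, d_loss, adv, l1)
        }
        w <- length(b) / n
        ed <- ed + d_loss * w
        ega <- ega + adv * w
        el1 <- el1 + l1 * w
      }
      g_loss <- ega + config$lambda_l1 * el1
      monitor <- if (has_val) {
        fv <- net_forward(G, Xv)$out
        sv <- net_forward(D, cat_channels(Xv, fv))$out
        generator_loss(sv, fv, Yv, config$lambda_l1)
      } else {
        g_loss
      }
      history <- rbind(history, data.frame(
        epoch = epoch, d_loss = ed, g_adv = ega, g_l1 = el1,
        g_loss = g_loss, monitor = monitor))
      if (verbose) {
        message(sprintf("epoch %3d  d %.4f  g_adv %.4f  l1 %.4f  monitor %.4f",
                        epoch, ed, ega, el1, monitor))
      }
      if (monitor < best - config$min_delta) {
        best <- monitor
        best_G <- G
        best_epoch <- epoch
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale > config$patience_epochs) break
      }
    }
    structure(
      list(generator = best_G, discriminator = D, config = config,
           history = history, best_epoch = best_epoch, tile_px = t_px,
           provenance = provenance,
           channel_order = c("non_radiative", "radiative", "scattering")),
      class = "model_bundle"
    )
  })
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle> %d px tiles, %d epochs trained (best epoch %d, monitor %.4f)\n",
    x$tile_px, nrow(x$history), x$best_epoch,
    if (x$best_epoch > 0) x$history$monitor[x$best_epoch] else NA))
  invisible(x)
}

#' Colorize a prepared stack with a trained bundle
#'
#' Runs the generator on overlapping tiles of the prepared stack and
#' recombines the predictions with raised-cosine stitching.
#'
#' @param bundle a [train_colorizer()] bundle.
#' @param stack a `normalized_stack` from [prepare_input()] (its
#'   provenance is compared with the bundle's; a mismatch warns).
#' @param grid optional [plan_tiles()] grid; defaults to the bundle's
#'   tile size with 50% overlap.
#' @param batch_size tiles per generator forward pass.
#' @return A [stained_image()] with RGB in `[0, 1]`.
#' @export
colorize <- function(bundle, stack, grid = NULL, batch_size = 16) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!inherits(stack, "normalized_stack")) {
    stopf("`stack` must be a normalized_stack from prepare_input()")
  }
  if (dim(stack$channels)[3] != 3) stopf("input must have 3 channels")
  if (length(bundle$provenance) &&
      !identical(bundle$provenance, stack$provenance)) {
    warnf("preprocessing provenance differs from the training data (%s vs %s)",
          paste(stack$provenance, collapse = " -> "),
          paste(bundle$provenance, collapse = " -> "))
  }
  shape <- dim(stack$channels)[1:2]
  if (is.null(grid)) grid <- plan_tiles(shape, bundle$tile_px, 0.5)
  tiles <- extract_tiles(stack$channels, grid)
  preds <- vector("list", length(tiles))
  for (start in seq(1, length(tiles), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(tiles))
    xb <- tiles_to_tensor(tiles[idx])
    yb <- net_forward(bundle$generator, xb)$out
    for (j in seq_along(idx)) preds[[idx[j]]] <- yb[, , , j, drop = FALSE][, , , 1]
  }
  rgb <- stitch_tiles(preds, grid)
  stained_image(clip01(rgb),
                pixel_pitch_nm = if (!is.null(stack$pixel_pitch_nm))
                  stack$pixel_pitch_nm else 250)
}

#' Save / load a model bundle
#'
#' The bundle directory holds the network parameters as a raw double
#' stream (`params.bin`), the architecture and configuration as YAML,
#' and the training history as CSV; the round trip is bit-exact.
#'
#' @param bundle a `model_bundle`.
#' @param dir target directory (created if missing).
#' @return `save_bundle` returns `dir` invisibly; `load_bundle` returns
#'   the restored `model_bundle`.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  theta <- c(net_flatten(bundle$generator), net_flatten(bundle$discriminator))
  writeBin(theta, file.path(dir, "params.bin"), size = 8)
  meta <- list(
    n_generator = length(net_flatten(bundle$generator)),
    tile_px = bundle$tile_px, best_epoch = bundle$best_epoch,
    provenance = as.list(bundle$provenance),
    channel_order = as.list(bundle$channel_order),
    config = unclass(bundle$config))
  yaml::write_yaml(meta, file.path(dir, "bundle.yaml"))
  write.csv(bundle$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  cfg <- do.call(train_config, meta$config[names(meta$config) %in%
                                             names(formals(train_config))])
  G <- build_generator(base_width = cfg$base_width, depth = cfg$depth,
                       seed = cfg$seed + 101L)
  D <- build_discriminator(base_width = cfg$base_width, seed = cfg$seed + 202L)
  n_total <- length(net_flatten(G)) + length(net_flatten(D))
  theta <- readBin(file.path(dir, "params.bin"), what = "double", n = n_total,
                   size = 8)
  G <- net_unflatten(G, theta[seq_len(meta$n_generator)])
  D <- net_unflatten(D, theta[-seq_len(meta$n_generator)])
  structure(
    list(generator = G, discriminator = D, config = cfg,
         history = read.csv(file.path(dir, "history.csv")),
         best_epoch = meta$best_epoch, tile_px = meta$tile_px,
         provenance = unlist(meta$provenance),
         channel_order = unlist(meta$channel_order)),
    class = "model_bundle"
  )
}
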