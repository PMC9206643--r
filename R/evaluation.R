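## Quantitative comparison of virtual and true H&E. Images are converted
## to CIELAB (a perceptually correlated space) before computing the
## structural similarity index (SSIM) and root mean square error (RMSE)
## over randomly sampled patches; the report carries mean +/- sd.

#' Convert an sRGB image to CIELAB
#'
#' Standard-observer CIELAB under D65 with sRGB companding, via
#' `grDevices::convertColor`. `L` lies in `[0, 100]`; `a` and `b` in
#' roughly `[-128, 127]`. Out-of-range input is clipped with a warning.
#'
#' @param image a [stained_image()] or `H x W x 3` array with values in
#'   `[0, 1]`.
#' @return `H x W x 3` array of L, a, b planes.
#' @export
rgb_to_lab <- function(image) {
  rgb <- if (inherits(image, "stained_image")) image$rgb else image
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stopf("`image` must be an H x W x 3 RGB array")
  }
  if (any(rgb < 0) || any(rgb > 1)) {
    warnf("RGB values outside [0, 1] were clipped before Lab conversion")
    rgb <- clip01(rgb)
  }
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  m <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  lab <- convertColor(m, from = "sRGB", to = "Lab")
  array(lab, c(h, w, 3))
}

## Box-filter window sums over all `valid` window positions via an
## integral image; returns an (h-w+1) x (w-w+1) matrix.
box_sum <- function(m, win) {
  h <- nrow(m); w <- ncol(m)
  I <- matrix(0, h + 1, w + 1)
  I[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  rows <- seq_len(h - win + 1)
  cols <- seq_len(w - win + 1)
  I[rows + win, cols + win, drop = FALSE] -
    I[rows, cols + win, drop = FALSE] -
    I[rows + win, cols, drop = FALSE] +
    I[rows, cols, drop = FALSE]
}

#' Structural similarity index
#'
#' Mean over all sliding windows of the standard SSIM expression
#' (luminance x contrast x structure with the two stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`), using a uniform square window
#' and population moments.
#'
#' @param a,b numeric matrices of equal shape, at least `window_px` in
#'   each dimension.
#' @param window_px side of the sliding window (default 7).
#' @param dynamic_range value range `L` of the data (e.g. 100 for the
#'   CIELAB L channel).
#' @return A single value in `[-1, 1]`.
#' @export
ssim <- function(a, b, window_px = 7, dynamic_range = 1) {
  if (!all(dim(a) == dim(b))) stopf("`a` and `b` must share shape")
  if (dynamic_range <= 0) stopf("`dynamic_range` must be positive")
  if (any(dim(a) < window_px)) {
    stopf("images must be at least window_px (%d) in each dimension", window_px)
  }
  n <- window_px^2
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu_a <- box_sum(a, window_px) / n
  mu_b <- box_sum(b, window_px) / n
  var_a <- box_sum(a * a, window_px) / n - mu_a^2
  var_b <- box_sum(b * b, window_px) / n - mu_b^2
  cov_ab <- box_sum(a * b, window_px) / n - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(s)
}

#' Root mean square error
#'
#' `sqrt(mean((a - b)^2))` over all pixels (and channels, for arrays).
#'
#' @param a,b numeric arrays of equal shape.
#' @return A nonnegative number.
#' @export
rmse <- function(a, b) {
  if (!all(dim(a) == dim(b)) || length(a) != length(b)) {
    stopf("`a` and `b` must share shape")
  }
  sqrt(mean((a - b)^2))
}

#' Patchwise SSIM/RMSE evaluation in CIELAB
#'
#' Converts both images to CIELAB, samples `n_patches` square patch
#' locations uniformly (with replacement, seeded), and computes per
#' patch the SSIM (averaged over the L, a, b channels, with dynamic
#' range 100 for L and 255 for a/b) and the RMSE pooled over the three
#' Lab channels. Reports mean and standard deviation of both metrics.
#'
#' @param pred,truth aligned equal-shape [stained_image()]s (or RGB
#'   arrays).
#' @param n_patches number of sampled patches (default 1000).
#' @param patch_px patch side in pixels (default 256; reduced with a
#'   warning when the images are smaller).
#' @param seed RNG seed for patch sampling.
#' @param window_px SSIM window.
#' @return An object of class `metrics_report` with fields `ssim_mean`,
#'   `ssim_sd`, `rmse_mean`, `rmse_sd`, `n_patches`, `patch_px`,
#'   `color_space`, `rmse_units` and `seed`.
#' @export
evaluate_pair <- function(pred, truth, n_patches = 1000, patch_px = 256,
                          seed = 1L, window_px = 7) {
  pr <- if (inherits(pred, "stained_image")) pred$rgb else pred
  tr <- if (inherits(truth, "stained_image")) truth$rgb else truth
  if (!all(dim(pr) == dim(tr))) stopf("`pred` and `truth` must share shape")
  h <- dim(pr)[1]; w <- dim(pr)[2]
  if (min(h, w) < patch_px) {
    patch_px <- min(h, w)
    warnf("images smaller than requested patch; using patch_px = %d", patch_px)
  }
  if (patch_px < window_px) stopf("patch_px must be at least window_px")
  lab_p <- rgb_to_lab(pr)
  lab_t <- rgb_to_lab(tr)
  dr <- c(100, 255, 255)
  anchors <- with_seed(seed, data.frame(
    row = sample.int(h - patch_px + 1, n_patches, replace = TRUE),
    col = sample.int(w - patch_px + 1, n_patches, replace = TRUE)))
  ssim_i <- rmse_i <- numeric(n_patches)
  for (i in seq_len(n_patches)) {
    rows <- anchors$row[i]:(anchors$row[i] + patch_px - 1)
    cols <- anchors$col[i]:(anchors$col[i] + patch_px - 1)
    s <- 0
    for (k in 1:3) {
      s <- s + ssim(lab_p[rows, cols, k], lab_t[rows, cols, k],
                    window_px = window_px, dynamic_range = dr[k])
    }
    ssim_i[i] <- s / 3
    rmse_i[i] <- rmse(lab_p[rows, cols, ], lab_t[rows, cols, ])
  }
  structure(
    list(ssim_mean = mean(ssim_i), ssim_sd = sd(ssim_i),
         rmse_mean = mean(rmse_i), rmse_sd = sd(rmse_i),
         n_patches = as.integer(n_patches), patch_px = as.integer(patch_px),
         color_space = "CIELAB (D65, sRGB companding)",
         rmse_units = "native Lab units, pooled over L, a, b",
         ssim_detail = "per Lab channel (L range 100, a/b range 255), averaged",
         seed = as.integer(seed)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  SSIM: %.4f +/- %.4f\n", x$ssim_mean, x$ssim_sd))
  cat(sprintf("  RMSE: %.4f +/- %.4f (%s)\n", x$rmse_mean, x$rmse_sd, x$rmse_units))
  cat(sprintf("  %d patches of %d px, %s\n", x$n_patches, x$patch_px,
              x$color_space))
  invisible(x)
}
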