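## Deterministic overlapping tiling and seamless stitching. Tiles of
## `tile_px` pixels are anchored every `stride = round(tile_px * (1 -
## overlap_frac))` pixels, with the final anchor clamped so the last tile
## ends exactly at the image border; predictions are recombined with a
## separable raised-cosine window normalized to a partition of unity, so
## patch borders leave no visible seams.

#' Plan an overlapping tile grid
#'
#' @param image_shape integer `c(height, width)`.
#' @param tile_px tile side length in pixels (default 256).
#' @param overlap_frac fractional overlap between adjacent tiles, in
#'   `[0, 1)` (default 0.5).
#' @return An object of class `tile_grid`: `tile_px`, `overlap_frac`,
#'   `stride`, `anchors` (data.frame of 1-based top-left `row, col`, in
#'   row-major order), `image_shape` and `pad` (per-axis reflect padding
#'   applied when the image is smaller than one tile).
#' @export
plan_tiles <- function(image_shape, tile_px = 256, overlap_frac = 0.5) {
  if (!is_count(tile_px)) stopf("`tile_px` must be a positive integer")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stopf("`overlap_frac` must lie in [0, 1)")
  }
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  if (h < 1 || w < 1) stopf("image shape must be positive")
  stride <- max(1L, as.integer(round(tile_px * (1 - overlap_frac))))
  anchors_axis <- function(d) {
    if (d <= tile_px) return(1L)
    last <- d - tile_px + 1L
    unique(c(seq.int(1L, last, by = stride), last))
  }
  rows <- anchors_axis(h)
  cols <- anchors_axis(w)
  structure(
    list(tile_px = as.integer(tile_px), overlap_frac = overlap_frac,
         stride = stride,
         anchors = expand.grid(col = cols, row = rows)[, c("row", "col")],
         image_shape = c(h, w),
         pad = c(max(0L, tile_px - h), max(0L, tile_px - w))),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "<tile_grid> %d tiles of %d px (overlap %.0f%%, stride %d) on %d x %d image\n",
    nrow(x$anchors), x$tile_px, 100 * x$overlap_frac, x$stride,
    x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

## Reflect-pad an image on the bottom/right so images smaller than one
## tile still produce a full tile.
pad_reflect <- function(img, pad_h, pad_w) {
  if (pad_h == 0 && pad_w == 0) return(img)
  two_d <- length(dim(img)) < 3
  if (two_d) dim(img) <- c(dim(img), 1L)
  h <- dim(img)[1]; w <- dim(img)[2]
  ## mirror without repeating the border pixel, wrapping if pad exceeds size
  refl <- function(n, pad) {
    if (pad == 0) return(seq_len(n))
    idx <- seq_len(pad)
    src <- if (n == 1) rep(1L, pad) else n - 1 - (idx - 1) %% (n - 1)
    c(seq_len(n), src)
  }
  out <- img[refl(h, pad_h), refl(w, pad_w), , drop = FALSE]
  if (two_d) out <- out[, , 1]
  out
}

#' Extract tiles from an image
#'
#' @param image numeric matrix or `H x W x C` array matching the grid's
#'   `image_shape`.
#' @param grid a [plan_tiles()] grid.
#' @return List of tiles (same dimensionality as `image`) in anchor
#'   order.
#' @export
extract_tiles <- function(image, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- dim(image)
  if (d[1] != grid$image_shape[1] || d[2] != grid$image_shape[2]) {
    stopf("image shape (%d x %d) does not match grid (%d x %d)",
          d[1], d[2], grid$image_shape[1], grid$image_shape[2])
  }
  img <- pad_reflect(image, grid$pad[1], grid$pad[2])
  two_d <- length(dim(img)) < 3
  t_px <- grid$tile_px
  lapply(seq_len(nrow(grid$anchors)), function(i) {
    r <- grid$anchors$row[i]; c <- grid$anchors$col[i]
    if (two_d) img[r:(r + t_px - 1), c:(c + t_px - 1)]
    else img[r:(r + t_px - 1), c:(c + t_px - 1), , drop = FALSE]
  })
}

## Separable raised-cosine (Hann) blending profile, floored at eps so
## every covered pixel keeps strictly positive weight.
raised_cosine_window <- function(t_px, eps = 1e-3) {
  u <- (seq_len(t_px) - 0.5) / t_px
  pmax(0.5 - 0.5 * cos(2 * pi * u), eps)
}

#' Stitch tiles back into an image
#'
#' Weighted recombination `out(p) = sum w_t(p) tile_t(p) / sum w_t(p)`
#' over all tiles covering pixel `p`, with a separable raised-cosine
#' window (floored at `1e-3`). The normalization makes the effective
#' weights a partition of unity, so tiles cut from an image stitch back
#' to that image to numerical precision.
#'
#' @param tiles list of tiles in anchor order (as from
#'   [extract_tiles()] or per-tile model outputs).
#' @param grid the [plan_tiles()] grid the tiles were planned on.
#' @param window `"raised_cosine"` (default) or `"uniform"`.
#' @return Image of the grid's `image_shape` (matrix if the tiles are
#'   matrices, else `H x W x C`).
#' @export
stitch_tiles <- function(tiles, grid, window = c("raised_cosine", "uniform")) {
  stopifnot(inherits(grid, "tile_grid"))
  window <- match.arg(window)
  n <- nrow(grid$anchors)
  if (length(tiles) != n) {
    stopf("grid expects %d tiles, got %d", n, length(tiles))
  }
  t_px <- grid$tile_px
  first <- tiles[[1]]
  two_d <- length(dim(first)) < 3
  chans <- if (two_d) 1L else dim(first)[3]
  wv <- if (window == "raised_cosine") raised_cosine_window(t_px) else rep(1, t_px)
  W <- outer(wv, wv)
  hp <- grid$image_shape[1] + grid$pad[1]
  wp <- grid$image_shape[2] + grid$pad[2]
  num <- array(0, c(hp, wp, chans))
  den <- matrix(0, hp, wp)
  for (i in seq_len(n)) {
    r <- grid$anchors$row[i]; c <- grid$anchors$col[i]
    tile <- tiles[[i]]
    if (two_d) dim(tile) <- c(t_px, t_px, 1L)
    if (!all(dim(tile)[1:2] == t_px)) stopf("tile %d has wrong size", i)
    rows <- r:(r + t_px - 1); cols <- c:(c + t_px - 1)
    den[rows, cols] <- den[rows, cols] + W
    for (k in seq_len(chans)) {
      num[rows, cols, k] <- num[rows, cols, k] + tile[, , k] * W
    }
  }
  out <- array(0, c(hp, wp, chans))
  for (k in seq_len(chans)) out[, , k] <- num[, , k] / den
  out <- out[seq_len(grid$image_shape[1]), seq_len(grid$image_shape[2]), ,
             drop = FALSE]
  if (two_d) out <- out[, , 1]
  out
}
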