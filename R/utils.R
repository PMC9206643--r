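## Internal numeric helpers shared across modules.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x == round(x)

## Bilinear interpolation of `img` (H x W matrix or H x W x C array) at
## fractional pixel coordinates (x = column, y = row, 1-based, pixel
## centres at integers). Out-of-bounds locations receive `fill`.
## Returns a length(x) vector (matrix input) or length(x) x C matrix.
bilinear_sample <- function(img, x, y, fill = 0) {
  chans <- if (length(dim(img)) == 3) dim(img)[3] else 1L
  if (length(dim(img)) < 3) dim(img) <- c(dim(img), 1L)
  h <- dim(img)[1]
  w <- dim(img)[2]
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  inside <- x >= 1 & x <= w & y >= 1 & y <= h
  ## clamp the 2x2 neighbourhood so border pixels interpolate against
  ## themselves rather than indexing out of range
  cx0 <- pmin(pmax(x0, 1), w)
  cx1 <- pmin(pmax(x0 + 1, 1), w)
  cy0 <- pmin(pmax(y0, 1), h)
  cy1 <- pmin(pmax(y0 + 1, 1), h)
  out <- matrix(fill, nrow = length(x), ncol = chans)
  for (c in seq_len(chans)) {
    plane <- img[, , c]
    v <- (1 - fx) * (1 - fy) * plane[cbind(cy0, cx0)] +
      fx * (1 - fy) * plane[cbind(cy0, cx1)] +
      (1 - fx) * fy * plane[cbind(cy1, cx0)] +
      fx * fy * plane[cbind(cy1, cx1)]
    v[!inside] <- fill
    out[, c] <- v
  }
  if (chans == 1L) out <- drop(out)
  out
}

## Isotropic Gaussian smoothing of a matrix; sigma in pixels.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- 2 * max(2, ceiling(2 * sigma)) + 1  # odd kernel size
  ## FFT filtering can leave ~1e-16 negatives on nonnegative input
  pmax(as.matrix(EBImage::gblur(m, sigma = sigma, radius = r)), 0)
}

## Bilinear resize of a matrix or H x W x C array to new dimensions.
resize_bilinear <- function(img, new_h, new_w) {
  if (length(dim(img)) == 3) {
    out <- array(0, c(new_h, new_w, dim(img)[3]))
    for (c in seq_len(dim(img)[3])) {
      out[, , c] <- resize_bilinear(img[, , c], new_h, new_w)
    }
    return(out)
  }
  ## EBImage treats dim 1 as x; an H x W matrix therefore resizes with
  ## w = new_h, h = new_w.
  as.matrix(EBImage::resize(img, w = new_h, h = new_w, filter = "bilinear"))
}
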