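## Shared fixtures and independent brute-force oracles used across the
## suite. Oracles are deliberately naive (loops, sorting, enumeration)
## and never call the implementation paths they check.

## Small phantom shared by several tests; built once per test run.
local_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_phantom(phantom_spec(128, 128, seed = 7L))
    }
    cache
  }
})

## Smooth random single-channel image (for correlation-based tests).
smooth_random_image <- function(h, w, seed, sigma = 3) {
  withr::with_seed(seed, {
    m <- matrix(runif(h * w), h, w)
    k <- stats::dnorm(-(2 * sigma):(2 * sigma), sd = sigma)
    m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
    m <- t(apply(m, 1, function(row) stats::filter(row, k, circular = TRUE)))
    m <- m - min(m)
    m / max(m)
  })
}

## Sort-based type-7 percentile stretch oracle.
stretch_oracle <- function(x, low_pct, high_pct) {
  s <- sort(x)
  n <- length(s)
  q7 <- function(p) {
    hpos <- (n - 1) * p + 1
    lo <- floor(hpos)
    hi <- ceiling(hpos)
    s[lo] + (hpos - lo) * (s[hi] - s[lo])
  }
  p_lo <- q7(low_pct / 100)
  p_hi <- q7(1 - high_pct / 100)
  if (p_hi == p_lo) return(x * 0)
  pmin(pmax((x - p_lo) / (p_hi - p_lo), 0), 1)
}

## Per-window SSIM oracle (uniform window, population moments).
ssim_brute <- function(a, b, win = 7, L = 1) {
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  vals <- numeric(0)
  for (i in 1:(nrow(a) - win + 1)) {
    for (j in 1:(ncol(a) - win + 1)) {
      wa <- a[i:(i + win - 1), j:(j + win - 1)]
      wb <- b[i:(i + win - 1), j:(j + win - 1)]
      mua <- mean(wa); mub <- mean(wb)
      va <- mean(wa^2) - mua^2
      vb <- mean(wb^2) - mub^2
      cab <- mean(wa * wb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + c1) * (2 * cab + c2)) /
                  ((mua^2 + mub^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

## Brute-force nearest-centre binning-and-mean reconstruction oracle;
## pixels without any record stay NA.
recon_brute <- function(records, pitch_nm, h, w) {
  pitch_um <- pitch_nm * 1e-3
  out <- array(NA_real_, c(h, w, 3))
  col <- floor(records$x_um / pitch_um) + 1
  row <- floor(records$y_um / pitch_um) + 1
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      sel <- which(row == r & col == c)
      if (length(sel)) {
        out[r, c, 1] <- mean(records$ch1[sel])
        out[r, c, 2] <- mean(records$ch2[sel])
        out[r, c, 3] <- mean(records$ch3[sel])
      }
    }
  }
  out
}

## Tile-anchor enumeration oracle.
anchors_brute <- function(dim, tile, stride) {
  if (dim <= tile) return(1L)
  a <- integer(0)
  k <- 1L
  while (k <= dim - tile + 1L) {
    a <- c(a, k)
    k <- k + stride
  }
  unique(c(a, dim - tile + 1L))
}
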