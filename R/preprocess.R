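## Intensity preprocessing of the three contrast channels into the
## colorizer's input representation: per-channel min-max normalization,
## percentile contrast stretching, and color reversal (bright raw signal
## becomes dark, matching the polarity of stained brightfield images).

#' Percentile contrast stretch
#'
#' Saturates the lowest `low_pct` percent and the highest `high_pct`
#' percent of all pixel values of the whole channel and rescales the
#' rest linearly to `[0, 1]`. Percentiles use the linear-interpolation
#' definition (`stats::quantile` type 7). A constant channel maps to all
#' zeros.
#'
#' @param channel nonempty numeric matrix (or vector).
#' @param low_pct,high_pct saturated tail sizes in percent; must satisfy
#'   `low_pct >= 0`, `high_pct >= 0`, `low_pct + high_pct < 100`.
#' @return Same shape as `channel`, values in `[0, 1]`.
#' @export
stretch_percentile <- function(channel, low_pct = 1, high_pct = 1) {
  if (length(channel) == 0) stopf("`channel` must be nonempty")
  if (low_pct < 0 || high_pct < 0 || low_pct + high_pct >= 100) {
    stopf("invalid percentile bounds: need low_pct, high_pct >= 0 and low_pct + high_pct < 100")
  }
  p <- quantile(channel, c(low_pct / 100, 1 - high_pct / 100),
                names = FALSE, type = 7)
  out <- if (p[2] == p[1]) {
    channel * 0
  } else {
    clip01((channel - p[1]) / (p[2] - p[1]))
  }
  out
}

#' Reverse channel polarity
#'
#' Maps `x` to `1 - x` so that strong absorption (bright raw signal)
#' appears dark, matching the colormap of stained brightfield images.
#'
#' @param channel numeric matrix with values in `[0, 1]`.
#' @return Same shape, `1 - channel`.
#' @export
color_reverse <- function(channel) {
  1 - channel
}

#' Prepare a contrast stack for colorization
#'
#' Applies, per channel and in order: min-max normalization, percentile
#' contrast stretch (default 1% tails), and color reversal. Channel
#' order is preserved as (non-radiative, radiative, scattering) and the
#' applied operations are recorded in a provenance log; feeding an
#' already-prepared stack back in warns.
#'
#' @param stack a [contrast_stack()] (or an already-prepared
#'   `normalized_stack`, which triggers a provenance warning).
#' @param low_pct,high_pct stretch tail sizes, percent.
#' @return An object of class `normalized_stack`: list with `channels`
#'   (`H x W x 3` in `[0, 1]`), `channel_order` and `provenance`.
#' @export
prepare_input <- function(stack, low_pct = 1, high_pct = 1) {
  prior <- character(0)
  if (inherits(stack, "normalized_stack")) {
    warnf("input already carries preprocessing provenance (%s); applying a second pass",
          paste(stack$provenance, collapse = " -> "))
    prior <- stack$provenance
    channels <- stack$channels
    pitch <- stack$pixel_pitch_nm
  } else if (inherits(stack, "contrast_stack")) {
    channels <- stack$channels
    pitch <- stack$pixel_pitch_nm
  } else {
    stopf("`stack` must be a contrast_stack (3 channels present)")
  }
  if (length(dim(channels)) != 3 || dim(channels)[3] != 3) {
    stopf("`stack` must have 3 channels")
  }
  out <- array(0, dim(channels))
  for (k in 1:3) {
    ch <- channels[, , k]
    rng <- range(ch)
    ch <- if (rng[2] > rng[1]) (ch - rng[1]) / (rng[2] - rng[1]) else ch * 0
    ch <- stretch_percentile(ch, low_pct, high_pct)
    out[, , k] <- color_reverse(ch)
  }
  ops <- c(prior, "minmax", sprintf("stretch(%g,%g)", low_pct, high_pct), "reverse")
  structure(
    list(channels = out,
         channel_order = c("non_radiative", "radiative", "scattering"),
         provenance = ops, pixel_pitch_nm = pitch),
    class = "normalized_stack"
  )
}

#' @export
print.normalized_stack <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<normalized_stack> %d x %d px, channels: %s; provenance: %s\n",
              d[1], d[2], paste(x$channel_order, collapse = ", "),
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}
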