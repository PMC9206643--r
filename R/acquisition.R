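## Cartesian image formation from per-pulse scan records. Each excitation
## pulse yields one record (stage position + per-channel signal feature);
## records are binned to the nearest pixel centre, multi-record pixels
## averaged, and empty pixels filled by nearest-neighbour propagation
## with a validity mask.

#' Compress a pulse trace to a single pixel feature
#'
#' Reduces a sampled per-pulse signal to the scalar that becomes the
#' pixel value. The default reducer is peak amplitude above baseline,
#' `max(trace) - median(trace)`, which is invariant to constant offsets
#' and nonnegative.
#'
#' @param trace nonempty numeric vector of signal samples.
#' @param reducer `"peak_above_baseline"` (default), `"max"`, or
#'   `"integral"` (mean of baseline-subtracted samples).
#' @return A single nonnegative number.
#' @export
pulse_feature <- function(trace,
                          reducer = c("peak_above_baseline", "max", "integral")) {
  reducer <- match.arg(reducer)
  if (length(trace) == 0 || !is.numeric(trace)) {
    stopf("`trace` must be a nonempty numeric vector")
  }
  switch(reducer,
    peak_above_baseline = max(trace) - median(trace),
    max = max(trace),
    integral = mean(pmax(trace - median(trace), 0))
  )
}

#' Reconstruct a contrast stack from a pulse stream
#'
#' Fits per-pulse pixel values to a Cartesian grid based on their stage
#' positions: each record is assigned to the nearest pixel centre,
#' multi-record pixels are averaged, and pixels with no record are
#' filled by iterative nearest-neighbour propagation and flagged
#' `FALSE` in the validity mask.
#'
#' @param records a data.frame with columns `x_um, y_um, ch1, ch2, ch3`
#'   (e.g. from [emit_scan_stream()] or [read_pulse_stream()]).
#' @param pitch_nm pixel pitch; defaults to the stream's
#'   `pixel_pitch_nm` attribute.
#' @param shape `c(height_px, width_px)` of the target grid; defaults to
#'   the stream's `shape` attribute.
#' @param origin_um grid origin; defaults to the stream's attribute or
#'   `c(0, 0)`.
#' @return A [contrast_stack()] whose `mask` flags measured (`TRUE`)
#'   versus interpolated (`FALSE`) pixels.
#' @export
reconstruct_grid <- function(records, pitch_nm = attr(records, "pixel_pitch_nm"),
                             shape = attr(records, "shape"),
                             origin_um = attr(records, "origin_um")) {
  if (is.null(pitch_nm) || is.null(shape)) {
    stopf("`pitch_nm` and `shape` are required (no attributes found on `records`)")
  }
  if (is.null(origin_um)) origin_um <- c(0, 0)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  pitch_um <- pitch_nm * 1e-3
  col <- floor((records$x_um - origin_um[1]) / pitch_um) + 1
  row <- floor((records$y_um - origin_um[2]) / pitch_um) + 1
  inside <- col >= 1 & col <= w & row >= 1 & row <= h
  if (!any(inside)) stopf("empty reconstruction: no record falls inside the extent")
  lin <- (col[inside] - 1) * h + row[inside]  # column-major linear index
  counts <- tabulate(lin, nbins = h * w)
  channels <- array(0, c(h, w, 3))
  for (k in 1:3) {
    vals <- records[[paste0("ch", k)]][inside]
    sums <- rep(0, h * w)
    agg <- rowsum(vals, group = lin)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    plane <- matrix(0, h, w)
    plane[counts > 0] <- sums[counts > 0] / counts[counts > 0]
    channels[, , k] <- plane
  }
  mask <- matrix(counts > 0, h, w)
  if (!all(mask)) channels <- fill_empty_pixels(channels, mask)
  contrast_stack(channels, pixel_pitch_nm = pitch_nm, origin_um = origin_um,
                 mask = mask)
}

## Iterative nearest-neighbour fill: at each pass every still-empty pixel
## with at least one filled 8-neighbour takes the mean of those
## neighbours, so values propagate outward ring by ring.
fill_empty_pixels <- function(channels, mask) {
  h <- dim(channels)[1]; w <- dim(channels)[2]
  filled <- mask
  while (!all(filled)) {
    num <- array(0, dim(channels))
    den <- matrix(0, h, w)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ys <- pmin(pmax(seq_len(h) + dy, 1), h)
      xs <- pmin(pmax(seq_len(w) + dx, 1), w)
      nb_ok <- filled[ys, xs, drop = FALSE]
      den <- den + nb_ok
      for (k in 1:3) {
        num[, , k] <- num[, , k] + channels[ys, xs, k] * nb_ok
      }
    }
    grow <- !filled & den > 0
    if (!any(grow)) break
    for (k in 1:3) {
      plane <- channels[, , k]
      plane[grow] <- (num[, , k] / pmax(den, 1))[grow]
      channels[, , k] <- plane
    }
    filled <- filled | grow
  }
  channels
}

#' Physical extent of a pixel grid
#'
#' @param width_px,height_px grid extent in pixels.
#' @param pitch_nm pixel pitch in nanometres.
#' @return List with `width_mm`, `height_mm`, `area_mm2`.
#' @export
physical_extent <- function(width_px, height_px, pitch_nm) {
  if (width_px <= 0 || height_px <= 0 || pitch_nm <= 0) {
    stopf("all arguments must be positive")
  }
  width_mm <- width_px * pitch_nm * 1e-6
  height_mm <- height_px * pitch_nm * 1e-6
  list(width_mm = width_mm, height_mm = height_mm,
       area_mm2 = width_mm * height_mm)
}
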