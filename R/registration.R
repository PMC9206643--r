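## Landmark-based co-registration of H&E images onto the photoacoustic
## frame. The photoacoustic stack is always the reference; the H&E image
## is the moving image. A fitted transform maps reference-frame pixel
## coordinates to moving-frame pixel coordinates, so warping is done by
## inverse mapping: each reference pixel samples the moving image at the
## transformed location.

#' Resample a moving image to the reference pixel pitch
#'
#' Coarse field-of-view matching: the moving (H&E) image is bilinearly
#' resampled so its pixel pitch equals the reference stack's pitch. This
#' precedes control-point registration so that the residual misalignment
#' is purely geometric.
#'
#' @param reference a [contrast_stack()] providing the target pitch.
#' @param moving a [stained_image()] to resample.
#' @return A [stained_image()] at the reference pitch.
#' @export
match_fov <- function(reference, moving) {
  if (is.null(reference$pixel_pitch_nm) || is.null(moving$pixel_pitch_nm)) {
    stopf("both images need `pixel_pitch_nm` metadata")
  }
  s <- moving$pixel_pitch_nm / reference$pixel_pitch_nm
  if (s == 1) return(moving)
  d <- dim(moving$rgb)
  new_h <- max(1L, as.integer(round(d[1] * s)))
  new_w <- max(1L, as.integer(round(d[2] * s)))
  stained_image(clip01(resize_bilinear(moving$rgb, new_h, new_w)),
                pixel_pitch_nm = reference$pixel_pitch_nm)
}

#' Refine landmark positions by local cross-correlation
#'
#' Each moving point is shifted to the offset within `search_px` that
#' maximizes the normalized cross-correlation (NCC) between a window
#' around the reference point and the shifted window in the moving
#' image. Ties are broken toward zero shift. Registration operates on a
#' single channel: in the intended pipeline this is the (preprocessed)
#' non-radiative channel against the H&E luminance, since all
#' photoacoustic channels are intrinsically co-registered.
#'
#' @param reference_channel single-channel matrix (reference frame).
#' @param moving single-channel matrix (moving frame).
#' @param landmarks a [landmark_set()].
#' @param window_px half-width of the correlation window in pixels.
#' @param search_px maximum absolute shift searched per axis, pixels.
#' @param subpixel if `TRUE` (default), the integer NCC peak is refined
#'   by per-axis parabolic interpolation of the correlation surface.
#' @return The refined [landmark_set()].
#' @export
refine_landmarks <- function(reference_channel, moving, landmarks,
                             window_px = 12, search_px = 5,
                             subpixel = TRUE) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (search_px == 0) return(landmarks)
  w <- as.integer(window_px)
  s <- as.integer(search_px)
  hr <- nrow(reference_channel); wr <- ncol(reference_channel)
  hm <- nrow(moving); wm <- ncol(moving)
  out <- landmarks
  flat <- 0L
  for (i in seq_len(nrow(landmarks))) {
    xr <- round(landmarks$x_ref[i]); yr <- round(landmarks$y_ref[i])
    xm <- round(landmarks$x_mov[i]); ym <- round(landmarks$y_mov[i])
    if (xr - w < 1 || xr + w > wr || yr - w < 1 || yr + w > hr ||
        xm - w - s < 1 || xm + w + s > wm || ym - w - s < 1 || ym + w + s > hm) {
      next  # window does not fit; leave the point unchanged
    }
    ref_win <- as.vector(reference_channel[(yr - w):(yr + w), (xr - w):(xr + w)])
    if (sd(ref_win) == 0) { flat <- flat + 1L; next }
    ncc <- matrix(-Inf, 2 * s + 1, 2 * s + 1)  # rows dy, cols dx
    for (dy in -s:s) for (dx in -s:s) {
      mov_win <- as.vector(
        moving[(ym + dy - w):(ym + dy + w), (xm + dx - w):(xm + dx + w)])
      ncc[dy + s + 1, dx + s + 1] <-
        if (sd(mov_win) == 0) -Inf else stats::cor(ref_win, mov_win)
    }
    if (!any(is.finite(ncc))) { flat <- flat + 1L; next }
    ## visit offsets nearest zero first and demand strict improvement,
    ## so exact ties resolve toward zero shift
    offs <- expand.grid(dy = -s:s, dx = -s:s)
    offs <- offs[order(offs$dx^2 + offs$dy^2), ]
    best <- -Inf; bdx <- 0L; bdy <- 0L
    for (k in seq_len(nrow(offs))) {
      v <- ncc[offs$dy[k] + s + 1, offs$dx[k] + s + 1]
      if (is.finite(v) && v > best) { best <- v; bdx <- offs$dx[k]; bdy <- offs$dy[k] }
    }
    ddx <- 0; ddy <- 0
    if (subpixel) {
      ddx <- parabolic_offset(ncc[bdy + s + 1, ], bdx + s + 1)
      ddy <- parabolic_offset(ncc[, bdx + s + 1], bdy + s + 1)
    }
    out$x_mov[i] <- landmarks$x_mov[i] + bdx + ddx
    out$y_mov[i] <- landmarks$y_mov[i] + bdy + ddy
  }
  if (flat > 0) {
    warnf("%d landmark window(s) had zero variance; left unchanged", flat)
  }
  out
}

## Sub-pixel peak localization: parabola through the NCC peak and its two
## neighbours along one axis; 0 when the peak is on the search border or
## the curvature vanishes.
parabolic_offset <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(0)
  c0 <- v[i]; cm <- v[i - 1]; cp <- v[i + 1]
  if (!all(is.finite(c(cm, c0, cp)))) return(0)
  den <- cm - 2 * c0 + cp
  if (abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
}

#' Fit a spatial transform through landmark pairs
#'
#' Fits a mapping from reference-frame to moving-frame coordinates. The
#' default non-rigid family is the thin-plate spline, which interpolates
#' the landmarks exactly and minimizes bending energy elsewhere; an
#' affine family (least squares) and the identity are also available.
#'
#' @param landmarks a [landmark_set()]; at least 3 non-collinear pairs
#'   for affine, at least 4 for the thin-plate spline.
#' @param family `"thin_plate_spline"` (default), `"affine"` or
#'   `"identity"`.
#' @param regularization nonnegative ridge term added to the spline
#'   kernel diagonal; 0 (default) gives exact interpolation.
#' @return An object of class `spatial_transform`.
#' @export
fit_transform <- function(landmarks,
                          family = c("thin_plate_spline", "affine", "identity"),
                          regularization = 0) {
  family <- match.arg(family)
  if (family == "identity") {
    return(structure(list(family = "identity"), class = "spatial_transform"))
  }
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- cbind(landmarks$x_ref, landmarks$y_ref)
  v <- cbind(landmarks$x_mov, landmarks$y_mov)
  dup <- duplicated(round(p, 9))
  if (any(dup)) {
    stopf("degenerate landmarks: duplicated reference points at rows %s",
          paste(which(dup), collapse = ", "))
  }
  n <- nrow(p)
  need <- if (family == "affine") 3L else 4L
  if (n < need) stopf("family '%s' needs at least %d landmark pairs", family, need)
  X <- cbind(1, p)
  if (qr(X)$rank < 3) {
    stopf("degenerate landmarks: reference points are collinear (rows %s)",
          paste(seq_len(n), collapse = ", "))
  }
  if (family == "affine") {
    coef <- qr.solve(X, v)  # 3 x 2: column k maps to output coordinate k
    return(structure(list(family = "affine", coef = coef),
                     class = "spatial_transform"))
  }
  ## thin-plate spline: solve [[K + rI, X], [X', 0]] [w; a] = [v; 0]
  K <- tps_kernel(p, p)
  L <- rbind(cbind(K + diag(regularization, n), X),
             cbind(t(X), matrix(0, 3, 3)))
  rhs <- rbind(v, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    stopf("thin-plate spline system is singular (%s); check landmarks for near-duplicates",
          conditionMessage(e))
  })
  structure(
    list(family = "thin_plate_spline", centers = p,
         weights = sol[seq_len(n), , drop = FALSE],
         affine = sol[n + 1:3, , drop = FALSE]),
    class = "spatial_transform"
  )
}

## U(r) = r^2 log r (with U(0) = 0), evaluated between all rows of a and b.
tps_kernel <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  k <- 0.5 * d2 * log(pmax(d2, .Machine$double.xmin))
  k[d2 == 0] <- 0
  k
}

#' Evaluate a spatial transform at points
#'
#' @param transform a `spatial_transform` from [fit_transform()].
#' @param xy n x 2 matrix of reference-frame pixel coordinates.
#' @return n x 2 matrix of moving-frame coordinates.
#' @export
transform_points <- function(transform, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  switch(transform$family,
    identity = xy,
    affine = cbind(1, xy) %*% transform$coef,
    thin_plate_spline = {
      U <- tps_kernel(xy, transform$centers)
      cbind(1, xy) %*% transform$affine + U %*% transform$weights
    },
    stopf("unknown transform family '%s'", transform$family)
  )
}

#' @export
print.spatial_transform <- function(x, ...) {
  n <- if (is.null(x$centers)) 0L else nrow(x$centers)
  cat(sprintf("<spatial_transform> family = %s%s\n", x$family,
              if (n) sprintf(" (%d centers)", n) else ""))
  invisible(x)
}

#' Warp a moving image onto the reference frame
#'
#' Inverse-mapping resample: every reference-frame pixel centre is mapped
#' through `transform` and the moving image is sampled there bilinearly.
#' Out-of-bounds samples are filled with white (the brightfield H&E
#' background) and flagged `FALSE` in the output mask.
#'
#' @param moving a [stained_image()] or a numeric matrix / `H x W x C`
#'   array.
#' @param transform a `spatial_transform` mapping reference coordinates
#'   to moving coordinates.
#' @param output_shape integer vector `c(height, width)` of the
#'   reference frame.
#' @param fill fill value for out-of-bounds samples (default 1, white).
#' @return Same type as `moving`; stained images carry a validity mask.
#' @export
warp_image <- function(moving, transform, output_shape, fill = 1) {
  is_stained <- inherits(moving, "stained_image")
  img <- if (is_stained) moving$rgb else moving
  h <- as.integer(output_shape[1]); w <- as.integer(output_shape[2])
  grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
  mapped <- transform_points(transform, grid)
  hm <- dim(img)[1]; wm <- dim(img)[2]
  inside <- mapped[, 1] >= 1 & mapped[, 1] <= wm &
    mapped[, 2] >= 1 & mapped[, 2] <= hm
  vals <- bilinear_sample(img, mapped[, 1], mapped[, 2], fill = fill)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  chans <- ncol(vals)
  out <- array(vals, c(h, w, chans))
  mask <- matrix(inside, h, w)
  if (is_stained) {
    stained_image(out, pixel_pitch_nm = moving$pixel_pitch_nm, mask = mask)
  } else if (length(dim(moving)) == 2) {
    out[, , 1]
  } else {
    out
  }
}

#' Propose landmarks on a textured grid
#'
#' Automated stand-in for interactive control-point picking: candidate
#' points on a regular grid are kept where the local standard deviation
#' of the reference channel exceeds a threshold, so correlation windows
#' have structure to lock onto. Moving coordinates are initialized equal
#' to the reference coordinates (appropriate after [match_fov()]).
#'
#' @param channel single-channel reference matrix.
#' @param spacing_px grid spacing in pixels; `NULL` (default) picks
#'   roughly an 8 x 8 grid, never denser than 16 px.
#' @param margin_px margin kept clear of the border (should cover the
#'   refinement window plus search radius).
#' @param min_sd minimum local standard deviation for a candidate.
#' @param window_px half-width of the variance window.
#' @return A [landmark_set()] with `mov == ref`.
#' @export
select_landmarks <- function(channel, spacing_px = NULL, margin_px = 20,
                             min_sd = 0.02, window_px = 8) {
  h <- nrow(channel); w <- ncol(channel)
  if (is.null(spacing_px)) {
    spacing_px <- max(16, round((min(h, w) - 2 * margin_px) / 7))
  }
  xs <- seq(margin_px + 1, w - margin_px, by = spacing_px)
  ys <- seq(margin_px + 1, h - margin_px, by = spacing_px)
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (y in ys) for (x in xs) {
    win <- channel[(y - window_px):(y + window_px),
                   (x - window_px):(x + window_px)]
    if (sd(as.vector(win)) >= min_sd) {
      keep_x <- c(keep_x, x); keep_y <- c(keep_y, y)
    }
  }
  if (length(keep_x) < 4) {
    stopf("fewer than 4 textured candidate points found; lower `min_sd` or `spacing_px`")
  }
  landmark_set(keep_x, keep_y, keep_x, keep_y)
}

#' Register a moving H&E image onto a reference stack
#'
#' Convenience composition of the registration stage: propose landmarks
#' on the reference non-radiative channel, refine them against the
#' moving image by normalized cross-correlation, fit a thin-plate
#' spline, and warp the moving image onto the reference frame.
#'
#' @param reference a [contrast_stack()].
#' @param moving a [stained_image()] at the reference pitch (apply
#'   [match_fov()] first if needed).
#' @param landmarks optional starting [landmark_set()]; defaults to
#'   [select_landmarks()] on the prepared non-radiative channel.
#' @param search_px,window_px NCC refinement parameters.
#' @param family transform family passed to [fit_transform()].
#' @return List with `warped` (a [stained_image()]), `transform`, and
#'   `landmarks` (refined).
#' @export
register_he <- function(reference, moving, landmarks = NULL,
                        search_px = 10, window_px = 12,
                        family = "thin_plate_spline") {
  ## correlate on matched polarity: prepared (color-reversed)
  ## non-radiative channel has dark nuclei, as does H&E luminance
  ref_chan <- prepare_input(reference)$channels[, , 1]
  mov_gray <- (moving$rgb[, , 1] + moving$rgb[, , 2] + moving$rgb[, , 3]) / 3
  if (is.null(landmarks)) {
    landmarks <- select_landmarks(ref_chan,
                                  margin_px = window_px + search_px + 2)
  }
  refined <- refine_landmarks(ref_chan, mov_gray, landmarks,
                              window_px = window_px, search_px = search_px)
  tf <- fit_transform(refined, family = family)
  warped <- warp_image(moving, tf, dim(ref_chan))
  list(warped = warped, transform = tf, landmarks = refined)
}
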