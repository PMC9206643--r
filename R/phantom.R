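## Synthetic tissue phantom: fully ground-truthed inputs with the
## statistical structure the pipeline assumes. Nuclei (ellipses) carry
## the nuclear concentration map c_n; fibers, cytoplasm texture and
## vessel blobs carry the extranuclear map c_e. The three contrast
## channels are linear mixtures with dominant/cross-talk coefficients,
## and the paired H&E render follows a Beer-Lambert stain model, so the
## mapping the colorizer must learn is known exactly.

#' Specify a synthetic tissue phantom
#'
#' @param height_px,width_px image extent in pixels (positive integers).
#' @param pixel_pitch_nm pixel pitch in nanometres (default 250, the
#'   acquisition pitch the pipeline targets).
#' @param nuclei_density expected nuclei per 100 x 100 px region.
#' @param nucleus_axes_px `c(mean, sd)` of the nucleus ellipse semi-axes
#'   in pixels.
#' @param fiber_count number of connective-tissue fibers.
#' @param fiber_thickness_px fiber stroke thickness in pixels.
#' @param vessel_count number of vessel blobs.
#' @param noise_sd per-channel additive noise standard deviations in
#'   `[0, 1]` (length 1 or 3; channel 3 noise acts as speckle).
#' @param warp_amplitude_px maximum landmark displacement of the
#'   misregistration warp applied to the moving H&E copy.
#' @param seed integer RNG seed; identical spec + seed gives
#'   bit-identical samples.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height_px = 512, width_px = 512,
                         pixel_pitch_nm = 250,
                         nuclei_density = 5,
                         nucleus_axes_px = c(6, 1.5),
                         fiber_count = 8, fiber_thickness_px = 3,
                         vessel_count = 2,
                         noise_sd = c(0.02, 0.02, 0.02),
                         warp_amplitude_px = 6,
                         seed = 1L) {
  if (!is_count(height_px) || !is_count(width_px)) {
    stopf("invalid phantom spec: image extents must be positive integers")
  }
  if (pixel_pitch_nm <= 0) stopf("invalid phantom spec: pixel pitch must be positive")
  if (nuclei_density < 0 || fiber_count < 0 || vessel_count < 0 ||
      warp_amplitude_px < 0 || any(noise_sd < 0)) {
    stopf("invalid phantom spec: densities, counts, noise and warp amplitude must be nonnegative")
  }
  if (fiber_thickness_px <= 0) stopf("invalid phantom spec: fiber thickness must be positive")
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 3)
  structure(
    list(height_px = as.integer(height_px), width_px = as.integer(width_px),
         pixel_pitch_nm = pixel_pitch_nm, nuclei_density = nuclei_density,
         nucleus_axes_px = nucleus_axes_px, fiber_count = as.integer(fiber_count),
         fiber_thickness_px = fiber_thickness_px,
         vessel_count = as.integer(vessel_count), noise_sd = noise_sd,
         warp_amplitude_px = warp_amplitude_px, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Draw one synthetic tissue phantom
#'
#' Generates the nuclear and extranuclear concentration maps, forms the
#' three contrast channels through a linear mixing model with 10%
#' cross-talk, renders the perfectly registered H&E ground truth,
#' derives a misregistered H&E copy through a known smooth warp, and
#' (optionally) emits the per-pulse scan stream.
#'
#' Channel model (before clipping to `[0, 1]`):
#' `non-radiative = 0.9 c_n + 0.09 c_e + noise`,
#' `radiative = 0.9 c_e + 0.09 c_n + noise`,
#' `scattering = smoothed(c_n + c_e) * (1 + speckle)`.
#'
#' @param spec a [phantom_spec()].
#' @param include_stream emit the pulse-record stream (default `TRUE`);
#'   disable for high-volume statistical replicates.
#' @return An object of class `phantom_sample`: a list with `contrast`
#'   ([contrast_stack()]), `he_true` and `he_moving` ([stained_image()]),
#'   `true_warp` (`spatial_transform`, reference to moving),
#'   `landmarks_true` ([landmark_set()]), `concentration_maps`
#'   (`list(c_n, c_e)`), `nuclei` (data.frame of placed ellipses) and
#'   `pulse_stream`.
#' @export
sample_phantom <- function(spec, include_stream = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height_px; w <- spec$width_px
  with_seed(spec$seed, {
    ## --- nuclear compartment: random ellipses ---
    n_nuc <- rpois(1, spec$nuclei_density * h * w / 1e4)
    nuclei <- data.frame(cx = runif(n_nuc, 1, w), cy = runif(n_nuc, 1, h),
                         a = pmax(1, rnorm(n_nuc, spec$nucleus_axes_px[1],
                                           spec$nucleus_axes_px[2])),
                         b = pmax(1, rnorm(n_nuc, spec$nucleus_axes_px[1],
                                           spec$nucleus_axes_px[2])),
                         theta = runif(n_nuc, 0, pi),
                         amp = runif(n_nuc, 0.7, 1))
    c_n <- matrix(0, h, w)
    for (i in seq_len(n_nuc)) {
      c_n <- paint_ellipse(c_n, nuclei$cx[i], nuclei$cy[i], nuclei$a[i],
                           nuclei$b[i], nuclei$theta[i], nuclei$amp[i])
    }
    ## --- extranuclear compartment: fibers + cytoplasm texture + vessels ---
    fibers <- matrix(0, h, w)
    for (i in seq_len(spec$fiber_count)) {
      fibers <- paint_fiber(fibers, spec$fiber_thickness_px)
    }
    texture <- blur_gaussian(matrix(runif(h * w), h, w), sigma = 3)
    texture <- texture - min(texture)
    if (max(texture) > 0) texture <- texture / max(texture)
    vessels <- matrix(0, h, w)
    for (i in seq_len(spec$vessel_count)) {
      vessels <- paint_ellipse(vessels, runif(1, 1, w), runif(1, 1, h),
                               runif(1, 12, 28), runif(1, 8, 18),
                               runif(1, 0, pi), 1)
    }
    if (spec$vessel_count > 0) vessels <- blur_gaussian(vessels, 1.5)
    c_e <- 0.55 * fibers + 0.25 * texture + 1.0 * vessels
    ## --- contrast channels: dominant + 10% cross-talk mixing ---
    ch1 <- 0.9 * c_n + 0.09 * c_e
    ch2 <- 0.9 * c_e + 0.09 * c_n
    ch3 <- blur_gaussian(c_n + c_e, 2)
    if (max(ch3) > 0) ch3 <- 0.85 * ch3 / max(ch3)
    if (spec$noise_sd[1] > 0) ch1 <- ch1 + rnorm(h * w, 0, spec$noise_sd[1])
    if (spec$noise_sd[2] > 0) ch2 <- ch2 + rnorm(h * w, 0, spec$noise_sd[2])
    if (spec$noise_sd[3] > 0) ch3 <- ch3 * (1 + rnorm(h * w, 0, spec$noise_sd[3]))
    channels <- array(c(clip01(ch1), clip01(ch2), clip01(ch3)), c(h, w, 3))
    contrast <- contrast_stack(channels, pixel_pitch_nm = spec$pixel_pitch_nm)
    he_true <- render_he(c_n, c_e, pixel_pitch_nm = spec$pixel_pitch_nm)
    mis <- apply_misregistration(he_true, spec$warp_amplitude_px,
                                 seed = spec$seed + 1L)
    stream <- if (include_stream) {
      emit_scan_stream(contrast, jitter_px = 0, seed = spec$seed + 2L)
    }
    structure(
      list(contrast = contrast, he_true = he_true, he_moving = mis$warped,
           true_warp = mis$transform, landmarks_true = mis$landmarks,
           concentration_maps = list(c_n = c_n, c_e = c_e),
           nuclei = nuclei, pulse_stream = stream, spec = spec),
      class = "phantom_sample"
    )
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf(
    "<phantom_sample> %d x %d px, %d nuclei, warp amplitude %g px, seed %d\n",
    x$spec$height_px, x$spec$width_px, nrow(x$nuclei),
    x$spec$warp_amplitude_px, x$spec$seed))
  invisible(x)
}

## Stamp a filled (possibly rotated) ellipse; existing values are kept
## where larger, so overlapping structures merge with max().
paint_ellipse <- function(m, cx, cy, a, b, theta, amp) {
  h <- nrow(m); w <- ncol(m)
  r <- max(a, b)
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(m)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (cos(theta) * dx + sin(theta) * dy) / a
  v <- (-sin(theta) * dx + cos(theta) * dy) / b
  inside <- u^2 + v^2 <= 1
  sub <- m[ys, xs, drop = FALSE]
  sub[inside] <- pmax(sub[inside], amp)
  m[ys, xs] <- sub
  m
}

## Smoothed random curve with a disc stamp: a direction random walk with
## small angular increments, drawn at the requested stroke thickness.
paint_fiber <- function(m, thickness) {
  h <- nrow(m); w <- ncol(m)
  n_steps <- round(0.7 * max(h, w))
  x <- runif(1, 1, w); y <- runif(1, 1, h)
  ang <- runif(1, 0, 2 * pi)
  dang <- rnorm(n_steps, 0, 0.12)
  rad <- max(1, thickness / 2)
  off <- expand.grid(dy = -ceiling(rad):ceiling(rad),
                     dx = -ceiling(rad):ceiling(rad))
  off <- off[off$dx^2 + off$dy^2 <= rad^2, ]
  amp <- runif(1, 0.6, 1)
  for (k in seq_len(n_steps)) {
    ang <- ang + dang[k]
    x <- x + cos(ang); y <- y + sin(ang)
    if (x < 1 || x > w || y < 1 || y > h) break
    px <- round(x) + off$dx; py <- round(y) + off$dy
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    idx <- cbind(py[ok], px[ok])
    m[idx] <- pmax(m[idx], amp)
  }
  m
}

#' Default H&E stain absorbance vectors
#'
#' Unit-normalized RGB optical-density directions for hematoxylin and
#' eosin, the standard values used in stain unmixing.
#'
#' @return 2 x 3 matrix, rows `hematoxylin` and `eosin`.
#' @export
default_stain_vectors <- function() {
  s <- rbind(hematoxylin = c(0.65, 0.70, 0.29),
             eosin = c(0.07, 0.99, 0.11))
  s / sqrt(rowSums(s^2))
}

#' Render an H&E image from concentration maps
#'
#' Beer-Lambert forward model of chemical staining: the per-pixel
#' optical density is `OD = c_n * S_h + c_e * S_e` and the brightfield
#' RGB transmission is `exp(-OD)`, giving values in `(0, 1]`.
#'
#' @param c_n,c_e nonnegative same-shape matrices: nuclear
#'   (hematoxylin-binding) and extranuclear (eosin-binding) stain
#'   concentrations.
#' @param stain_vectors 2 x 3 nonnegative matrix of RGB absorbance
#'   directions (rows: hematoxylin, eosin); see
#'   [default_stain_vectors()].
#' @param pixel_pitch_nm pitch metadata for the output.
#' @return A [stained_image()].
#' @export
render_he <- function(c_n, c_e, stain_vectors = default_stain_vectors(),
                      pixel_pitch_nm = 250) {
  if (!all(dim(c_n) == dim(c_e))) stopf("`c_n` and `c_e` must share shape")
  if (any(c_n < 0) || any(c_e < 0)) {
    stopf("concentration maps must be nonnegative")
  }
  if (any(stain_vectors < 0) || !all(dim(stain_vectors) == c(2, 3))) {
    stopf("`stain_vectors` must be a nonnegative 2 x 3 matrix")
  }
  h <- nrow(c_n); w <- ncol(c_n)
  rgb <- array(0, c(h, w, 3))
  for (k in 1:3) {
    rgb[, , k] <- exp(-(c_n * stain_vectors[1, k] + c_e * stain_vectors[2, k]))
  }
  stained_image(rgb, pixel_pitch_nm = pixel_pitch_nm)
}

#' Apply a known smooth misregistration warp
#'
#' Emulates the misalignment between separately acquired modalities that
#' registration must remove: a coarse control-point grid is perturbed by
#' random displacements of magnitude at most `warp_amplitude_px`
#' (border points stay fixed), a thin-plate spline through the perturbed
#' grid defines the true reference-to-moving transform, and the image is
#' resampled into the moving frame.
#'
#' @param image a [stained_image()].
#' @param warp_amplitude_px maximum control-point displacement, pixels.
#' @param seed integer RNG seed.
#' @param grid_n control points per axis (default 5).
#' @return List with `warped` (the moving-frame image), `transform` (the
#'   true reference-to-moving `spatial_transform`) and `landmarks` (the
#'   true [landmark_set()]).
#' @export
apply_misregistration <- function(image, warp_amplitude_px, seed = 1L,
                                  grid_n = 5) {
  stopifnot(inherits(image, "stained_image"), warp_amplitude_px >= 0)
  h <- dim(image$rgb)[1]; w <- dim(image$rgb)[2]
  gx <- seq(1, w, length.out = grid_n)
  gy <- seq(1, h, length.out = grid_n)
  grid <- expand.grid(x = gx, y = gy)
  if (warp_amplitude_px == 0) {
    return(list(warped = image,
                transform = fit_transform(NULL, family = "identity"),
                landmarks = landmark_set(grid$x, grid$y, grid$x, grid$y)))
  }
  with_seed(seed, {
    interior <- grid$x > min(gx) & grid$x < max(gx) &
      grid$y > min(gy) & grid$y < max(gy)
    n_int <- sum(interior)
    rad <- warp_amplitude_px * sqrt(runif(n_int))
    ang <- runif(n_int, 0, 2 * pi)
    dx <- dy <- rep(0, nrow(grid))
    dx[interior] <- rad * cos(ang)
    dy[interior] <- rad * sin(ang)
    lm_fwd <- landmark_set(grid$x, grid$y, grid$x + dx, grid$y + dy)
    fwd <- fit_transform(lm_fwd, family = "thin_plate_spline")
    ## approximate inverse: spline through the swapped pairs
    inv <- fit_transform(landmark_set(grid$x + dx, grid$y + dy, grid$x, grid$y),
                         family = "thin_plate_spline")
    warped <- warp_image(image, inv, c(h, w))
    list(warped = warped, transform = fwd, landmarks = lm_fwd)
  })
}

#' Emit a per-pulse scan stream from a contrast stack
#'
#' Produces one pulse record per pixel in raster order (row by row, left
#' to right), with stage positions at the pixel centres plus optional
#' uniform jitter, and per-channel features equal to the pixel values --
#' the inverse of grid reconstruction.
#'
#' @param contrast a [contrast_stack()].
#' @param jitter_px half-width of uniform positional jitter, pixels.
#' @param seed RNG seed (used only when `jitter_px > 0`).
#' @return A data.frame of class `pulse_stream` with columns
#'   `x_um, y_um, ch1, ch2, ch3`, carrying `pixel_pitch_nm`, `shape` and
#'   `origin_um` attributes.
#' @export
emit_scan_stream <- function(contrast, jitter_px = 0, seed = 1L) {
  stopifnot(inherits(contrast, "contrast_stack"), jitter_px >= 0)
  ch <- contrast$channels
  h <- dim(ch)[1]; w <- dim(ch)[2]
  pitch_um <- contrast$pixel_pitch_nm * 1e-3
  cols <- rep(seq_len(w), times = h)   # raster order: row-major
  rows <- rep(seq_len(h), each = w)
  x <- contrast$origin_um[1] + (cols - 0.5) * pitch_um
  y <- contrast$origin_um[2] + (rows - 0.5) * pitch_um
  if (jitter_px > 0) {
    with_seed(seed, {
      x <- x + runif(length(x), -jitter_px, jitter_px) * pitch_um
      y <- y + runif(length(y), -jitter_px, jitter_px) * pitch_um
    })
  }
  idx <- cbind(rows, cols)
  out <- data.frame(x_um = x, y_um = y,
                    ch1 = ch[, , 1][idx], ch2 = ch[, , 2][idx],
                    ch3 = ch[, , 3][idx])
  structure(out, class = c("pulse_stream", "data.frame"),
            pixel_pitch_nm = contrast$pixel_pitch_nm,
            shape = c(h, w), origin_um = contrast$origin_um)
}
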