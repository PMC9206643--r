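## S3 containers for the pipeline's domain objects.

#' Construct a three-channel contrast stack
#'
#' A contrast stack holds the three intrinsically co-registered
#' photoacoustic channels -- non-radiative absorption, radiative
#' absorption and optical scattering -- on a common Cartesian grid.
#'
#' @param channels `H x W x 3` numeric array with values in `[0, 1]`
#'   (channel order: non-radiative, radiative, scattering).
#' @param pixel_pitch_nm positive pixel pitch in nanometres.
#' @param origin_um physical position of the grid origin, micrometres.
#' @param mask optional logical `H x W` validity matrix; `FALSE` marks
#'   pixels filled by interpolation rather than measured.
#' @return An object of class `contrast_stack`.
#' @export
contrast_stack <- function(channels, pixel_pitch_nm = 250,
                           origin_um = c(0, 0), mask = NULL) {
  channels <- as.array(channels)
  if (length(dim(channels)) != 3 || dim(channels)[3] != 3) {
    stopf("`channels` must be an H x W x 3 array")
  }
  if (!is.numeric(pixel_pitch_nm) || length(pixel_pitch_nm) != 1 ||
      !is.finite(pixel_pitch_nm) || pixel_pitch_nm <= 0) {
    stopf("`pixel_pitch_nm` must be a positive number")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(channels)[1], dim(channels)[2])
  structure(
    list(channels = channels, pixel_pitch_nm = pixel_pitch_nm,
         origin_um = as.numeric(origin_um), mask = mask),
    class = "contrast_stack"
  )
}

#' @export
print.contrast_stack <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf(
    "<contrast_stack> %d x %d px, 3 channels (non-radiative, radiative, scattering), pitch %g nm\n",
    d[1], d[2], x$pixel_pitch_nm))
  invisible(x)
}

#' Construct an RGB stained image
#'
#' Container for a brightfield-style H&E image, real or virtual.
#'
#' @param rgb `H x W x 3` numeric array, values in `[0, 1]`.
#' @param pixel_pitch_nm positive pixel pitch in nanometres.
#' @param mask optional logical `H x W` validity matrix (`FALSE` marks
#'   out-of-bounds fill after warping).
#' @return An object of class `stained_image`.
#' @export
stained_image <- function(rgb, pixel_pitch_nm = 250, mask = NULL) {
  rgb <- as.array(rgb)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stopf("`rgb` must be an H x W x 3 array")
  }
  if (pixel_pitch_nm <= 0) stopf("`pixel_pitch_nm` must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, dim(rgb)[1], dim(rgb)[2])
  structure(list(rgb = rgb, pixel_pitch_nm = pixel_pitch_nm, mask = mask),
            class = "stained_image")
}

#' @export
print.stained_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<stained_image> %d x %d px RGB, pitch %g nm\n",
              d[1], d[2], x$pixel_pitch_nm))
  invisible(x)
}

#' Construct a landmark set
#'
#' Paired control points between a reference frame and a moving frame, in
#' 1-based pixel coordinates of their respective images.
#'
#' @param x_ref,y_ref,x_mov,y_mov numeric vectors of equal length.
#' @return An object of class `landmark_set` (also a data.frame with
#'   columns `x_ref, y_ref, x_mov, y_mov`).
#' @export
landmark_set <- function(x_ref, y_ref, x_mov, y_mov) {
  n <- length(x_ref)
  if (any(lengths(list(y_ref, x_mov, y_mov)) != n)) {
    stopf("landmark coordinate vectors must have equal length")
  }
  if (!all(is.finite(c(x_ref, y_ref, x_mov, y_mov)))) {
    stopf("landmark coordinates must be finite")
  }
  structure(
    data.frame(x_ref = x_ref, y_ref = y_ref, x_mov = x_mov, y_mov = y_mov),
    class = c("landmark_set", "data.frame")
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d control-point pairs\n", nrow(x)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("... %d more\n", nrow(x) - 6))
  invisible(x)
}
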