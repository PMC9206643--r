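## File interfaces: contrast stacks as multi-page 16-bit TIFF with a
## YAML sidecar (pitch, origin, validity mask), H&E renders as 8-bit RGB
## TIFF, landmarks and pulse streams as headered CSV, transforms and
## specs as YAML.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write / read a contrast stack
#'
#' The three channels are stored as pages of a 16-bit TIFF; pitch,
#' origin and (when any pixel is interpolated) the validity mask are
#' stored in a YAML sidecar next to the image.
#'
#' @param stack a [contrast_stack()].
#' @param path output TIFF path.
#' @return `write_contrast_stack` returns `path` invisibly;
#'   `read_contrast_stack` returns a [contrast_stack()].
#' @export
write_contrast_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contrast_stack"))
  pages <- lapply(1:3, function(k) clip01(stack$channels[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(pixel_pitch_nm = stack$pixel_pitch_nm,
               origin_um = as.list(stack$origin_um))
  if (!all(stack$mask)) {
    meta$mask_false <- as.list(which(!stack$mask))  # column-major indices
  }
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_contrast_stack
#' @export
read_contrast_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(sidecar_path(path))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  channels <- array(0, c(h, w, 3))
  for (k in 1:3) channels[, , k] <- pages[[k]]
  mask <- matrix(TRUE, h, w)
  if (!is.null(meta$mask_false)) mask[unlist(meta$mask_false)] <- FALSE
  contrast_stack(channels, pixel_pitch_nm = meta$pixel_pitch_nm,
                 origin_um = unlist(meta$origin_um), mask = mask)
}

#' Write / read a stained image
#'
#' 8-bit RGB TIFF plus a YAML sidecar with the pixel pitch.
#'
#' @param image a [stained_image()].
#' @param path output TIFF path.
#' @return `write_stained_image` returns `path` invisibly;
#'   `read_stained_image` returns a [stained_image()].
#' @export
write_stained_image <- function(image, path) {
  stopifnot(inherits(image, "stained_image"))
  tiff::writeTIFF(clip01(image$rgb), path, bits.per.sample = 8)
  yaml::write_yaml(list(pixel_pitch_nm = image$pixel_pitch_nm), sidecar_path(path))
  invisible(path)
}

#' @rdname write_stained_image
#' @export
read_stained_image <- function(path) {
  rgb <- tiff::readTIFF(path)
  meta <- if (file.exists(sidecar_path(path))) yaml::read_yaml(sidecar_path(path))
  stained_image(rgb, pixel_pitch_nm = meta$pixel_pitch_nm %||% 250)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read landmarks as CSV
#'
#' Headered CSV with columns `x_ref, y_ref, x_mov, y_mov`.
#'
#' @param landmarks a [landmark_set()].
#' @param path CSV path.
#' @return The path (write, invisibly) or a [landmark_set()] (read).
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(as.data.frame(unclass(landmarks)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  d <- read.csv(path)
  landmark_set(d$x_ref, d$y_ref, d$x_mov, d$y_mov)
}

#' Write / read a pulse stream as CSV
#'
#' Headered CSV `x_um, y_um, ch1, ch2, ch3`; grid metadata (pitch,
#' shape, origin) goes to a YAML sidecar so the stream alone suffices
#' for reconstruction.
#'
#' @param stream a `pulse_stream` from [emit_scan_stream()].
#' @param path CSV path.
#' @return The path (write, invisibly) or a `pulse_stream` (read).
#' @export
write_pulse_stream <- function(stream, path) {
  write.csv(as.data.frame(unclass(stream))[, c("x_um", "y_um", "ch1", "ch2", "ch3")],
            path, row.names = FALSE)
  yaml::write_yaml(list(pixel_pitch_nm = attr(stream, "pixel_pitch_nm"),
                        shape = as.list(attr(stream, "shape")),
                        origin_um = as.list(attr(stream, "origin_um"))),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_pulse_stream
#' @export
read_pulse_stream <- function(path) {
  d <- read.csv(path)
  meta <- if (file.exists(sidecar_path(path))) yaml::read_yaml(sidecar_path(path))
  structure(d, class = c("pulse_stream", "data.frame"),
            pixel_pitch_nm = meta$pixel_pitch_nm,
            shape = unlist(meta$shape), origin_um = unlist(meta$origin_um))
}

#' Serialize a spatial transform to YAML
#'
#' @param transform a `spatial_transform`.
#' @param path YAML path.
#' @return The path (write, invisibly) or a `spatial_transform` (read).
#' @export
write_transform <- function(transform, path) {
  obj <- list(family = transform$family)
  if (transform$family == "affine") obj$coef <- as.list(as.vector(transform$coef))
  if (transform$family == "thin_plate_spline") {
    obj$centers <- as.list(as.vector(transform$centers))
    obj$weights <- as.list(as.vector(transform$weights))
    obj$affine <- as.list(as.vector(transform$affine))
    obj$n <- nrow(transform$centers)
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- yaml::read_yaml(path)
  tf <- switch(obj$family,
    identity = list(family = "identity"),
    affine = list(family = "affine",
                  coef = matrix(unlist(obj$coef), 3, 2)),
    thin_plate_spline = list(
      family = "thin_plate_spline",
      centers = matrix(unlist(obj$centers), obj$n, 2),
      weights = matrix(unlist(obj$weights), obj$n, 2),
      affine = matrix(unlist(obj$affine), 3, 2)),
    stopf("unknown transform family in %s", path))
  structure(tf, class = "spatial_transform")
}
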