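#' Calibrated single-channel image stack
#'
#' A `frame_stack` is the in-memory representation of one fluorescence channel
#' of a time-lapse recording: a numeric `D1 x D2 x T` array (rows `y`, columns
#' `x`, frames `t`, all 1-based) carrying its channel label and spatial /
#' temporal calibration. All downstream geometry (ROI sides, sliding-window
#' sizes, structuring-element radii) is specified in micrometres or hours and
#' converted through the calibration; nothing is ever inferred from image
#' content.
#'
#' @param pixels Numeric array with `dim = c(D1, D2, T)` (a matrix is accepted
#'   as a single frame). Intensities must be finite and non-negative.
#' @param channel Channel label, one of `"red"`, `"green"`, `"transmission"`.
#' @param calibration A [calibration()] object.
#' @return A `frame_stack` object.
#' @examples
#' fs <- frame_stack(array(0, dim = c(16, 16, 3)), "red")
#' dim(fs)
#' @export
frame_stack <- function(pixels, channel = c("red", "green", "transmission"),
                        calibration = apoptomap::calibration()) {
  channel <- match.arg(channel)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    abort("`pixels` must be a D1 x D2 x T array.", class = "apoptomap_format_error")
  if (any(dim(pixels) < 1L))
    abort("All stack dimensions must be >= 1.", class = "apoptomap_format_error")
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0))
    abort("Stack intensities must be finite and non-negative.",
          class = "apoptomap_format_error")
  stopifnot(inherits(calibration, "apoptomap_calibration"))
  structure(pixels,
            channel = channel, calibration = calibration,
            class = c("frame_stack", "array"))
}

#' Spatial and temporal calibration
#'
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param frame_interval_h Hours per frame (> 0). The default matches hourly
#'   acquisition, the sampling rate the whole analysis is designed around.
#' @return A `apoptomap_calibration` object (a named list).
#' @export
calibration <- function(pixel_size_um = 0.645, frame_interval_h = 1) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    abort("`pixel_size_um` must be a single positive number.",
          class = "apoptomap_config_error")
  if (!is.numeric(frame_interval_h) || length(frame_interval_h) != 1L ||
      frame_interval_h <= 0)
    abort("`frame_interval_h` must be a single positive number.",
          class = "apoptomap_config_error")
  structure(list(pixel_size_um = pixel_size_um, frame_interval_h = frame_interval_h),
            class = "apoptomap_calibration")
}

#' @export
print.apoptomap_calibration <- function(x, ...) {
  cat(sprintf("<calibration: %.4g um/px, %.4g h/frame>\n",
              x$pixel_size_um, x$frame_interval_h))
  invisible(x)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cal <- stack_calibration(x)
  cat(sprintf("<frame_stack: %s channel, %d x %d px, %d frame%s, %.4g um/px, %.4g h/frame>\n",
              stack_channel(x), d[1], d[2], d[3], if (d[3] == 1) "" else "s",
              cal$pixel_size_um, cal$frame_interval_h))
  invisible(x)
}

#' Accessors for frame_stack metadata
#' @param x A `frame_stack`.
#' @return `stack_channel()` the channel label; `stack_calibration()` the
#'   [calibration()]; `n_frames()` the number of frames.
#' @export
stack_channel <- function(x) attr(x, "channel")

#' @rdname stack_channel
#' @export
stack_calibration <- function(x) attr(x, "calibration")

#' @rdname stack_channel
#' @export
n_frames <- function(x) dim(x)[3L]

#' Extract one frame as a plain matrix
#' @param x A `frame_stack`.
#' @param t Frame index (1-based).
#' @export
get_frame <- function(x, t) {
  stopifnot(t >= 1L, t <= dim(x)[3L])
  x[, , t, drop = TRUE]
}

# unit conversions -------------------------------------------------------

#' Convert physical units to pixels / frames through a calibration
#'
#' @param um Length in micrometres.
#' @param hours Duration in hours.
#' @param cal A [calibration()].
#' @return `um_to_px()` a length in pixels (not rounded); `hours_to_frames()`
#'   a whole number of frames (rounded, at least 1).
#' @export
um_to_px <- function(um, cal) um / cal$pixel_size_um

#' @rdname um_to_px
#' @export
hours_to_frames <- function(hours, cal) max(1L, as.integer(round(hours / cal$frame_interval_h)))

#' @rdname um_to_px
#' @export
frames_to_hours <- function(frames, cal) frames * cal$frame_interval_h
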