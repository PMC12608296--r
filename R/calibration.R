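#' Camera calibration for a monitored room
#'
#' Keypoints and bounding boxes arrive in pixel coordinates; converting
#' displacements to physical speeds and distances needs the video frame rate
#' and a pixel-to-meter scale. The inter-frame interval is derived as
#' `1 / frame_rate`.
#'
#' @param frame_rate Frames per second of the source video. Must be > 0.
#' @param scale Meters per pixel. Must be > 0. The scale is a required
#'   per-room calibration input; it is never estimated from the stream.
#'
#' @return An object of class `calibration`: a list with `frame_rate`,
#'   `scale` and `dt` (seconds between frames).
#' @examples
#' calib <- calibration(frame_rate = 30, scale = 0.01)
#' calib$dt # 1/30 s
#' @export
calibration <- function(frame_rate, scale) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    abort("`frame_rate` must be a single positive number.")
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("`scale` must be a single positive number (meters per pixel).")
  }
  structure(
    list(frame_rate = frame_rate, scale = scale, dt = 1 / frame_rate),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> %.6g fps, %.6g m/px (dt = %.6g s)\n",
    x$frame_rate, x$scale, x$dt
  ))
  invisible(x)
}
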