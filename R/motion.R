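#' Per-keypoint displacement between two frames
#'
#' Euclidean pixel displacement of each keypoint between a frame and its
#' successor. A keypoint that is invisible at either endpoint yields `NA`
#' rather than a silent zero.
#'
#' @param kpts_t,kpts_t1 Keypoint matrices for the same person at frames
#'   `t` and `t + 1`: numeric matrices with columns `x`, `y` and optionally
#'   `vis` (nonzero = visible; all visible when absent). Both must have the
#'   same number of rows.
#'
#' @return Numeric vector of pixel displacements, one per keypoint, `NA`
#'   where either endpoint is invisible.
#' @examples
#' a <- cbind(x = c(0, 1), y = c(0, 1))
#' b <- cbind(x = c(3, 1), y = c(4, 1))
#' keypoint_displacement(a, b) # 5, 0
#' @export
keypoint_displacement <- function(kpts_t, kpts_t1) {
  kpts_t <- as_kpt_matrix(kpts_t)
  kpts_t1 <- as_kpt_matrix(kpts_t1)
  if (nrow(kpts_t) != nrow(kpts_t1)) {
    abort("Keypoint counts differ between the two frames.")
  }
  d <- sqrt((kpts_t1[, 1] - kpts_t[, 1])^2 + (kpts_t1[, 2] - kpts_t[, 2])^2)
  d[kpts_t[, 3] == 0 | kpts_t1[, 3] == 0] <- NA_real_
  unname(d)
}

as_kpt_matrix <- function(k) {
  k <- as.matrix(k)
  if (!is.numeric(k) || ncol(k) < 2) {
    abort("Keypoints must be a numeric matrix with columns x, y[, vis].")
  }
  if (ncol(k) == 2) k <- cbind(k, 1)
  k[, 1:3, drop = FALSE]
}

#' Full-body motion speed from a window of keypoint frames
#'
#' Per-keypoint speed is `scale * frame_rate * displacement` (pixel
#' displacement between consecutive frames converted to meters per second).
#' The body speed aggregates per-keypoint speeds over visible keypoints —
#' arithmetic mean by default, median as a jitter-robust option — and then
#' averages across the frame pairs of the window.
#'
#' @param kpt_x,kpt_y Numeric matrices, one row per frame (ordered, a single
#'   person) and one column per keypoint.
#' @param calib A [calibration()] object.
#' @param kpt_vis Optional visibility matrix of the same shape (nonzero =
#'   visible). Defaults to all visible.
#' @param aggregate `"mean"` (default) or `"median"` across visible
#'   keypoints.
#'
#' @return A single non-negative speed in m/s, or `NA` if no frame pair has
#'   any visible keypoint (an explicit undefined-speed signal, never a
#'   silent zero).
#' @examples
#' calib <- calibration(30, 0.01)
#' x <- rbind(rep(0, 4), rep(5, 4)) # every keypoint shifts 5 px
#' y <- rbind(rep(0, 4), rep(0, 4))
#' body_speed(x, y, calib) # 0.01 * 30 * 5 = 1.5 m/s
#' @export
body_speed <- function(kpt_x, kpt_y, calib, kpt_vis = NULL,
                       aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  kpt_x <- as.matrix(kpt_x)
  kpt_y <- as.matrix(kpt_y)
  if (!identical(dim(kpt_x), dim(kpt_y))) {
    abort("`kpt_x` and `kpt_y` must have identical dimensions.")
  }
  if (nrow(kpt_x) < 2) abort("The window must contain at least 2 frames.")
  if (is.null(kpt_vis)) kpt_vis <- matrix(1, nrow(kpt_x), ncol(kpt_x))
  kpt_vis <- as.matrix(kpt_vis)

  n <- nrow(kpt_x)
  dx <- kpt_x[-1, , drop = FALSE] - kpt_x[-n, , drop = FALSE]
  dy <- kpt_y[-1, , drop = FALSE] - kpt_y[-n, , drop = FALSE]
  disp <- sqrt(dx^2 + dy^2)
  vis_pair <- (kpt_vis[-1, , drop = FALSE] != 0) & (kpt_vis[-n, , drop = FALSE] != 0)
  disp[!vis_pair] <- NA_real_

  speed <- calib$scale * calib$frame_rate * disp
  agg_fun <- if (aggregate == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  }
  per_pair <- apply(speed, 1, function(v) {
    if (all(is.na(v))) NA_real_ else agg_fun(v)
  })
  if (all(is.na(per_pair))) {
    warn("All keypoints missing in every frame pair; speed is undefined.")
    return(NA_real_)
  }
  mean(per_pair, na.rm = TRUE)
}

#' Bounding-box centroid
#'
#' The center of a box given as `(xmin, ymin, xmax, ymax)`:
#' `((xmin + xmax)/2, (ymin + ymax)/2)`.
#'
#' @param bbox A numeric vector of length 4, or a 4-column matrix /
#'   data frame (one box per row), ordered `xmin, ymin, xmax, ymax`.
#'
#' @return For a single box, a named numeric vector `c(xc, yc)`; for
#'   several, a two-column matrix.
#' @examples
#' bbox_centroid(c(0, 0, 4, 2)) # (2, 1)
#' @export
bbox_centroid <- function(bbox) {
  m <- if (is.null(dim(bbox))) matrix(as.numeric(bbox), nrow = 1) else as.matrix(bbox)
  if (ncol(m) != 4) abort("A bounding box has 4 coordinates: xmin, ymin, xmax, ymax.")
  if (any(m[, 1] > m[, 3]) || any(m[, 2] > m[, 4])) {
    abort("Invalid bounding box: requires xmin <= xmax and ymin <= ymax.")
  }
  out <- cbind(xc = (m[, 1] + m[, 3]) / 2, yc = (m[, 2] + m[, 4]) / 2)
  if (is.null(dim(bbox))) out[1, ] else out
}

#' Inter-person distance from bounding boxes, in meters
#'
#' Euclidean distance between the two box centroids in pixel space,
#' converted to meters with the calibration scale. Distances always leave
#' this module in meters so that suppression thresholds (which are physical)
#' compare like with like.
#'
#' @param bbox_a,bbox_b Boxes as in [bbox_centroid()]; vectorized when
#'   given matrices with matching row counts.
#' @param calib A [calibration()] object.
#'
#' @return Distance(s) in meters; zero iff the centroids coincide.
#' @examples
#' calib <- calibration(30, 0.01)
#' interperson_distance(c(0, 0, 2, 2), c(3, 5, 5, 7), calib) # 0.01 * sqrt(34)
#' @export
interperson_distance <- function(bbox_a, bbox_b, calib) {
  ca <- bbox_centroid(bbox_a)
  cb <- bbox_centroid(bbox_b)
  if (is.null(dim(ca))) ca <- matrix(ca, nrow = 1)
  if (is.null(dim(cb))) cb <- matrix(cb, nrow = 1)
  d_px <- sqrt((cb[, 1] - ca[, 1])^2 + (cb[, 2] - ca[, 2])^2)
  unname(d_px * calib$scale)
}
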