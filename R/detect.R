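#' Detect abnormal (pre-fall) behaviour events in a keypoint stream
#'
#' For each resident, the vertical hip-joint trajectory is scored by
#' one-step-ahead forecast residuals (default: rolling least-squares linear
#' extrapolation), thresholded at `tau_A` (default `k` x MAD of the
#' resident's own residuals, with a floor), and flagged frames are grouped
#' into events. Sudden stand-up attempts produce large residuals because
#' the torso jumps off its recent linear trend.
#'
#' Flagged frames closer than `merge_gap_s` seconds are clustered into one
#' event, and a cluster only becomes an event when it contains at least
#' `persist_s` seconds' worth of flagged frames — a persistence (debounce)
#' filter that discards isolated jitter spikes. An event is labelled
#' `"stand_up_attempt"` when the upper body (hips and shoulders) rises —
#' image y decreases — at a rate of at least `standup_frac` body-box
#' heights per second during the cluster; otherwise `"other"`. Nurses are
#' never flagged.
#'
#' @param frames A keypoint stream: tibble with columns `frame`, `ts`,
#'   `person_id`, `role`, `xmin`, `ymin`, `xmax`, `ymax` and matrix columns
#'   `kpt_x`, `kpt_y`, `kpt_vis` (one column per keypoint).
#' @param calib A [calibration()] object.
#' @param window Forecast window length in frames (default 10).
#' @param k MAD multiplier for the adaptive threshold (default 3).
#' @param tau Absolute threshold override in pixels; `NULL` (default) uses
#'   [tau_mad()].
#' @param tau_floor Threshold floor in pixels (default 0.5).
#' @param persist_s Minimum flagged duration for an event, seconds.
#' @param merge_gap_s Maximum gap between flagged frames of one event.
#' @param standup_frac Upward-motion rate (body-box heights per second)
#'   above which an event is a stand-up attempt.
#' @param flag_window_s Look-back horizon for counting a resident's recent
#'   flags (feeds the urgency score).
#' @param aggregate Keypoint aggregation for [body_speed()].
#'
#' @return A tibble of events: `event_id`, `person_id`, `ordinal` (per
#'   resident), `ts`, `frame`, `score`, `tau`, `label`, `n_flagged`,
#'   `speed` (m/s), `accel` (m/s^2), `recent_flags`. Zero rows when nothing
#'   is abnormal.
#' @export
detect_events <- function(frames, calib, window = 10, k = 3, tau = NULL,
                          tau_floor = 0.5, persist_s = 0.6, merge_gap_s = 6,
                          standup_frac = 0.2, flag_window_s = 300,
                          aggregate = "mean") {
  stopifnot(is.data.frame(frames))
  skel <- skeleton_layout()
  persist_frames <- max(1L, as.integer(round(persist_s * calib$frame_rate)))
  residents <- sort(unique(frames$person_id[frames$role == "resident"]))

  out <- purrr::map(residents, function(pid) {
    sub <- frames[frames$person_id == pid, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    n <- nrow(sub)
    if (n <= window) return(NULL)
    hip_y <- rowMeans(sub$kpt_y[, skel$hips, drop = FALSE])
    scores <- abs(rolling_residuals(hip_y, window))
    tau_i <- tau %||% tau_mad(scores, k = k, floor = tau_floor)
    flag_idx <- which(!is.na(scores) & scores > tau_i)
    if (!length(flag_idx)) return(NULL)

    gaps <- diff(sub$ts[flag_idx])
    cluster_id <- cumsum(c(1, as.integer(gaps > merge_gap_s)))
    clusters <- split(flag_idx, cluster_id)
    clusters <- clusters[vapply(clusters, length, 1L) >= persist_frames]
    if (!length(clusters)) return(NULL)

    evs <- purrr::map(clusters, function(idx) {
      i0 <- min(idx)
      i1 <- max(idx)
      span <- i0:i1
      # peak upward (rising) torso rate over any ~1 s stretch of the cluster
      # (image y decreases as the body rises); context starts one window
      # before the first flag so the onset of the rise is included, and the
      # body-box height is taken at cluster start, before any excursion
      # inflates it
      w_f <- max(1L, as.integer(round(calib$frame_rate)))
      ctx <- max(1L, i0 - w_f):i1
      torso_y <- rowMeans(sub$kpt_y[ctx, c(skel$hips, skel$shoulders), drop = FALSE])
      w_f <- min(w_f, length(ctx) - 1L)
      drops <- torso_y[seq_len(length(ctx) - w_f)] -
        torso_y[seq_len(length(ctx) - w_f) + w_f]
      box_h <- sub$ymax[ctx[1]] - sub$ymin[ctx[1]]
      rate <- if (length(drops)) max(0, drops) / (w_f * calib$dt) else 0
      label <- if (box_h > 0 && rate >= standup_frac * box_h) {
        "stand_up_attempt"
      } else {
        "other"
      }
      # body speed over the onset window, and its change from the window before
      w0 <- max(1L, i0 - 1L)
      w1 <- min(n, i0 + persist_frames)
      v <- body_speed(
        sub$kpt_x[w0:w1, , drop = FALSE], sub$kpt_y[w0:w1, , drop = FALSE],
        calib,
        kpt_vis = sub$kpt_vis[w0:w1, , drop = FALSE], aggregate = aggregate
      )
      span_len <- w1 - w0
      p0 <- max(1L, w0 - span_len)
      acc <- 0
      if (p0 < w0) {
        v_prev <- body_speed(
          sub$kpt_x[p0:w0, , drop = FALSE], sub$kpt_y[p0:w0, , drop = FALSE],
          calib,
          kpt_vis = sub$kpt_vis[p0:w0, , drop = FALSE], aggregate = aggregate
        )
        dt_w <- sub$ts[w1] - sub$ts[w0]
        if (is.finite(v) && is.finite(v_prev) && dt_w > 0) acc <- (v - v_prev) / dt_w
      }
      tibble::tibble(
        person_id = pid,
        ts = sub$ts[i0],
        frame = sub$frame[i0],
        score = max(scores[idx]),
        tau = tau_i,
        label = label,
        n_flagged = length(idx),
        speed = ifelse(is.finite(v), v, 0),
        accel = acc
      )
    })
    dplyr::bind_rows(evs)
  })
  events <- dplyr::bind_rows(out)
  if (!nrow(events)) {
    return(tibble::tibble(
      event_id = character(), person_id = character(), ordinal = integer(),
      ts = numeric(), frame = integer(), score = numeric(), tau = numeric(),
      label = character(), n_flagged = integer(), speed = numeric(),
      accel = numeric(), recent_flags = integer()
    ))
  }
  events <- events[order(events$ts, events$person_id), , drop = FALSE]
  events <- events |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(
      ordinal = dplyr::row_number(),
      recent_flags = vapply(seq_along(.data$ts), function(i) {
        sum(.data$ts >= .data$ts[i] - flag_window_s & .data$ts < .data$ts[i])
      }, integer(1))
    ) |>
    dplyr::ungroup()
  events$event_id <- sprintf("%s-e%03d", events$person_id, events$ordinal)
  events[, c(
    "event_id", "person_id", "ordinal", "ts", "frame", "score", "tau",
    "label", "n_flagged", "speed", "accel", "recent_flags"
  )]
}
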