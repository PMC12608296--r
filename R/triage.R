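#' Maximum reachable distance threshold
#'
#' A nurse can avert a stand-up-related fall only by arriving before the
#' resident is up. With `stand_up_time` the typical time a resident needs
#' to rise and `reach_window` the tolerated response slack (default 1 s),
#' the acceptable reaching time is `stand_up_time - reach_window` and the
#' maximum reachable distance is that time multiplied by the nurse walking
#' speed.
#'
#' @param stand_up_time Typical elderly stand-up duration, seconds.
#' @param nurse_speed Nurse walking speed, m/s (>= 0).
#' @param reach_window Response slack, seconds (default 1).
#'
#' @return `theta_x` in meters. When `stand_up_time <= reach_window`
#'   nothing is reachable: returns 0 with a warning.
#' @examples
#' reachable_threshold(3, 1.2) # (3 - 1) * 1.2 = 2.4 m
#' @export
reachable_threshold <- function(stand_up_time, nurse_speed, reach_window = 1) {
  if (nurse_speed < 0) abort("`nurse_speed` must be >= 0.")
  if (reach_window <= 0) abort("`reach_window` must be > 0.")
  if (stand_up_time <= reach_window) {
    warn("`stand_up_time` does not exceed the reach window; no alarm is reachable (theta_x = 0).")
    return(0)
  }
  (stand_up_time - reach_window) * nurse_speed
}

#' Suppression thresholds
#'
#' Bundles the rule-based suppression parameters: the maximum reachable
#' distance `theta_x` (computed from stand-up time, nurse speed and the
#' reach window when not given directly) and the minimum urgency `theta_u`.
#'
#' @param theta_x Maximum reachable distance, meters; `NULL` derives it via
#'   [reachable_threshold()].
#' @param theta_u Minimum urgency in \[0, 1\] (default 0.2).
#' @param reach_window,stand_up_time,nurse_speed See
#'   [reachable_threshold()].
#'
#' @return A list of class `suppression_thresholds`.
#' @export
suppression_thresholds <- function(theta_x = NULL, theta_u = 0.2,
                                   reach_window = 1, stand_up_time = 3,
                                   nurse_speed = 1.2) {
  if (theta_u < 0 || theta_u > 1) abort("`theta_u` must lie in [0, 1].")
  if (is.null(theta_x)) {
    theta_x <- reachable_threshold(stand_up_time, nurse_speed, reach_window)
  }
  if (theta_x < 0) abort("`theta_x` must be >= 0.")
  structure(
    list(
      theta_x = theta_x, theta_u = theta_u, reach_window = reach_window,
      stand_up_time = stand_up_time, nurse_speed = nurse_speed
    ),
    class = "suppression_thresholds"
  )
}

#' Rule-based alarm suppression
#'
#' First decision gate: an alarm is discarded when (in clause order)
#' * `too_far` — the nearest available nurse is beyond `theta_x` (no one
#'   can reach in time; the minimum over available nurses is the
#'   safety-first scalar reduction of the per-nurse distance map);
#' * `not_urgent` — urgency is strictly below `theta_u`;
#' * `low_priority` — the resident's clinical class is `"low"` (fully
#'   dependent, with a stationed attendant; the alarm is non-actionable).
#'
#' Kept alarms proceed to the delay and validation gates; discarded alarms
#' belong in the shadow log.
#'
#' @param alarms Alarm tibble from [assemble_alarms()] (needs
#'   `min_dist_avail`, `urgency`, `priority_class`).
#' @param thresholds A [suppression_thresholds()] object.
#'
#' @return `alarms` with logical `keep` and character `reason`
#'   (`"too_far"`, `"not_urgent"`, `"low_priority"` or `"none"`) columns.
#' @export
suppress_alarms <- function(alarms, thresholds) {
  stopifnot(inherits(thresholds, "suppression_thresholds"))
  reason <- dplyr::case_when(
    alarms$min_dist_avail > thresholds$theta_x ~ "too_far",
    alarms$urgency < thresholds$theta_u ~ "not_urgent",
    alarms$priority_class == "low" ~ "low_priority",
    .default = "none"
  )
  dplyr::mutate(alarms, keep = reason == "none", reason = reason)
}

#' Delay weighting parameters
#'
#' Weights of the personalized-delay combination: urgency complement,
#' ward workload, and clinical-class delay. Defaults (0.5, 0.25, 0.25)
#' follow domain judgment: urgency dominates the timing decision.
#'
#' @param a1,a2,a3 Weights in \[0, 1\] summing to 1.
#' @return A named numeric vector of class `delay_weights`.
#' @export
delay_weights <- function(a1 = 0.5, a2 = 0.25, a3 = 0.25) {
  w <- c(a1 = a1, a2 = a2, a3 = a3)
  check_simplex(w, "delay weights (alpha)")
  structure(w, class = c("delay_weights", "numeric"))
}

#' Personalized notification delay
#'
#' `D = a1 * (1 - urgency) + a2 * workload + a3 * care_delay(class)`, a
#' unitless value in \[0, 1\]. The clinical-class delay term encodes that
#' mid-priority (independent) residents tolerate a longer deferral than
#' high-priority ones: `high -> 0`, `mid -> 1`. Low-priority alarms never
#' reach this gate (suppressed upstream); they are also assigned 1.
#' Multiply by a configured `delay_scale` to obtain seconds.
#'
#' @param urgency Urgency in \[0, 1\] (vectorized).
#' @param workload Ward workload fraction in \[0, 1\].
#' @param priority_class `"high"`, `"mid"` or `"low"`.
#' @param weights A [delay_weights()] vector.
#'
#' @return Delay value(s) in \[0, 1\].
#' @examples
#' compute_delay(0.4, 0.5, "mid") # 0.5*0.6 + 0.25*0.5 + 0.25*1 = 0.675
#' @export
compute_delay <- function(urgency, workload, priority_class,
                          weights = delay_weights()) {
  care_delay <- c(high = 0, mid = 1, low = 1)[priority_class]
  unname(
    weights[["a1"]] * (1 - urgency) + weights[["a2"]] * workload +
      weights[["a3"]] * care_delay
  )
}

#' Delay gate
#'
#' An alarm whose scheduled delay (in seconds) strictly exceeds the
#' acknowledgment horizon `t_ack` would arrive too late to act on and is
#' discarded; a delay exactly at the horizon is kept.
#'
#' @param delay Unitless delay from [compute_delay()] (vectorized).
#' @param t_ack Acknowledgment horizon, seconds (default 30).
#' @param delay_scale Seconds per unit delay (default 10).
#'
#' @return Logical vector: `TRUE` = keep.
#' @export
delay_gate <- function(delay, t_ack = 30, delay_scale = 10) {
  if (any(delay < 0)) abort("`delay` must be >= 0.")
  delay * delay_scale <= t_ack
}
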