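#' Urgency weighting parameters
#'
#' Weights for the four urgency terms — squashed velocity, squashed
#' acceleration, risky-activity indicator, and recent-flag count. The
#' defaults follow domain judgment: frequent recent anomalies weigh most
#' (0.35), then activity category (0.25), with velocity and acceleration
#' equally weighted (0.2 each). The weights must lie in \[0, 1\] and sum
#' to 1 so that the urgency score stays in \[0, 1\].
#'
#' @param g1,g2,g3,g4 Weights for velocity, acceleration, activity and
#'   flag count respectively.
#' @return A named numeric vector of class `urgency_weights`.
#' @export
urgency_weights <- function(g1 = 0.2, g2 = 0.2, g3 = 0.25, g4 = 0.35) {
  w <- c(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
  check_simplex(w, "urgency weights (gamma)")
  structure(w, class = c("urgency_weights", "numeric"))
}

check_simplex <- function(w, what) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    abort(sprintf("Each of the %s must lie in [0, 1].", what))
  }
  if (abs(sum(w) - 1) > 1e-8) {
    abort(sprintf("The %s must sum to 1 (got %.6g).", what, sum(w)))
  }
  invisible(w)
}

#' Urgency score of an alarm
#'
#' Weighted combination of motion and history terms, each squashed into
#' \[0, 1\]:
#' `u = g1 * s(v) + g2 * s(a) + g3 * 1[activity risky] + g4 * sf(flags)`,
#' clamped to \[0, 1\]. Velocity and acceleration are squashed against
#' per-resident baselines, `s(v) = v / (v + v_baseline)` (bounded and
#' parameter-free; acceleration uses its magnitude); the flag count is
#' normalized as `min(flags, flag_cap) / flag_cap`.
#'
#' @param speed Body speed in m/s (vectorized).
#' @param accel Body acceleration in m/s^2; its magnitude is used.
#' @param activity Activity label(s); membership of `risky` drives the
#'   indicator term.
#' @param flag_count Number of recent abnormal-behaviour flags (>= 0).
#' @param weights An [urgency_weights()] vector.
#' @param v_baseline,a_baseline Per-resident (or global) squashing
#'   baselines, m/s and m/s^2.
#' @param flag_cap Saturation point of the flag-count term.
#' @param risky Character vector of risky activity labels.
#'
#' @return Urgency value(s) in \[0, 1\].
#' @examples
#' # saturated inputs with risky activity reach exactly 1
#' urgency_score(1e9, 1e9, "stand_up_attempt", 99)
#' @export
urgency_score <- function(speed, accel, activity, flag_count,
                          weights = urgency_weights(),
                          v_baseline = 0.1, a_baseline = 0.5, flag_cap = 3,
                          risky = c("stand_up_attempt", "unstable_posture")) {
  if (any(flag_count < 0)) abort("`flag_count` must be non-negative.")
  sv <- squash_ratio(pmax(speed, 0), v_baseline)
  sa <- squash_ratio(abs(accel), a_baseline)
  sf <- pmin(flag_count, flag_cap) / flag_cap
  ind <- as.numeric(activity %in% risky)
  u <- weights[["g1"]] * sv + weights[["g2"]] * sa + weights[["g3"]] * ind +
    weights[["g4"]] * sf
  pmin(pmax(u, 0), 1)
}

squash_ratio <- function(x, baseline) {
  ifelse(x + baseline > 0, x / (x + baseline), 0)
}

#' Clinical priority class of a resident
#'
#' Maps the care level (CL, 1 = autonomous .. 5 = dependent) and the
#' per-activity assistance levels (AL, 1 = independent .. 5 = full
#' assistance, over meals, bath, excretion, movement, dress-up) to an alert
#' priority class:
#' * `"low"` — fully dependent residents (CL 4–5 with aggregated AL = 5):
#'   an attendant is stationed beside them, so alerts are non-actionable;
#' * `"mid"` — fully independent residents (CL = 1 and aggregated AL = 1);
#' * `"high"` — everyone in the intermediate band.
#'
#' The five AL scores are aggregated by maximum (worst-case dependency) by
#' default; `"mean"` is available.
#'
#' @param care_level Integer(s) in 1..5.
#' @param assistance A numeric vector of 5 AL scores, or a matrix/data
#'   frame with 5 columns (one row per resident), each score in 1..5.
#' @param al_aggregate `"max"` (default) or `"mean"`.
#'
#' @return Character vector of `"high"`, `"mid"`, `"low"`.
#' @examples
#' clinical_priority(1, rep(1, 5)) # "mid"
#' clinical_priority(5, rep(5, 5)) # "low"
#' clinical_priority(3, c(4, 3, 2, 1, 1)) # "high"
#' @export
clinical_priority <- function(care_level, assistance,
                              al_aggregate = c("max", "mean")) {
  al_aggregate <- match.arg(al_aggregate)
  if (is.null(dim(assistance))) {
    assistance <- matrix(as.numeric(assistance), nrow = 1)
  } else {
    assistance <- as.matrix(assistance)
  }
  if (ncol(assistance) != 5) {
    abort("`assistance` needs 5 activity scores: meals, bath, excretion, movement, dress-up.")
  }
  if (any(!(care_level %in% 1:5)) || any(!(assistance %in% 1:5))) {
    abort("Care and assistance levels must be integers in 1..5.")
  }
  al <- if (al_aggregate == "max") {
    apply(assistance, 1, max)
  } else {
    rowMeans(assistance)
  }
  dplyr::case_when(
    care_level %in% c(4, 5) & al == 5 ~ "low",
    care_level == 1 & al == 1 ~ "mid",
    .default = "high"
  )
}

#' Ward-level nurse workload fraction
#'
#' The fraction of on-duty nurses currently engaged in a task:
#' `sum(busy) / n`, in \[0, 1\].
#'
#' @param nurses A nurse roster tibble with a logical (or 0/1) `busy`
#'   column; one row per on-duty nurse.
#'
#' @return A single value in \[0, 1\].
#' @export
nurse_workload <- function(nurses) {
  if (!is.data.frame(nurses) || !nrow(nurses)) {
    abort("The roster must contain at least one on-duty nurse.")
  }
  if (!"busy" %in% names(nurses)) abort("The roster needs a `busy` column.")
  mean(as.numeric(nurses$busy))
}

#' Assemble alarm candidates from detected events
#'
#' Builds the five-part alarm context for every detected event: temporal
#' (event timestamp), spatial (per-nurse centroid distances in meters at
#' the event frame), urgency (weighted motion/history score), clinical
#' (resident priority class), and resource (ward workload fraction). The
#' concatenation of the five parts is kept as a `feature` list-column.
#'
#' @param events Event tibble from [detect_events()].
#' @param residents Resident roster: `resident_id`, `care_level`,
#'   `al_meals`, `al_bath`, `al_excretion`, `al_movement`, `al_dressup`,
#'   optional `baseline_speed`.
#' @param nurses Nurse roster: `nurse_id`, `busy`, optional
#'   `workload_index`.
#' @param frames Keypoint stream (needed for nurse positions at event
#'   time).
#' @param calib A [calibration()] object.
#' @param weights An [urgency_weights()] vector.
#' @param v_baseline,a_baseline,flag_cap,risky Urgency squashing
#'   parameters; a resident's `baseline_speed` overrides `v_baseline`.
#' @param al_aggregate Passed to [clinical_priority()].
#'
#' @return An alarm tibble: `alarm_id`, `ts`, `frame`, `resident_id`,
#'   `label`, `urgency`, `priority_class`, `workload`, `distances`
#'   (list-column of named per-nurse distances, meters), `min_dist` and
#'   `min_dist_avail` (minimum over all / over non-busy nurses),
#'   `nearest_nurse`, `nearest_avail`, `score`, `recent_flags`, `feature`.
#' @export
assemble_alarms <- function(events, residents, nurses, frames, calib,
                            weights = urgency_weights(),
                            v_baseline = 0.1, a_baseline = 0.5, flag_cap = 3,
                            risky = c("stand_up_attempt", "unstable_posture"),
                            al_aggregate = "max") {
  if (!is.data.frame(nurses) || !nrow(nurses)) {
    abort("The nurse roster must be non-empty.")
  }
  unknown <- setdiff(events$person_id, residents$resident_id)
  if (length(unknown)) {
    abort(sprintf("Events reference unknown residents: %s", toString(unknown)))
  }
  if (!nrow(events)) {
    return(empty_alarms())
  }
  al_cols <- c("al_meals", "al_bath", "al_excretion", "al_movement", "al_dressup")
  prof <- residents[match(events$person_id, residents$resident_id), , drop = FALSE]
  prio <- clinical_priority(prof$care_level, prof[, al_cols], al_aggregate = al_aggregate)
  vb <- if ("baseline_speed" %in% names(prof)) {
    ifelse(is.na(prof$baseline_speed), v_baseline, prof$baseline_speed)
  } else {
    rep(v_baseline, nrow(prof))
  }
  u <- urgency_score(events$speed, events$accel, events$label,
    events$recent_flags,
    weights = weights, v_baseline = vb,
    a_baseline = a_baseline, flag_cap = flag_cap, risky = risky
  )
  r <- nurse_workload(nurses)
  avail <- nurse_available(nurses)

  nurse_frames <- frames[frames$role == "nurse", , drop = FALSE]
  dist_maps <- purrr::map2(events$frame, events$person_id, function(fr, pid) {
    nurse_distances(frames, nurse_frames, fr, pid, nurses$nurse_id, calib)
  })
  min_all <- vapply(dist_maps, function(d) suppressWarnings(min(d)), numeric(1))
  min_av <- vapply(dist_maps, function(d) {
    d <- d[avail]
    if (!length(d) || all(!is.finite(d))) Inf else min(d, na.rm = TRUE)
  }, numeric(1))
  nearest <- vapply(dist_maps, function(d) names(d)[which.min(d)[1]], character(1))
  nearest_av <- vapply(dist_maps, function(d) {
    d <- d[avail]
    if (!length(d) || all(!is.finite(d))) NA_character_ else names(d)[which.min(d)[1]]
  }, character(1))

  tibble::tibble(
    alarm_id = events$event_id,
    ts = events$ts,
    frame = events$frame,
    resident_id = events$person_id,
    ordinal = events$ordinal,
    label = events$label,
    urgency = u,
    priority_class = prio,
    workload = r,
    distances = dist_maps,
    min_dist = min_all,
    min_dist_avail = min_av,
    nearest_nurse = nearest,
    nearest_avail = nearest_av,
    score = events$score,
    recent_flags = events$recent_flags,
    feature = purrr::pmap(
      list(events$ts, dist_maps, u, prio, r),
      function(t, x, uu, cc, rr) c(t = t, x, u = uu, c = c(high = 1, mid = 0.5, low = 0)[[cc]], r = rr)
    )
  )
}

empty_alarms <- function() {
  tibble::tibble(
    alarm_id = character(), ts = numeric(), frame = integer(),
    resident_id = character(), ordinal = integer(), label = character(),
    urgency = numeric(), priority_class = character(), workload = numeric(),
    distances = list(), min_dist = numeric(), min_dist_avail = numeric(),
    nearest_nurse = character(), nearest_avail = character(),
    score = numeric(), recent_flags = integer(), feature = list()
  )
}

# Named per-nurse distances (meters) between a resident and every nurse at
# (or nearest before) a given frame.
nurse_distances <- function(frames, nurse_frames, fr, pid, nurse_ids, calib) {
  me <- frames[frames$person_id == pid & frames$frame == fr, , drop = FALSE]
  if (!nrow(me)) abort(sprintf("No frame %s for resident %s.", fr, pid))
  my_box <- c(me$xmin[1], me$ymin[1], me$xmax[1], me$ymax[1])
  d <- vapply(nurse_ids, function(nid) {
    nf <- nurse_frames[nurse_frames$person_id == nid & nurse_frames$frame <= fr, , drop = FALSE]
    if (!nrow(nf)) return(NA_real_)
    nf <- nf[which.max(nf$frame), , drop = FALSE]
    interperson_distance(my_box, c(nf$xmin, nf$ymin, nf$xmax, nf$ymax), calib)
  }, numeric(1))
  setNames(d, nurse_ids)
}

# Availability for assignment: an explicit `available` column when present
# (a stationed attendant is busy by duty yet can respond to an adjacent
# alarm), otherwise the complement of the task flag.
nurse_available <- function(nurses) {
  if ("available" %in% names(nurses)) as.logical(nurses$available) else !as.logical(nurses$busy)
}
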