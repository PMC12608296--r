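# Shared fixtures: everything is built in code at test time.

calib30 <- calibration(frame_rate = 30, scale = 0.01)

# keypoint matrix from coordinate vectors
kpts <- function(x, y, vis = NULL) {
  if (is.null(vis)) vis <- rep(1, length(x))
  cbind(x = x, y = y, vis = vis)
}

# a compact ward scenario that still exercises every code path
small_scenario <- function(minutes = 5, noise = 2, ...) {
  scenario_config(session_minutes = c(minutes, minutes), noise_sigma = noise, ...)
}

# minimal nurse roster
mk_nurses <- function(n = 2, busy = FALSE, available = TRUE, p_ack = 1) {
  tibble::tibble(
    nurse_id = sprintf("nurse%d", seq_len(n)),
    busy = rep_len(busy, n),
    available = rep_len(available, n),
    workload_index = 0L,
    p_ack = rep_len(p_ack, n)
  )
}

# minimal resident roster
mk_residents <- function(ids, care_level, al) {
  out <- tibble::tibble(resident_id = ids, care_level = care_level)
  for (col in c("al_meals", "al_bath", "al_excretion", "al_movement", "al_dressup")) {
    out[[col]] <- al
  }
  out$baseline_speed <- 0.1
  out
}

# a single synthetic alarm row with explicit context values
mk_alarm <- function(urgency = 0.5, priority_class = "high", workload = 0,
                     min_dist_avail = 1, distances = c(nurse1 = 1, nurse2 = 2),
                     ts = 0, resident_id = "res01", ordinal = 1L,
                     label = "stand_up_attempt") {
  d_min <- min(distances)
  d_near <- names(distances)[which.min(distances)]
  tibble::tibble(
    alarm_id = paste0(resident_id, "-e001"), ts = ts, frame = 1L,
    resident_id = resident_id, ordinal = ordinal, label = label,
    urgency = urgency, priority_class = priority_class, workload = workload,
    distances = list(distances), min_dist = d_min,
    min_dist_avail = min_dist_avail,
    nearest_nurse = d_near, nearest_avail = d_near,
    score = 10, recent_flags = 0L, feature = list(numeric())
  )
}
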