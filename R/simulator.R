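#' Scenario configuration for the ward simulator
#'
#' Describes a simulated lunchtime monitoring session: room geometry,
#' resident mix by care tier, nurse staffing, stand-up event rates, video
#' calibration, keypoint noise and the acknowledgment model. Defaults
#' emulate the reference facility setting: 28 residents (6 high-, 8
#' medium-, 14 low-care) across 3 dining rooms, 4 nurses of whom 2 are
#' stationed beside the fully dependent residents, sessions of 30–60 min.
#'
#' @param n_rooms Number of rooms (default 3).
#' @param tiers Residents per care tier, named `high`, `medium`, `low`.
#' @param n_nurses Number of on-duty nurses (default 4).
#' @param n_stationed Nurses permanently stationed beside high-tier
#'   residents (default 2); must not exceed `n_nurses`.
#' @param session_minutes Length-2 range the session duration is drawn
#'   from, minutes (default 30–60).
#' @param frame_rate Frames per second (default 5).
#' @param scale Meters per pixel (default 0.01).
#' @param event_rate Stand-up attempts per resident-hour by tier, named
#'   `high`, `medium`, `low` (defaults 2, 6, 10: mobile low-care residents
#'   attempt to stand far more often than immobile high-care residents).
#' @param noise_sigma Keypoint jitter standard deviation, pixels.
#' @param p_ack Per-notification acknowledgment probability.
#' @param ack_latency_mean Mean acknowledgment latency, seconds
#'   (exponential, truncated at the acknowledgment horizon).
#' @param nurse_speed Roaming nurse walking speed, m/s.
#' @param room_w_m,room_h_m,room_gap_m Room width/height and inter-room
#'   corridor gap, meters.
#' @param rise_m,rise_s,hold_s,return_s Stand-up excursion shape: torso
#'   rise in meters, rise time, hold time and sit-back time in seconds.
#' @param min_event_gap_s Minimum spacing between one resident's events.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_rooms = 3,
                            tiers = c(high = 6, medium = 8, low = 14),
                            n_nurses = 4, n_stationed = 2,
                            session_minutes = c(30, 60),
                            frame_rate = 5, scale = 0.01,
                            event_rate = c(high = 2, medium = 6, low = 10),
                            noise_sigma = 2, p_ack = 0.9,
                            ack_latency_mean = 5, nurse_speed = 1.2,
                            room_w_m = 8, room_h_m = 6, room_gap_m = 2,
                            rise_m = 0.35, rise_s = 0.4, hold_s = 2,
                            return_s = 1, min_event_gap_s = 30) {
  if (n_stationed > n_nurses) {
    abort("Infeasible scenario: more stationed nurses than nurses on duty.")
  }
  if (any(tiers < 0) || n_rooms < 1 || n_nurses < 1) {
    abort("Counts must be non-negative (and at least one room and nurse).")
  }
  if (!all(c("high", "medium", "low") %in% names(tiers))) {
    abort("`tiers` must name high, medium and low counts.")
  }
  if (length(session_minutes) == 1) session_minutes <- rep(session_minutes, 2)
  if (noise_sigma < 0 || p_ack < 0 || p_ack > 1) {
    abort("`noise_sigma` must be >= 0 and `p_ack` in [0, 1].")
  }
  structure(
    list(
      n_rooms = n_rooms, tiers = tiers, n_nurses = n_nurses,
      n_stationed = n_stationed, session_minutes = session_minutes,
      frame_rate = frame_rate, scale = scale, event_rate = event_rate,
      noise_sigma = noise_sigma, p_ack = p_ack,
      ack_latency_mean = ack_latency_mean, nurse_speed = nurse_speed,
      room_w_m = room_w_m, room_h_m = room_h_m, room_gap_m = room_gap_m,
      rise_m = rise_m, rise_s = rise_s, hold_s = hold_s,
      return_s = return_s, min_event_gap_s = min_event_gap_s
    ),
    class = "scenario_config"
  )
}

# 17-point stick-figure templates (pixel offsets from the hip midpoint,
# image y grows downward). Deliberately schematic: just enough articulation
# to drive vertical-excursion detection and bounding boxes.
skeleton_template <- function(posture = c("seated", "standing")) {
  posture <- match.arg(posture)
  leg_drop <- if (posture == "seated") c(25, 50) else c(35, 70)
  x <- c(0, -4, 4, -8, 8, -15, 15, -20, 20, -22, 22, -10, 10, -12, 12, -13, 13)
  y <- c(-65, -68, -68, -66, -66, -50, -50, -30, -30, -12, -12, 0, 0,
         leg_drop[1], leg_drop[1], leg_drop[2], leg_drop[2])
  cbind(x = x, y = y)
}

#' Simulate a monitored ward session
#'
#' Generates a seeded synthetic session: per-frame keypoint streams for
#' every resident and nurse, resident care profiles, nurse trajectories
#' (stationed nurses fixed beside high-tier residents, the rest walking
#' piecewise-constant-velocity waypoint paths), scripted stand-up
#' excursions as ground-truth events, and Gaussian keypoint jitter.
#' Everything is reproducible from `(config, seed)`; bounding boxes derive
#' from the noiseless skeleton so jitter models joint-estimation noise
#' only.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed fixing all randomness.
#'
#' @return A `ward_session` list: `frames` (keypoint stream tibble with
#'   matrix columns `kpt_x`, `kpt_y`, `kpt_vis`), `residents`, `nurses`,
#'   `truth` (injected events with per-resident `ordinal`), `calib`,
#'   `config`, `seed`, `duration_s`.
#' @export
simulate_ward <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  px <- function(m) m / config$scale
  f <- config$frame_rate
  duration_s <- 60 * runif(1, config$session_minutes[1], config$session_minutes[2])
  n_frames <- as.integer(floor(duration_s * f))
  ts <- (seq_len(n_frames) - 1) / f
  room_w <- px(config$room_w_m)
  room_h <- px(config$room_h_m)
  room_x0 <- (seq_len(config$n_rooms) - 1) * (room_w + px(config$room_gap_m))

  residents <- build_residents(config)
  residents$x <- room_x0[residents$room] +
    room_w * runif(nrow(residents), 0.15, 0.85)
  residents$y <- room_h * runif(nrow(residents), 0.2, 0.8)

  nurses <- build_nurses(config, residents)
  nurse_paths <- purrr::map(seq_len(nrow(nurses)), function(i) {
    if (nurses$stationed[i]) {
      # fixed beside an assigned high-tier resident
      cbind(x = rep(nurses$x0[i], n_frames), y = rep(nurses$y0[i], n_frames))
    } else {
      waypoint_path(
        n_frames, f, px(config$nurse_speed),
        xr = room_x0[nurses$room[i]] + room_w * c(0.1, 0.9),
        yr = room_h * c(0.1, 0.9)
      )
    }
  })

  truth <- inject_events(config, residents, duration_s)
  excursion_s <- config$rise_s + config$hold_s + config$return_s

  seated <- skeleton_template("seated")
  standing <- skeleton_template("standing")
  rise_px <- px(config$rise_m)
  skel <- skeleton_layout()

  person_frames <- vector("list", nrow(residents) + nrow(nurses))
  for (i in seq_len(nrow(residents))) {
    rid <- residents$resident_id[i]
    rise <- numeric(n_frames)
    evs <- truth[truth$resident_id == rid, , drop = FALSE]
    for (t0 in evs$ts) {
      rel <- ts - t0
      r <- rep(0, n_frames)
      r[rel >= 0 & rel < config$rise_s] <-
        rel[rel >= 0 & rel < config$rise_s] / config$rise_s
      r[rel >= config$rise_s & rel < config$rise_s + config$hold_s] <- 1
      idx <- rel >= config$rise_s + config$hold_s & rel < excursion_s
      r[idx] <- 1 - (rel[idx] - config$rise_s - config$hold_s) / config$return_s
      rise <- pmax(rise, r)
    }
    person_frames[[i]] <- person_stream(
      rid, "resident", seated, residents$x[i], residents$y[i],
      rise * rise_px, skel$upper, n_frames, ts, config$noise_sigma
    )
  }
  for (j in seq_len(nrow(nurses))) {
    p <- nurse_paths[[j]]
    person_frames[[nrow(residents) + j]] <- person_stream(
      nurses$nurse_id[j], "nurse", standing, p[, 1], p[, 2],
      numeric(n_frames), skel$upper, n_frames, ts, config$noise_sigma
    )
  }
  frames <- dplyr::bind_rows(person_frames)

  structure(
    list(
      frames = frames,
      residents = residents[, setdiff(names(residents), c("x", "y"))],
      nurses = nurses[, setdiff(names(nurses), c("x0", "y0"))],
      truth = truth,
      calib = calibration(f, config$scale),
      config = config, seed = seed, duration_s = duration_s
    ),
    class = "ward_session"
  )
}

#' @export
print.ward_session <- function(x, ...) {
  cat(sprintf(
    "<ward_session> seed %d: %.1f min, %d residents, %d nurses, %d rooms, %d truth events\n",
    x$seed, x$duration_s / 60, nrow(x$residents), nrow(x$nurses),
    x$config$n_rooms, nrow(x$truth)
  ))
  invisible(x)
}

build_residents <- function(config) {
  tiers <- config$tiers
  mk <- function(tier, n, cl, al, base_v) {
    if (!n) return(NULL)
    tibble::tibble(
      tier = tier,
      care_level = rep_len(cl, n),
      al = rep_len(al, n),
      baseline_speed = base_v
    )
  }
  res <- dplyr::bind_rows(
    mk("high", tiers[["high"]], c(4L, 5L), 5L, 0.05),
    mk("medium", tiers[["medium"]], 3L, 3L, 0.10),
    mk("low", tiers[["low"]], c(1L, 2L), c(1L, 2L), 0.15)
  )
  res$resident_id <- sprintf("res%02d", seq_len(nrow(res)))
  # high-tier residents share room 1 (with the stationed nurses); the rest
  # are spread over the remaining rooms, medium and low mixed
  other_rooms <- if (config$n_rooms > 1) 2:config$n_rooms else 1L
  res$room <- NA_integer_
  res$room[res$tier == "high"] <- 1L
  rest <- which(res$tier != "high")
  res$room[rest] <- rep_len(other_rooms, length(rest))
  # two of the medium-care residents sit in room 1 with the dependent group
  med <- which(res$tier == "medium")
  if (length(med) >= 2 && config$n_rooms > 1) res$room[med[1:2]] <- 1L
  al_cols <- c("al_meals", "al_bath", "al_excretion", "al_movement", "al_dressup")
  for (col in al_cols) res[[col]] <- res$al
  res[, c("resident_id", "tier", "room", "care_level", al_cols, "baseline_speed")]
}

build_nurses <- function(config, residents) {
  n <- config$n_nurses
  ns <- config$n_stationed
  nurses <- tibble::tibble(
    nurse_id = sprintf("nurse%d", seq_len(n)),
    stationed = seq_len(n) <= ns,
    busy = seq_len(n) <= ns, # stationed attendants are engaged by duty
    available = TRUE, # ...but can still respond to alarms within reach
    workload_index = 0L,
    p_ack = config$p_ack
  )
  high <- residents[residents$tier == "high", , drop = FALSE]
  roam_rooms <- if (config$n_rooms > 1) 2:config$n_rooms else 1L
  nurses$room <- NA_integer_
  nurses$x0 <- NA_real_
  nurses$y0 <- NA_real_
  for (i in seq_len(n)) {
    if (nurses$stationed[i]) {
      anchor <- high[1 + (i - 1) %% max(1, nrow(high)), , drop = FALSE]
      nurses$room[i] <- if (nrow(anchor)) anchor$room else 1L
      nurses$x0[i] <- if (nrow(anchor)) anchor$x + 50 else 100
      nurses$y0[i] <- if (nrow(anchor)) anchor$y else 100
    } else {
      nurses$room[i] <- roam_rooms[1 + (i - ns - 1) %% length(roam_rooms)]
    }
  }
  nurses
}

waypoint_path <- function(n_frames, f, speed_px, xr, yr) {
  duration <- n_frames / f
  pts <- matrix(c(mean(xr), mean(yr)), ncol = 2)
  total_t <- 0
  while (total_t < duration) {
    nxt <- c(runif(1, xr[1], xr[2]), runif(1, yr[1], yr[2]))
    total_t <- total_t + sqrt(sum((nxt - pts[nrow(pts), ])^2)) / speed_px
    pts <- rbind(pts, nxt)
  }
  seg_t <- c(0, cumsum(sqrt(rowSums(diff(pts)^2)) / speed_px))
  t_frame <- (seq_len(n_frames) - 1) / f
  cbind(
    x = stats::approx(seg_t, pts[, 1], xout = t_frame, rule = 2)$y,
    y = stats::approx(seg_t, pts[, 2], xout = t_frame, rule = 2)$y
  )
}

inject_events <- function(config, residents, duration_s) {
  excursion_s <- config$rise_s + config$hold_s + config$return_s
  hours <- duration_s / 3600
  out <- purrr::map(seq_len(nrow(residents)), function(i) {
    rate <- config$event_rate[[residents$tier[i]]]
    n_ev <- rpois(1, rate * hours)
    if (!n_ev) return(NULL)
    lo <- 10
    hi <- duration_s - excursion_s - 10
    if (hi <= lo) return(NULL)
    t0 <- sort(runif(n_ev, lo, hi))
    # enforce per-resident spacing (greedy: keep the earliest of any close pair)
    keep <- rep(TRUE, n_ev)
    last <- -Inf
    for (k in seq_len(n_ev)) {
      if (t0[k] - last < config$min_event_gap_s) keep[k] <- FALSE else last <- t0[k]
    }
    tibble::tibble(resident_id = residents$resident_id[i],
                   room = residents$room[i], ts = t0[keep])
  })
  truth <- dplyr::bind_rows(out)
  if (!nrow(truth)) {
    return(tibble::tibble(
      truth_id = character(), resident_id = character(), room = integer(),
      ts = numeric(), frame = integer(), ordinal = integer()
    ))
  }
  truth <- truth[order(truth$ts, truth$resident_id), , drop = FALSE]
  truth <- truth |>
    dplyr::group_by(.data$resident_id) |>
    dplyr::mutate(ordinal = dplyr::row_number()) |>
    dplyr::ungroup()
  truth$frame <- as.integer(floor(truth$ts * config$frame_rate)) + 1L
  truth$truth_id <- sprintf("%s-t%03d", truth$resident_id, truth$ordinal)
  truth[, c("truth_id", "resident_id", "room", "ts", "frame", "ordinal")]
}

# Build one person's frame rows. pos_x/pos_y may be scalars (static) or
# per-frame vectors; `rise` is the per-frame upward torso excursion in px.
person_stream <- function(id, role, template, pos_x, pos_y, rise, upper,
                          n_frames, ts, noise_sigma) {
  nk <- nrow(template)
  base_x <- outer(rep(1, n_frames), template[, 1]) + pos_x
  base_y <- outer(rep(1, n_frames), template[, 2]) + pos_y
  if (any(rise > 0)) base_y[, upper] <- base_y[, upper] - rise
  margin <- 5
  xmin <- apply(base_x, 1, min) - margin
  xmax <- apply(base_x, 1, max) + margin
  ymin <- apply(base_y, 1, min) - margin
  ymax <- apply(base_y, 1, max) + margin
  kx <- base_x
  ky <- base_y
  if (noise_sigma > 0) {
    kx <- kx + matrix(rnorm(n_frames * nk, 0, noise_sigma), n_frames, nk)
    ky <- ky + matrix(rnorm(n_frames * nk, 0, noise_sigma), n_frames, nk)
  }
  tibble::tibble(
    frame = seq_len(n_frames),
    ts = ts,
    person_id = id,
    role = role,
    xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
    kpt_x = kx, kpt_y = ky,
    kpt_vis = matrix(1, n_frames, nk)
  )
}

# Deterministic keyed uniform draw in [0, 1). A small multiplicative mixer
# over the key bytes: draws depend only on (seed, key), never on call
# order, so the simulator's truth labeler and the triage engine's
# escalation replay see identical acknowledgment outcomes.
keyed_uniform <- function(seed, key) {
  bytes <- utf8ToInt(paste0(seed, ":", key))
  x <- (as.numeric(seed) + 987654321) %% 4294967296
  for (b in c(bytes, 17, 251, 89)) {
    x <- ((x + b) * 69069 + 1) %% 4294967296
  }
  x <- (x * 69069 + 12345) %% 4294967296
  x / 4294967296
}

# Acknowledgment outcome for one (event, nurse) notification.
ack_draw <- function(seed, resident_id, ordinal, nurse_id, p_ack,
                     latency_mean = 5, t_ack = 30) {
  key <- sprintf("%s#%d@%s", resident_id, ordinal, nurse_id)
  u <- keyed_uniform(seed, key)
  ok <- u < p_ack
  lat <- min(qexp(keyed_uniform(seed, paste0(key, ":lat")), 1 / latency_mean), t_ack)
  list(ack = ok, latency = if (ok) lat else NA_real_)
}

#' Programmatic ground-truth labels for simulated events
#'
#' A declared proxy for human annotation ("which nurse actually
#' intervened"): for every injected event the label is
#' * `"none"` when the resident is clinically low-priority (fully
#'   dependent, stationed attendant adjacent) — no alert should be sent;
#' * `"none"` when no available (non-stationed, non-busy) nurse is within
#'   the maximum reachable distance at event time;
#' * otherwise the first nurse, in order of increasing distance among the
#'   reachable available ones, that acknowledges — the same deterministic
#'   keyed acknowledgment draws the triage engine replays — or `"none"` if
#'   every reachable nurse fails to acknowledge.
#'
#' @param session A `ward_session`.
#' @param config A [triage_config()]; supplies `theta_x` and the
#'   acknowledgment horizon.
#'
#' @return The session's `truth` tibble with `label` (nurse id or
#'   `"none"`) and `why` columns.
#' @export
ground_truth_labels <- function(session, config = triage_config()) {
  stopifnot(inherits(session, "ward_session"))
  truth <- session$truth
  if (!nrow(truth)) {
    truth$label <- character()
    truth$why <- character()
    return(truth)
  }
  al_cols <- c("al_meals", "al_bath", "al_excretion", "al_movement", "al_dressup")
  res <- session$residents
  prio <- clinical_priority(res$care_level, res[, al_cols],
                            al_aggregate = config$al_aggregate)
  names(prio) <- res$resident_id
  theta_x <- config$thresholds$theta_x
  nurses <- session$nurses
  avail <- nurse_available(nurses)
  nurse_frames <- session$frames[session$frames$role == "nurse", , drop = FALSE]

  lab <- character(nrow(truth))
  why <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (prio[[truth$resident_id[i]]] == "low") {
      lab[i] <- "none"
      why[i] <- "low_priority"
      next
    }
    d <- nurse_distances(session$frames, nurse_frames, truth$frame[i],
                         truth$resident_id[i], nurses$nurse_id, session$calib)
    cand <- which(avail & is.finite(d) & d <= theta_x)
    if (!length(cand)) {
      lab[i] <- "none"
      why[i] <- "unreachable"
      next
    }
    cand <- cand[order(d[cand], nurses$nurse_id[cand])]
    lab[i] <- "none"
    why[i] <- "no_ack"
    for (j in cand) {
      a <- ack_draw(session$seed, truth$resident_id[i], truth$ordinal[i],
                    nurses$nurse_id[j], nurses$p_ack[j],
                    session$config$ack_latency_mean, config$t_ack)
      if (a$ack) {
        lab[i] <- nurses$nurse_id[j]
        why[i] <- "responded"
        break
      }
    }
  }
  truth$label <- lab
  truth$why <- why
  truth
}
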