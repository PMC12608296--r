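#' Run the full alert-triage pipeline on a session
#'
#' Executes the end-to-end decision loop over a simulated (or imported)
#' session under one of four alerting strategies:
#'
#' * `"baseline"` — conventional notify-all: every detected event is sent
#'   to every on-duty nurse, with no suppression, delay or validation. For
#'   event-level scoring the predicted responder is the nearest nurse.
#' * `"rsd"` — rule-based suppression plus the delay gate; surviving
#'   alarms go to the nearest reachable available nurse, with
#'   acknowledgment-driven escalation down the distance ranking.
#' * `"rsdv"` — adds priority validation by the configured backend against
#'   the fixed base threshold `tau0`.
#' * `"proposed"` — the full pipeline: backend validation against the
#'   dynamic per-alarm threshold, backend nurse ranking, escalation.
#'
#' Alarms are processed in time order; simultaneous alarms are handled in
#' descending urgency (ties by resident id), and each handled alert
#' increments the assigned nurse's workload index before the next alarm is
#' considered. Every alarm receives exactly one disposition:
#' `suppressed`, `delay_discarded`, `validation_discarded`, `dispatched`,
#' `escalated`, or `unanswered` (no nurse acknowledged). The effective
#' alert set is the union of dispatched and escalated alarms. The run is
#' fully deterministic given `(session, config, strategy)`.
#'
#' @param session A `ward_session` from [simulate_ward()], or any list
#'   providing `frames`, `residents`, `nurses`, `calib`, `seed` and a
#'   `config` with the acknowledgment-model fields.
#' @param config A [triage_config()].
#' @param strategy One of `"proposed"`, `"baseline"`, `"rsd"`, `"rsdv"`.
#' @param events Optional precomputed event tibble from [detect_events()];
#'   detected from the session stream when `NULL`.
#'
#' @return An object of class `triage_run`: list with `decisions` (one row
#'   per alarm), `alarms`, `events`, `strategy`, `config`, `nurses` (final
#'   workload state) and `shadow` (the shadow log of discarded alarms).
#' @export
run_triage <- function(session, config = triage_config(),
                       strategy = c("proposed", "baseline", "rsd", "rsdv"),
                       events = NULL) {
  if (is.character(strategy) && length(strategy) == 1 &&
      !strategy %in% c("proposed", "baseline", "rsd", "rsdv")) {
    abort(sprintf("Unknown strategy '%s'.", strategy))
  }
  strategy <- match.arg(strategy)
  stopifnot(inherits(config, "triage_config"))
  calib <- session$calib
  nurses <- session$nurses
  if (!"workload_index" %in% names(nurses)) nurses$workload_index <- 0L

  if (is.null(events)) {
    events <- detect_events(
      session$frames, calib,
      window = config$window, k = config$k, tau = config$tau,
      tau_floor = config$tau_floor, persist_s = config$persist_s,
      merge_gap_s = config$merge_gap_s, standup_frac = config$standup_frac,
      flag_window_s = config$flag_window_s, aggregate = config$aggregate
    )
  }
  alarms <- assemble_alarms(
    events, session$residents, nurses, session$frames, calib,
    weights = config$gamma, v_baseline = config$v_baseline,
    a_baseline = config$a_baseline, flag_cap = config$flag_cap,
    risky = config$risky, al_aggregate = config$al_aggregate
  )
  alarms <- alarms[order(alarms$ts, -alarms$urgency, alarms$resident_id), , drop = FALSE]

  backend <- if (is.function(config$backend)) {
    config$backend
  } else {
    backend_surrogate(config$surrogate_w)
  }
  th <- config$thresholds
  ack_args <- list(
    seed = session$seed,
    latency_mean = session$config$ack_latency_mean %||% 5,
    t_ack = config$t_ack
  )

  n <- nrow(alarms)
  dec <- vector("list", n)
  for (i in seq_len(n)) {
    al <- alarms[i, , drop = FALSE]
    d <- decide_alarm(al, nurses, config, strategy, backend, th, ack_args)
    if (!is.na(d$nurse)) {
      j <- match(d$nurse, nurses$nurse_id)
      nurses$workload_index[j] <- nurses$workload_index[j] + 1L
    }
    dec[[i]] <- d
  }
  decisions <- dplyr::bind_rows(dec)
  if (!n) decisions <- empty_decisions()
  decisions$strategy <- rep(strategy, nrow(decisions))

  structure(
    list(
      decisions = decisions, alarms = alarms, events = events,
      strategy = strategy, config = config, nurses = nurses,
      shadow = decisions[decisions$disposition %in%
                           c("suppressed", "delay_discarded", "validation_discarded"), ,
                         drop = FALSE]
    ),
    class = "triage_run"
  )
}

empty_decisions <- function() {
  tibble::tibble(
    alarm_id = character(), ts = numeric(), resident_id = character(),
    disposition = character(), reason = character(), delay = numeric(),
    priority = numeric(), tau = numeric(), nurse = character(),
    first_nurse = character(), n_notified = integer(), notified = list(),
    ack_latency = numeric()
  )
}

decide_alarm <- function(al, nurses, config, strategy, backend, th, ack_args) {
  base <- tibble::tibble(
    alarm_id = al$alarm_id, ts = al$ts, resident_id = al$resident_id,
    disposition = NA_character_, reason = "none", delay = NA_real_,
    priority = NA_real_, tau = NA_real_, nurse = NA_character_,
    first_nurse = NA_character_, n_notified = 0L,
    notified = list(character()), ack_latency = NA_real_
  )
  if (strategy == "baseline") {
    base$disposition <- "dispatched"
    base$nurse <- al$nearest_nurse
    base$first_nurse <- al$nearest_nurse
    base$n_notified <- nrow(nurses)
    base$notified <- list(nurses$nurse_id)
    return(base)
  }

  # gate 1: rule-based suppression
  sup <- suppress_alarms(al, th)
  if (!sup$keep) {
    base$disposition <- "suppressed"
    base$reason <- sup$reason
    return(base)
  }
  # gate 2: context-weighted delay
  delay <- compute_delay(al$urgency, al$workload, al$priority_class, config$alpha)
  base$delay <- delay * config$delay_scale
  if (!delay_gate(delay, config$t_ack, config$delay_scale)) {
    base$disposition <- "delay_discarded"
    base$reason <- "unacceptable_delay"
    return(base)
  }
  # gate 3: priority validation (rsdv / proposed)
  if (strategy %in% c("rsdv", "proposed")) {
    val <- validate_alarm(al, nurses, th$theta_x, backend)
    tau <- if (strategy == "proposed") {
      dynamic_threshold(al$priority_class, al$workload, al$min_dist_avail,
                        th$theta_x, config$tau0, config$tau_beta)
    } else {
      config$tau0
    }
    base$priority <- val$priority
    base$tau <- tau
    if (is.na(val$priority) || val$priority < tau) {
      base$disposition <- "validation_discarded"
      base$reason <- "below_threshold"
      return(base)
    }
    ranking <- val$ranking
  } else {
    # rsd: nearest reachable available nurse, escalation down the distance order
    d <- al$distances[[1]][nurses$nurse_id]
    ok <- nurse_available(nurses) & is.finite(d) & d <= th$theta_x
    ranking <- nurses$nurse_id[ok][order(d[ok], nurses$nurse_id[ok])]
  }

  # dispatch with acknowledgment-driven escalation
  tried <- character()
  for (nid in ranking) {
    tried <- c(tried, nid)
    p_ack <- nurses$p_ack[match(nid, nurses$nurse_id)] %||% 1
    if (is.na(p_ack)) p_ack <- 1
    a <- ack_draw(ack_args$seed, al$resident_id, al$ordinal, nid, p_ack,
                  ack_args$latency_mean, ack_args$t_ack)
    if (a$ack) {
      base$disposition <- if (length(tried) == 1L) "dispatched" else "escalated"
      base$nurse <- nid
      base$first_nurse <- tried[1]
      base$n_notified <- length(tried)
      base$notified <- list(tried)
      base$ack_latency <- a$latency
      return(base)
    }
  }
  base$disposition <- "unanswered"
  base$reason <- if (length(tried)) "no_acknowledgment" else "no_reachable_nurse"
  base$first_nurse <- if (length(tried)) tried[1] else NA_character_
  base$n_notified <- length(tried)
  base$notified <- list(tried)
  base
}

#' Effective alert set of a run
#'
#' Alarms that survived every gate and were actually handled: disposition
#' `dispatched` or `escalated`.
#'
#' @param run A `triage_run`.
#' @return A tibble of decision rows.
#' @export
effective_alerts <- function(run) {
  stopifnot(inherits(run, "triage_run"))
  run$decisions[run$decisions$disposition %in% c("dispatched", "escalated"), ,
                drop = FALSE]
}

#' Shadow log of a run
#'
#' The retrospective record of suppressed and discarded alarms (one entry
#' per suppressed, delay-discarded or validation-discarded alarm), kept for
#' audit and threshold refinement.
#'
#' @param run A `triage_run`.
#' @return A tibble of decision rows.
#' @export
shadow_log <- function(run) {
  stopifnot(inherits(run, "triage_run"))
  run$shadow
}

#' @export
print.triage_run <- function(x, ...) {
  tab <- table(x$decisions$disposition)
  cat(sprintf("<triage_run> strategy '%s': %d alarms\n", x$strategy,
              nrow(x$decisions)))
  for (nm in names(tab)) cat(sprintf("  %-21s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy triage_run
#' @export
tidy.triage_run <- function(x, ...) x$decisions

#' @rdname tidiers
#' @method glance triage_run
#' @export
glance.triage_run <- function(x, ...) {
  d <- x$decisions
  tibble::tibble(
    strategy = x$strategy,
    n_alarms = nrow(d),
    suppressed = sum(d$disposition == "suppressed"),
    delay_discarded = sum(d$disposition == "delay_discarded"),
    validation_discarded = sum(d$disposition == "validation_discarded"),
    dispatched = sum(d$disposition == "dispatched"),
    escalated = sum(d$disposition == "escalated"),
    unanswered = sum(d$disposition == "unanswered"),
    n_effective = sum(d$disposition %in% c("dispatched", "escalated")),
    n_notifications = sum(d$n_notified)
  )
}
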