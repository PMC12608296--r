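#' Triage pipeline configuration
#'
#' Collects every tunable of the detection and triage pipeline with its
#' default. All weights are validated (simplex constraints), so an invalid
#' configuration fails loudly at construction, not mid-run.
#'
#' @param theta_u Minimum urgency for suppression (default 0.2).
#' @param reach_window Response slack, seconds (default 1).
#' @param stand_up_time Typical stand-up duration, seconds (default 3).
#' @param nurse_speed Nurse walking speed, m/s (default 1.2).
#' @param theta_x Maximum reachable distance, meters; `NULL` derives it
#'   from the three parameters above.
#' @param t_ack Acknowledgment horizon, seconds (default 30).
#' @param delay_scale Seconds per unit delay (default 10).
#' @param gamma Urgency weights, length 4 (see [urgency_weights()]).
#' @param alpha Delay weights, length 3 (see [delay_weights()]).
#' @param surrogate_w Surrogate backend weights, length 4.
#' @param tau0,tau_beta Dynamic-threshold parameters (see
#'   [dynamic_threshold()]).
#' @param backend `"surrogate"` (default) or a backend function satisfying
#'   the contract in [backend_surrogate()].
#' @param window,k,tau,tau_floor,persist_s,merge_gap_s,standup_frac,flag_window_s,aggregate
#'   Detection parameters (see [detect_events()]).
#' @param v_baseline,a_baseline,flag_cap,risky Urgency squashing
#'   parameters (see [urgency_score()]).
#' @param al_aggregate Assistance-level aggregation (see
#'   [clinical_priority()]).
#' @param match_window Truth-to-detection matching window, seconds.
#'
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(theta_u = 0.2, reach_window = 1, stand_up_time = 3,
                          nurse_speed = 1.2, theta_x = NULL, t_ack = 30,
                          delay_scale = 10,
                          gamma = c(0.2, 0.2, 0.25, 0.35),
                          alpha = c(0.5, 0.25, 0.25),
                          surrogate_w = c(0.4, 0.3, 0.2, 0.1),
                          tau0 = 0.3, tau_beta = c(0.1, 0, 0.2),
                          backend = "surrogate",
                          window = 10, k = 3, tau = NULL, tau_floor = 0.5,
                          persist_s = 0.6, merge_gap_s = 6,
                          standup_frac = 0.2, flag_window_s = 300,
                          aggregate = "mean",
                          v_baseline = 0.1, a_baseline = 0.5, flag_cap = 3,
                          risky = c("stand_up_attempt", "unstable_posture"),
                          al_aggregate = "max", match_window = 3) {
  gamma <- do.call(urgency_weights, as.list(unname(gamma)))
  alpha <- do.call(delay_weights, as.list(unname(alpha)))
  thresholds <- suppression_thresholds(
    theta_x = theta_x, theta_u = theta_u, reach_window = reach_window,
    stand_up_time = stand_up_time, nurse_speed = nurse_speed
  )
  if (t_ack <= 0) abort("`t_ack` must be > 0.")
  if (delay_scale < 0) abort("`delay_scale` must be >= 0.")
  if (length(surrogate_w) != 4 || any(surrogate_w < 0)) {
    abort("`surrogate_w` must be 4 non-negative weights.")
  }
  structure(
    list(
      thresholds = thresholds, t_ack = t_ack, delay_scale = delay_scale,
      gamma = gamma, alpha = alpha, surrogate_w = surrogate_w,
      tau0 = tau0, tau_beta = tau_beta, backend = backend,
      window = window, k = k, tau = tau, tau_floor = tau_floor,
      persist_s = persist_s, merge_gap_s = merge_gap_s,
      standup_frac = standup_frac, flag_window_s = flag_window_s,
      aggregate = aggregate, v_baseline = v_baseline,
      a_baseline = a_baseline, flag_cap = flag_cap, risky = risky,
      al_aggregate = al_aggregate, match_window = match_window
    ),
    class = "triage_config"
  )
}

#' Load a triage configuration from YAML
#'
#' Reads a YAML file of `triage_config()` keys, fills in defaults for
#' anything absent (an empty file yields the full default configuration)
#' and validates the result; a violated constraint raises an error naming
#' the offending field.
#'
#' @param path Path to a YAML file.
#' @return A `triage_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(triage_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s", toString(unknown)))
  }
  do.call(triage_config, vals)
}

#' Save a triage configuration to YAML
#'
#' The written file round-trips through [load_config()] to an identical
#' configuration.
#'
#' @param config A `triage_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "triage_config"))
  th <- config$thresholds
  flat <- list(
    theta_u = th$theta_u, reach_window = th$reach_window,
    stand_up_time = th$stand_up_time, nurse_speed = th$nurse_speed,
    theta_x = th$theta_x, t_ack = config$t_ack,
    delay_scale = config$delay_scale, gamma = as.numeric(config$gamma),
    alpha = as.numeric(config$alpha), surrogate_w = config$surrogate_w,
    tau0 = config$tau0, tau_beta = config$tau_beta,
    backend = if (is.character(config$backend)) config$backend else "surrogate",
    window = config$window, k = config$k, tau = config$tau,
    tau_floor = config$tau_floor, persist_s = config$persist_s,
    merge_gap_s = config$merge_gap_s, standup_frac = config$standup_frac,
    flag_window_s = config$flag_window_s, aggregate = config$aggregate,
    v_baseline = config$v_baseline, a_baseline = config$a_baseline,
    flag_cap = config$flag_cap, risky = config$risky,
    al_aggregate = config$al_aggregate, match_window = config$match_window
  )
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}
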