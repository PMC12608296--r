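#' Serialize an alarm into a fixed validation prompt
#'
#' Deterministic natural-language template carrying all five context parts
#' (timestamp, per-nurse distances, urgency, clinical class, workload) and
#' every roster nurse with availability. Identical alarms produce
#' byte-identical prompts, so any validation backend — the deterministic
#' surrogate or an external language model — sees a stable, auditable
#' serialization.
#'
#' @param alarm A single alarm (one-row tibble or list) from
#'   [assemble_alarms()].
#' @param nurses Nurse roster with `nurse_id`, `busy`, optional
#'   `workload_index`.
#'
#' @return A single character string.
#' @export
build_prompt <- function(alarm, nurses) {
  if (is.data.frame(alarm)) {
    stopifnot(nrow(alarm) == 1)
    alarm <- as.list(alarm)
    alarm$distances <- alarm$distances[[1]]
  }
  wl <- if ("workload_index" %in% names(nurses)) nurses$workload_index else rep(0L, nrow(nurses))
  nurse_lines <- sprintf(
    "- %s: distance %.3f m, %s, handled %d alerts",
    nurses$nurse_id,
    as.numeric(alarm$distances[nurses$nurse_id]),
    ifelse(nurse_available(nurses), "available", "unavailable"),
    as.integer(wl)
  )
  paste0(
    "An abnormal-behaviour alert requires triage.\n",
    sprintf("Time: %.3f s. Resident: %s. Activity: %s.\n",
            alarm$ts, alarm$resident_id, alarm$label),
    sprintf("Urgency: %.4f. Clinical priority: %s. Ward workload: %.4f.\n",
            alarm$urgency, alarm$priority_class, alarm$workload),
    "Nurses:\n", paste(nurse_lines, collapse = "\n"), "\n",
    "Reply with a priority in [0, 1] and the single most suitable nurse."
  )
}

#' Deterministic surrogate validation backend
#'
#' Stands behind the priority-backend contract with a transparent scoring
#' rule (no external model): for a nurse at distance `d`,
#' `score = w1 * urgency + w2 * clin(class) + w3 * proximity + w4 * (1 - workload)`
#' with `clin(high) = 1`, `clin(mid) = 0.5`, `clin(low) = 0` and
#' `proximity = max(0, 1 - d / theta_x)`. The alarm priority uses the
#' nearest available nurse's distance; the recommended nurse is the
#' available nurse with the highest per-nurse score, ties broken by lower
#' workload index then lexicographic id.
#'
#' @section Backend contract:
#' A backend is a function `f(alarm, nurses, theta_x)` returning a list
#' with `priority` in \[0, 1\], `nurse` (an id from the roster, or `NA`
#' when no nurse is available) and `ranking` (character vector of
#' available nurses, best first, used for escalation).
#'
#' @param w Numeric weights `(urgency, clinical, proximity, idleness)`,
#'   default `c(0.4, 0.3, 0.2, 0.1)`.
#'
#' @return A backend function.
#' @export
backend_surrogate <- function(w = c(0.4, 0.3, 0.2, 0.1)) {
  stopifnot(length(w) == 4, all(w >= 0))
  function(alarm, nurses, theta_x) {
    if (is.data.frame(alarm)) {
      stopifnot(nrow(alarm) == 1)
      alarm <- as.list(alarm)
      alarm$distances <- alarm$distances[[1]]
    }
    clin <- c(high = 1, mid = 0.5, low = 0)[[alarm$priority_class]]
    wl <- if ("workload_index" %in% names(nurses)) nurses$workload_index else rep(0L, nrow(nurses))
    d <- as.numeric(alarm$distances[nurses$nurse_id])
    avail <- nurse_available(nurses) & is.finite(d)
    prox <- pmax(0, 1 - d / theta_x)
    score <- w[1] * alarm$urgency + w[2] * clin + w[3] * prox +
      w[4] * (1 - alarm$workload)
    if (!any(avail)) {
      return(list(priority = NA_real_, nurse = NA_character_, ranking = character()))
    }
    # escalation ranking covers reachable available nurses only: alerting a
    # nurse who cannot arrive in time is non-actionable by construction
    reach <- avail & d <= theta_x
    idx <- which(if (any(reach)) reach else avail)
    ord <- idx[order(-score[idx], wl[idx], nurses$nurse_id[idx])]
    prio <- w[1] * alarm$urgency + w[2] * clin +
      w[3] * max(0, 1 - min(d[avail]) / theta_x) + w[4] * (1 - alarm$workload)
    list(
      priority = min(max(prio, 0), 1),
      nurse = nurses$nurse_id[ord[1]],
      ranking = if (any(reach)) nurses$nurse_id[ord] else character()
    )
  }
}

#' Validate an alarm and recommend a nurse
#'
#' Third decision gate: a pluggable backend maps the alarm context and the
#' roster to a scalar priority in \[0, 1\] and a recommended nurse. The
#' backend's output is contract-checked; out-of-range priorities or
#' unknown nurse ids raise an error rather than propagating silently.
#'
#' @param alarm One alarm row.
#' @param nurses Nurse roster.
#' @param theta_x Maximum reachable distance (meters), used by proximity
#'   terms.
#' @param backend A backend function; default [backend_surrogate()].
#'
#' @return A list `priority`, `nurse`, `ranking`.
#' @export
validate_alarm <- function(alarm, nurses, theta_x, backend = backend_surrogate()) {
  out <- backend(alarm, nurses, theta_x)
  if (!is.list(out) || !all(c("priority", "nurse", "ranking") %in% names(out))) {
    abort("Backend contract violated: expected list(priority, nurse, ranking).")
  }
  if (is.finite(out$priority) && (out$priority < 0 || out$priority > 1)) {
    abort("Backend contract violated: priority outside [0, 1].")
  }
  known <- c(nurses$nurse_id, NA_character_)
  if (!is.na(out$nurse) && !out$nurse %in% nurses$nurse_id) {
    abort(sprintf("Backend contract violated: unknown nurse '%s'.", out$nurse))
  }
  if (length(out$ranking) && !all(out$ranking %in% nurses$nurse_id)) {
    abort("Backend contract violated: ranking contains unknown nurses.")
  }
  out
}

#' Dynamic per-alarm priority threshold
#'
#' Context-dependent cutoff an alarm's priority must meet (`priority >=
#' tau` passes): higher when the ward is loaded or the nearest nurse is
#' far (dispatching costs more), lower for clinically high-priority
#' residents. `tau = clamp(tau0 + b1 * workload + b2 * min_dist / theta_x -
#' b3 * 1[class == high], 0, 1)`.
#'
#' @param priority_class `"high"`, `"mid"` or `"low"` (vectorized).
#' @param workload Ward workload fraction.
#' @param min_dist Nearest available nurse distance, meters.
#' @param theta_x Maximum reachable distance, meters.
#' @param tau0 Base threshold (default 0.3).
#' @param beta Numeric `(b1, b2, b3)`. The default distance weight `b2` is
#'   0: the surrogate priority already decreases with distance through its
#'   proximity term, and raising the threshold with distance as well would
#'   double-count it and starve far-but-reachable alarms.
#'
#' @return Threshold value(s) in \[0, 1\].
#' @examples
#' dynamic_threshold("high", 0, 0, theta_x = 2.4) # 0.3 - 0.2 = 0.1
#' @export
dynamic_threshold <- function(priority_class, workload, min_dist, theta_x,
                              tau0 = 0.3, beta = c(0.1, 0, 0.2)) {
  stopifnot(length(beta) == 3)
  ratio <- if (theta_x > 0) min_dist / theta_x else 1
  tau <- tau0 + beta[1] * workload + beta[2] * ratio -
    beta[3] * as.numeric(priority_class == "high")
  pmin(pmax(tau, 0), 1)
}
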