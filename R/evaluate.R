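#' Match triage decisions to ground-truth events
#'
#' Event-level alignment of a run's decisions to labelled truth events:
#' within each resident, every truth event is greedily paired with the
#' unused decision closest in time within `match_window` seconds. A
#' decision's predicted class is its final handling nurse (dispatched or
#' escalated) and `"none"` otherwise; unmatched truth events (missed
#' detections) predict `"none"`, and unmatched decisions (spurious
#' detections) have truth `"none"`.
#'
#' @param run A `triage_run`.
#' @param truth Labelled truth tibble from [ground_truth_labels()] (needs
#'   `resident_id`, `ts`, `label`).
#' @param match_window Maximum |time difference| for a pair, seconds.
#'
#' @return A tibble with one row per event (union of truth and detected):
#'   `resident_id`, `truth_ts`, `pred_ts`, `truth`, `predicted`.
#' @export
match_events <- function(run, truth, match_window = 3) {
  stopifnot(inherits(run, "triage_run"))
  d <- run$decisions
  pred_class <- ifelse(d$disposition %in% c("dispatched", "escalated"),
                       d$nurse, "none")
  dec <- tibble::tibble(resident_id = d$resident_id, ts = d$ts,
                        predicted = pred_class)
  out <- list()
  for (rid in union(unique(truth$resident_id), unique(dec$resident_id))) {
    tr <- truth[truth$resident_id == rid, , drop = FALSE]
    de <- dec[dec$resident_id == rid, , drop = FALSE]
    used <- rep(FALSE, nrow(de))
    rows <- list()
    for (i in seq_len(nrow(tr))) {
      gap <- abs(de$ts - tr$ts[i])
      gap[used] <- Inf
      j <- if (nrow(de)) which.min(gap) else integer()
      if (length(j) && is.finite(gap[j]) && gap[j] <= match_window) {
        used[j] <- TRUE
        rows[[length(rows) + 1]] <- tibble::tibble(
          resident_id = rid, truth_ts = tr$ts[i], pred_ts = de$ts[j],
          truth = tr$label[i], predicted = de$predicted[j]
        )
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          resident_id = rid, truth_ts = tr$ts[i], pred_ts = NA_real_,
          truth = tr$label[i], predicted = "none"
        )
      }
    }
    if (any(!used)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        resident_id = rid, truth_ts = NA_real_, pred_ts = de$ts[!used],
        truth = "none", predicted = de$predicted[!used]
      )
    }
    out[[length(out) + 1]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(resident_id = character(), truth_ts = numeric(),
                          pred_ts = numeric(), truth = character(),
                          predicted = character())
  }
  res
}

#' Event-level confusion matrix
#'
#' Truth-versus-predicted tally over the nurse classes plus the `"none"`
#' class ("no alert sent"), as in per-nurse alert-assignment scoring.
#'
#' @param matched Output of [match_events()] (columns `truth`,
#'   `predicted`), or any data frame with those columns.
#' @param classes Class labels; defaults to all labels present plus
#'   `"none"`, nurses first.
#'
#' @return A square counts matrix of class `triage_confusion` (rows =
#'   truth, columns = predicted).
#' @export
confusion_events <- function(matched, classes = NULL) {
  if (!all(c("truth", "predicted") %in% names(matched))) {
    abort("`matched` needs `truth` and `predicted` columns.")
  }
  if (!nrow(matched)) abort("No events to tally.")
  if (is.null(classes)) {
    classes <- c(sort(setdiff(unique(c(matched$truth, matched$predicted)), "none")), "none")
  } else if (length(setdiff(unique(c(matched$truth, matched$predicted)), classes))) {
    abort("Event labels outside the declared class set.")
  }
  m <- table(
    truth = factor(matched$truth, levels = classes),
    predicted = factor(matched$predicted, levels = classes)
  )
  structure(unclass(m), class = "triage_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall and F1 (defined as 0, and flagged, when the
#' denominator vanishes), overall accuracy (trace / total), macro F1
#' (unweighted mean of per-class F1), and one-vs-rest false positive and
#' false negative rates macro-averaged over classes.
#'
#' @param conf A `triage_confusion` matrix (or any square counts matrix
#'   with matching dimnames).
#'
#' @return A list of class `triage_metrics`: `per_class` tibble,
#'   `accuracy`, `macro_f1`, `fpr`, `fnr`, `n_events`.
#' @export
triage_metrics <- function(conf) {
  m <- unclass(as.matrix(conf))
  if (nrow(m) != ncol(m)) abort("Confusion matrix must be square.")
  total <- sum(m)
  if (!total) abort("Empty confusion matrix.")
  classes <- rownames(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  undefined <- (tp + fp == 0) & (tp + fn == 0)
  fpr <- ifelse(fp + tn > 0, fp / (fp + tn), 0)
  fnr <- ifelse(fn + tp > 0, fn / (fn + tp), 0)
  structure(
    list(
      per_class = tibble::tibble(
        class = classes, tp = as.numeric(tp), fp = as.numeric(fp),
        fn = as.numeric(fn), tn = as.numeric(tn),
        precision = unname(prec), recall = unname(rec), f1 = unname(f1),
        undefined = unname(undefined)
      ),
      accuracy = sum(tp) / total,
      macro_f1 = mean(f1),
      fpr = mean(fpr),
      fnr = mean(fnr),
      n_events = total
    ),
    class = "triage_metrics"
  )
}

#' @export
print.triage_metrics <- function(x, ...) {
  cat(sprintf(
    "<triage_metrics> %d events: accuracy %.3f, macro F1 %.3f, FPR %.4f, FNR %.4f\n",
    x$n_events, x$accuracy, x$macro_f1, x$fpr, x$fnr
  ))
  print(x$per_class)
  invisible(x)
}

#' @rdname tidiers
#' @method tidy triage_metrics
#' @export
tidy.triage_metrics <- function(x, ...) x$per_class

#' @rdname tidiers
#' @method glance triage_metrics
#' @export
glance.triage_metrics <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, macro_f1 = x$macro_f1, fpr = x$fpr,
    fnr = x$fnr, n_events = x$n_events
  )
}

#' Per-nurse alarm load relative to the notify-all baseline
#'
#' For each nurse, the number of notifications received under a strategy
#' divided by the notifications under the baseline run, plus the
#' complementary reduction. The baseline's own load is 100% for every
#' nurse by construction; a nurse with zero baseline notifications has an
#' undefined load, reported as `NA`.
#'
#' @param run A `triage_run`.
#' @param baseline_run The `triage_run` of the `"baseline"` strategy on
#'   the same stream.
#'
#' @return A tibble: `nurse_id`, `notifications`,
#'   `baseline_notifications`, `load` and `reduction` (fractions), with an
#'   `"overall"` row appended.
#' @export
alarm_load <- function(run, baseline_run) {
  stopifnot(inherits(run, "triage_run"), inherits(baseline_run, "triage_run"))
  ids <- baseline_run$nurses$nurse_id
  count_notes <- function(r) {
    all_notes <- unlist(r$decisions$notified)
    vapply(ids, function(nid) sum(all_notes == nid), numeric(1))
  }
  n_run <- count_notes(run)
  n_base <- count_notes(baseline_run)
  out <- tibble::tibble(
    nurse_id = ids,
    notifications = n_run,
    baseline_notifications = n_base,
    load = ifelse(n_base > 0, n_run / n_base, NA_real_)
  )
  overall <- tibble::tibble(
    nurse_id = "overall",
    notifications = sum(n_run),
    baseline_notifications = sum(n_base),
    load = if (sum(n_base) > 0) sum(n_run) / sum(n_base) else NA_real_
  )
  out <- dplyr::bind_rows(out, overall)
  out$reduction <- 1 - out$load
  out
}

#' Compare the four alerting strategies on one or more sessions
#'
#' Runs `baseline`, `rsd`, `rsdv` and `proposed` on the identical detected
#' event stream of each session, scores each against the programmatic
#' ground-truth labels, and tabulates overall, per-room and (for several
#' sessions, each standing for one monitored day) per-day metrics together
#' with per-nurse alarm loads.
#'
#' @param sessions A `ward_session` or list of them.
#' @param config A [triage_config()].
#' @param strategies Strategies to run (default all four).
#'
#' @return An object of class `strategy_comparison`: `summary` (one row
#'   per strategy), `per_room`, `per_day`, `room_summary` (mean and SD
#'   across rooms), `loads` (per strategy), and `truth`.
#' @export
compare_strategies <- function(sessions, config = triage_config(),
                               strategies = c("baseline", "rsd", "rsdv", "proposed")) {
  if (inherits(sessions, "ward_session")) sessions <- list(sessions)
  per_event <- list()
  loads <- list()
  for (day in seq_along(sessions)) {
    s <- sessions[[day]]
    truth <- ground_truth_labels(s, config)
    events <- detect_events(
      s$frames, s$calib,
      window = config$window, k = config$k, tau = config$tau,
      tau_floor = config$tau_floor, persist_s = config$persist_s,
      merge_gap_s = config$merge_gap_s, standup_frac = config$standup_frac,
      flag_window_s = config$flag_window_s, aggregate = config$aggregate
    )
    runs <- lapply(setNames(strategies, strategies), function(st) {
      run_triage(s, config, strategy = st, events = events)
    })
    room_of <- setNames(s$residents$room, s$residents$resident_id)
    for (st in strategies) {
      matched <- match_events(runs[[st]], truth, config$match_window)
      matched$room <- unname(room_of[matched$resident_id])
      matched$day <- day
      matched$strategy <- st
      per_event[[length(per_event) + 1]] <- matched
      if ("baseline" %in% strategies) {
        ld <- alarm_load(runs[[st]], runs[["baseline"]])
        ld$strategy <- st
        ld$day <- day
        loads[[length(loads) + 1]] <- ld
      }
    }
  }
  per_event <- dplyr::bind_rows(per_event)
  classes <- c(sort(unique(unlist(lapply(sessions, function(s) s$nurses$nurse_id)))), "none")
  slice_metrics <- function(df) {
    if (!nrow(df)) {
      return(tibble::tibble(accuracy = NA_real_, macro_f1 = NA_real_,
                            fpr = NA_real_, fnr = NA_real_, n_events = 0L))
    }
    glance(triage_metrics(confusion_events(df, classes)))
  }
  summary <- per_event |>
    dplyr::group_by(.data$strategy) |>
    dplyr::group_modify(~ slice_metrics(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(factor(.data$strategy, levels = strategies))
  per_room <- per_event |>
    dplyr::group_by(.data$strategy, .data$room) |>
    dplyr::group_modify(~ slice_metrics(.x)) |>
    dplyr::ungroup()
  per_day <- per_event |>
    dplyr::group_by(.data$strategy, .data$day) |>
    dplyr::group_modify(~ slice_metrics(.x)) |>
    dplyr::ungroup()
  room_summary <- per_room |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(
      accuracy_mean = mean(.data$accuracy, na.rm = TRUE),
      accuracy_sd = stats::sd(.data$accuracy, na.rm = TRUE),
      macro_f1_mean = mean(.data$macro_f1, na.rm = TRUE),
      macro_f1_sd = stats::sd(.data$macro_f1, na.rm = TRUE),
      .groups = "drop"
    )
  loads <- if (length(loads)) dplyr::bind_rows(loads) else NULL
  structure(
    list(summary = summary, per_room = per_room, per_day = per_day,
         room_summary = room_summary, loads = loads,
         per_event = per_event, classes = classes),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname tidiers
#' @method tidy strategy_comparison
#' @export
tidy.strategy_comparison <- function(x, ...) x$summary
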