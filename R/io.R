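#' Read and write JSON-lines files
#'
#' One JSON object per line; the append-friendly format used for keypoint
#' streams, event logs and decision logs. Writing is deterministic (full
#' double precision, stable key order), so identical inputs produce
#' byte-identical files.
#'
#' @param df A data frame; list-columns become JSON arrays.
#' @param path File path.
#' @return `read_jsonl()` a tibble; `write_jsonl()` `path`, invisibly.
#' @export
write_jsonl <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    row <- lapply(as.list(df[i, , drop = FALSE]), function(v) {
      if (is.list(v)) v[[1]] else v
    })
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    x <- lapply(x, function(v) {
      if (is.null(v)) NA else if (length(v) != 1 || is.list(v)) list(v) else v
    })
    tibble::as_tibble(x)
  })
  dplyr::bind_rows(rows)
}

#' Export / import a keypoint stream as JSON-lines
#'
#' One record per (frame, person):
#' `{frame, ts, person_id, role, bbox:[xmin,ymin,xmax,ymax], kpts:[[x,y,vis],...]}`.
#'
#' @param frames A keypoint stream tibble (matrix columns `kpt_x`,
#'   `kpt_y`, `kpt_vis`).
#' @param path File path.
#' @return `read_keypoint_stream()` a stream tibble; the writer `path`,
#'   invisibly.
#' @export
write_keypoint_stream <- function(frames, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(frames))) {
    rec <- list(
      frame = frames$frame[i], ts = frames$ts[i],
      person_id = frames$person_id[i], role = frames$role[i],
      bbox = c(frames$xmin[i], frames$ymin[i], frames$xmax[i], frames$ymax[i]),
      kpts = unname(cbind(frames$kpt_x[i, ], frames$kpt_y[i, ], frames$kpt_vis[i, ]))
    )
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)), con)
  }
  invisible(path)
}

#' @rdname write_keypoint_stream
#' @export
read_keypoint_stream <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  nk <- nrow(recs[[1]]$kpts)
  kx <- t(vapply(recs, function(r) r$kpts[, 1], numeric(nk)))
  ky <- t(vapply(recs, function(r) r$kpts[, 2], numeric(nk)))
  kv <- t(vapply(recs, function(r) r$kpts[, 3], numeric(nk)))
  tibble::tibble(
    frame = vapply(recs, function(r) as.integer(r$frame), integer(1)),
    ts = vapply(recs, function(r) as.numeric(r$ts), numeric(1)),
    person_id = vapply(recs, function(r) r$person_id, character(1)),
    role = vapply(recs, function(r) r$role, character(1)),
    xmin = vapply(recs, function(r) r$bbox[1], numeric(1)),
    ymin = vapply(recs, function(r) r$bbox[2], numeric(1)),
    xmax = vapply(recs, function(r) r$bbox[3], numeric(1)),
    ymax = vapply(recs, function(r) r$bbox[4], numeric(1)),
    kpt_x = kx, kpt_y = ky, kpt_vis = kv
  )
}

#' Write a run's decision log (JSON-lines)
#'
#' One record per alarm: id, timestamp, disposition, reason, delay,
#' priority, threshold, final nurse, notification count and strategy.
#' Deterministic: identical runs yield byte-identical logs.
#'
#' @param run A `triage_run`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_decision_log <- function(run, path) {
  stopifnot(inherits(run, "triage_run"))
  d <- run$decisions[, c("alarm_id", "ts", "resident_id", "disposition",
                         "reason", "delay", "priority", "tau", "nurse",
                         "n_notified", "strategy")]
  write_jsonl(d, path)
}

#' @rdname write_decision_log
#' @export
read_decision_log <- function(path) read_jsonl(path)

#' Read / write roster CSV files
#'
#' Residents: `resident_id, room, care_level, al_meals, al_bath,
#' al_excretion, al_movement, al_dressup[, baseline_speed]`. Nurses:
#' `nurse_id, room, busy[, stationed, workload_index, p_ack]`.
#'
#' @param path File path.
#' @param residents,nurses Roster tibbles.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
read_residents <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_residents
#' @export
write_residents <- function(residents, path) {
  readr::write_csv(residents, path)
  invisible(path)
}

#' @rdname read_residents
#' @export
read_nurses <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"workload_index" %in% names(out)) out$workload_index <- 0L
  out
}

#' @rdname read_residents
#' @export
write_nurses <- function(nurses, path) {
  readr::write_csv(nurses, path)
  invisible(path)
}
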