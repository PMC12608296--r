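#' Broom-style tidiers for triage objects
#'
#' `tidy()` returns the row-per-observation view of an object — the
#' decision log of a `triage_run`, the per-class metric table of a
#' `triage_metrics`, the per-strategy summary of a
#' `strategy_comparison`. `glance()` returns a one-row summary.
#'
#' @param x A `triage_run`, `triage_metrics` or `strategy_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL
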