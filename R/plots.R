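#' Plot strategy comparison metrics
#'
#' Bar chart of accuracy and macro F1 per alerting strategy.
#'
#' @param object A `strategy_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot strategy_comparison
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("accuracy", "macro_f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$strategy, levels = unique(object$summary$strategy)),
    y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "strategy", y = NULL, fill = NULL,
                  title = "Alert-assignment performance by strategy") +
    ggplot2::theme_minimal()
}

#' Plot per-class F1 of a metrics object
#'
#' @param object A `triage_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triage_metrics
#' @export
autoplot.triage_metrics <- function(object, ...) {
  ggplot2::ggplot(object$per_class,
                  ggplot2::aes(x = .data$class, y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "F1",
                  title = "Per-class F1 (nurses and the no-alert class)") +
    ggplot2::theme_minimal()
}

#' Plot per-nurse alarm load against the baseline
#'
#' Bar chart of the per-nurse load fraction (notifications relative to
#' notify-all) for each strategy of a comparison.
#'
#' @param comparison A `strategy_comparison` with loads (requires the
#'   baseline strategy to have been run).
#' @return A ggplot object.
#' @export
plot_alarm_load <- function(comparison) {
  stopifnot(inherits(comparison, "strategy_comparison"))
  if (is.null(comparison$loads)) {
    abort("No loads available: the comparison must include the baseline strategy.")
  }
  df <- comparison$loads[comparison$loads$nurse_id != "overall", , drop = FALSE]
  df <- df |>
    dplyr::group_by(.data$strategy, .data$nurse_id) |>
    dplyr::summarise(load = mean(.data$load, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nurse_id, y = .data$load,
                                   fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "alarm load (fraction of baseline)",
                  title = "Per-nurse alarm load by strategy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
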