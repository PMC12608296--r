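#' Default trajectory forecaster: rolling least-squares linear extrapolation
#'
#' The anomaly detector only consumes forecast residuals, so any model
#' satisfying the forecaster contract can stand behind it. The packaged
#' default fits an ordinary least-squares line to the most recent
#' `window` samples and extrapolates it, which is deterministic,
#' dependency-free, and exact on noiseless trajectories of degree <= 1.
#'
#' @section Forecaster contract:
#' A forecaster is a function `f(history, horizon)` taking a numeric vector
#' of past positions (oldest first) and a number of steps, and returning a
#' numeric vector of `horizon` predicted positions. It must be deterministic
#' given its inputs.
#'
#' @param window Number of trailing samples the line is fitted to; `NULL`
#'   (default) uses the whole history.
#'
#' @return A forecaster function.
#' @examples
#' f <- forecaster_linear()
#' f(c(1, 3, 5, 7), horizon = 3) # 9, 11, 13
#' @export
forecaster_linear <- function(window = NULL) {
  force(window)
  function(history, horizon) {
    h <- as.numeric(history)
    if (!is.null(window) && length(h) > window) h <- tail(h, window)
    n <- length(h)
    if (n < 2) return(rep(h[n], horizon))
    x <- seq_len(n)
    xb <- mean(x)
    yb <- mean(h)
    sxx <- sum((x - xb)^2)
    b <- sum((x - xb) * (h - yb)) / sxx
    a <- yb - b * xb
    a + b * (n + seq_len(horizon))
  }
}

#' Forecast a joint trajectory
#'
#' Applies a forecaster (see [forecaster_linear()] for the contract) to the
#' trailing `window_length` samples of a position series and returns the
#' predicted positions over the horizon.
#'
#' @param series A numeric vector of positions, or a data frame with
#'   columns `ts` and `value` (timestamps strictly increasing).
#' @param horizon Number of steps ahead to predict (>= 1).
#' @param forecaster A forecaster function; default [forecaster_linear()].
#' @param window_length Minimum (and fitted) history length; the series
#'   must contain at least this many samples.
#'
#' @return A tibble with columns `step` (1..horizon) and `predicted`.
#' @examples
#' forecast_trajectory(c(0, 2, 4, 6), horizon = 3, window_length = 4)
#' @export
forecast_trajectory <- function(series, horizon = 1, forecaster = forecaster_linear(),
                                window_length = 10) {
  if (is.data.frame(series)) {
    if (!all(c("ts", "value") %in% names(series))) {
      abort("A series data frame needs `ts` and `value` columns.")
    }
    if (is.unsorted(series$ts, strictly = TRUE)) {
      abort("Series timestamps must be strictly increasing.")
    }
    series <- series$value
  }
  series <- as.numeric(series)
  if (window_length < 2) abort("`window_length` must be at least 2.")
  if (length(series) < window_length) {
    abort(sprintf(
      "Series has %d samples but `window_length` is %d.",
      length(series), window_length
    ))
  }
  if (horizon < 1) abort("`horizon` must be >= 1.")
  pred <- forecaster(tail(series, window_length), horizon)
  if (length(pred) != horizon) {
    abort("Forecaster contract violated: wrong number of predictions.")
  }
  tibble::tibble(step = seq_len(horizon), predicted = as.numeric(pred))
}

#' Forecast-residual abnormality scores
#'
#' The abnormality score at each time point is the absolute forecast
#' residual `|observed - predicted|`.
#'
#' @param observed,predicted Aligned numeric vectors of equal length.
#'
#' @return Non-negative numeric vector of scores.
#' @export
residual_score <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.")
  }
  abs(as.numeric(observed) - as.numeric(predicted))
}

#' Flag abnormal time points from scores
#'
#' A time point is abnormal when its score strictly exceeds the threshold
#' `tau`; a score exactly equal to `tau` is normal.
#'
#' @param scores Non-negative numeric scores.
#' @param tau Positive threshold.
#' @param ts Optional timestamps aligned with `scores` (defaults to the
#'   score index).
#'
#' @return A tibble of flagged points with columns `index`, `ts`, `score`.
#' @examples
#' flag_abnormal(c(1, 6, 2), tau = 5) # one row, index 2
#' @export
flag_abnormal <- function(scores, tau, ts = NULL) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    abort("`tau` must be a single positive number.")
  }
  ts <- ts %||% seq_along(scores)
  idx <- which(scores > tau)
  tibble::tibble(index = idx, ts = ts[idx], score = as.numeric(scores[idx]))
}

# One-step-ahead rolling linear-extrapolation residuals, vectorized.
# The LS-line one-step prediction from a fixed-length window is a linear
# filter with constant coefficients, so the whole series is scored with a
# single convolution. Returns NA for the first `window` samples.
rolling_residuals <- function(y, window = 10) {
  n <- length(y)
  if (n <= window) return(rep(NA_real_, n))
  x <- seq_len(window)
  xb <- mean(x)
  sxx <- sum((x - xb)^2)
  # prediction at x = window + 1: c_i = 1/w + (x_i - xb) * (w + 1 - xb) / sxx
  cf <- 1 / window + (x - xb) * (window + 1 - xb) / sxx
  pred <- stats::filter(y, rev(cf), method = "convolution", sides = 1)
  pred <- c(NA_real_, as.numeric(pred)[-n])
  res <- y - pred
  res[seq_len(window)] <- NA_real_
  res
}

#' Adaptive abnormality threshold from residual spread
#'
#' Default threshold rule: `k` times the median absolute deviation (MAD,
#' scaled to be consistent with the standard deviation under normality) of
#' the residual scores, with an absolute floor that guards the degenerate
#' noiseless case where the MAD collapses to zero.
#'
#' @param scores Numeric abnormality scores (NAs ignored).
#' @param k Multiplier on the MAD (default 3).
#' @param floor Minimum threshold in score units (pixels), default 0.5.
#'
#' @return A single positive threshold.
#' @export
tau_mad <- function(scores, k = 3, floor = 0.5) {
  s <- scores[is.finite(scores)]
  m <- if (length(s)) stats::mad(s, center = 0) else 0
  max(k * m, floor)
}
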