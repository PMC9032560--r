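# Adaptive exponential-smoothing flow controller.
#
# A sidestream capnography pump must hold its sampling flow consistent
# with the subject's actual respiratory flow, which varies continuously.
# The controller forecasts the next respiratory flow with exponential
# smoothing, compares forecast to measurement, and adapts the smoothing
# parameter from the ratio of the current forecast error to its recent
# windowed mean; the adapted parameter then drives the next sampling-flow
# setting. The geometric weight series is truncated at the N buffered
# flows. Histories are ordered most-recent-first throughout this module.

#' Flow controller configuration
#'
#' @param f0 Initial sampling flow (L/min).
#' @param alpha0 Initial smoothing parameter, in (0, 1).
#' @param n_window Prediction window size N (number of buffered flows).
#' @param w_window Error window size W (number of buffered errors).
#' @param beta Self-adjustment coefficient (>= 0); `beta = 0` disables
#'   adaptation, reducing the controller to fixed-parameter smoothing.
#' @return A list of class `flow_config`.
#' @export
flow_config <- function(f0 = 1.0, alpha0 = 0.3, n_window = 5,
                        w_window = 10, beta = 0.1) {
  if (alpha0 <= 0 || alpha0 >= 1) abort_invalid("alpha0 must be in (0, 1)")
  if (n_window < 1 || w_window < 1) abort_invalid("window sizes must be >= 1")
  if (beta < 0) abort_invalid("beta must be >= 0")
  structure(list(f0 = f0, alpha0 = alpha0, n_window = as.integer(n_window),
                 w_window = as.integer(w_window), beta = beta),
            class = "flow_config")
}

#' Exponentially-smoothed forecast of the next flow
#'
#' `F_hat = sum_{k=0}^{K-1} alpha * (1-alpha)^k * history[k+1]` with
#' `K = min(n_terms, length(history))`; the series is truncated at the
#' available terms rather than renormalized.
#'
#' @param history Flow values, most recent first.
#' @param alpha Smoothing parameter in (0, 1].
#' @param n_terms Maximum number of terms (default: all of `history`).
#' @return The forecast flow.
#' @export
predict_next_flow <- function(history, alpha, n_terms = length(history)) {
  if (length(history) == 0) abort_state("flow history is empty")
  k <- min(n_terms, length(history))
  w <- alpha * (1 - alpha)^(seq_len(k) - 1)
  sum(w * history[seq_len(k)])
}

#' Signed forecast error
#'
#' `E = predicted - actual`.
#'
#' @param predicted,actual Flow values.
#' @return The signed error.
#' @export
forecast_error <- function(predicted, actual) predicted - actual

#' Mean forecast error over a sliding window
#'
#' Arithmetic mean of the last `min(w, length(errors))` recorded errors.
#'
#' @param errors Forecast errors, most recent first.
#' @param w Window size W.
#' @return The windowed mean error.
#' @export
window_mean_error <- function(errors, w) {
  if (length(errors) == 0) abort_state("no forecast errors recorded")
  mean(errors[seq_len(min(w, length(errors)))])
}

#' Adapt the smoothing parameter
#'
#' `alpha' = alpha * (1 + beta * (e / e_bar - 1))`, clamped to
#' `[0.01, 0.99]`. When `|e_bar| < 1e-9` the ratio is defined as 1, so the
#' parameter is left unchanged (the raw update divides by the windowed
#' mean and is unbounded; the guard and clamp are stabilizations).
#'
#' @param alpha Current smoothing parameter, in (0, 1).
#' @param e Current forecast error.
#' @param e_bar Windowed mean error.
#' @param beta Self-adjustment coefficient.
#' @return The adapted, clamped smoothing parameter.
#' @export
update_alpha <- function(alpha, e, e_bar, beta) {
  ratio <- if (abs(e_bar) < 1e-9) 1 else e / e_bar
  min(max(alpha * (1 + beta * (ratio - 1)), 0.01), 0.99)
}

#' Next sampling-flow setting
#'
#' Exponential smoothing of the past sampling flows with the adapted
#' parameter, truncated like [predict_next_flow()].
#'
#' @param sample_history Past sampling flows, most recent first.
#' @param alpha Adapted smoothing parameter.
#' @param n_terms Maximum number of terms.
#' @return The next sampling flow.
#' @export
control_flow <- function(sample_history, alpha,
                         n_terms = length(sample_history)) {
  if (length(sample_history) == 0) abort_state("sampling-flow history is empty")
  predict_next_flow(sample_history, alpha, n_terms)
}

#' Replay a respiratory flow trace through the controller
#'
#' Runs the full adapt loop over a recorded flow trace: at each step the
#' last N flows are smoothed into a forecast, the forecast error enters
#' the W-window, the smoothing parameter adapts from the error ratio, and
#' the sampling flow is re-set. The error window includes the current
#' step's error, so on a constant trace the ratio is 1 from the first
#' step and the parameter never moves.
#'
#' @param flow_trace Respiratory flow samples in chronological order;
#'   must be longer than `config$n_window`.
#' @param config A [flow_config()].
#' @return Data.frame log with one row per step: `step` (index of the
#'   forecast target), `f_actual`, `f_hat`, `e`, `e_bar`, `alpha`,
#'   `f_sample`. Its length is `length(flow_trace) - n_window`.
#' @export
run_controller <- function(flow_trace, config) {
  stopifnot(inherits(config, "flow_config"))
  n <- config$n_window
  len <- length(flow_trace)
  if (len <= n) {
    abort_invalid(sprintf("flow trace length (%d) must exceed the prediction window (%d)",
                          len, n))
  }
  steps <- len - n
  alpha <- config$alpha0
  errors <- numeric(0)
  samples <- config$f0 # most recent first
  log <- data.frame(step = integer(steps), f_actual = numeric(steps),
                    f_hat = numeric(steps), e = numeric(steps),
                    e_bar = numeric(steps), alpha = numeric(steps),
                    f_sample = numeric(steps))
  for (s in seq_len(steps)) {
    i <- n + s - 1
    hist <- flow_trace[i:(i - n + 1)]
    f_hat <- predict_next_flow(hist, alpha, n)
    e <- forecast_error(f_hat, flow_trace[i + 1])
    errors <- c(e, errors)
    if (length(errors) > config$w_window) {
      errors <- errors[seq_len(config$w_window)]
    }
    e_bar <- window_mean_error(errors, config$w_window)
    alpha <- update_alpha(alpha, e, e_bar, config$beta)
    f_next <- control_flow(samples, alpha, n)
    samples <- c(f_next, samples)
    if (length(samples) > n) samples <- samples[seq_len(n)]
    log[s, ] <- list(i + 1L, flow_trace[i + 1], f_hat, e, e_bar, alpha, f_next)
  }
  log
}
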