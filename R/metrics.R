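# Regression evaluation metrics.
#
# Alongside RMSE and R^2, the package reports a percentage-error family
# tailored to clinical regression, where the worst case matters: the
# maximum percentage error (MPE), the mean absolute percentage error
# (MAPE), the root mean square percentage error (RMSPE, normalized by the
# mean of the true values), their average, the comprehensive percentage
# error CPE = (MPE + MAPE + RMSPE) / 3, and the accuracy rate
# ACC = 100 - CPE. All percentages are on the 0-100 scale.

check_metric_input <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    abort_invalid("predictions and truths must have equal length")
  }
  if (length(truths) < 1) abort_invalid("at least one observation required")
  if (!all(is.finite(predictions)) || !all(is.finite(truths))) {
    abort_invalid("predictions and truths must be finite")
  }
}

#' Maximum percentage error
#'
#' `max_i |x_i - y_i| / y_i * 100`. The denominator is the raw true value
#' (no epsilon guard), so any zero truth is a domain error.
#'
#' @param predictions Predicted values.
#' @param truths True values (all non-zero; positive in this domain).
#' @return MPE in percent.
#' @export
mpe <- function(predictions, truths) {
  check_metric_input(predictions, truths)
  if (any(truths == 0)) abort_invalid("MPE is undefined for zero truths")
  max(abs(predictions - truths) / truths) * 100
}

#' Mean absolute percentage error
#'
#' `mean_i |x_i - y_i| / max(eps, |y_i|) * 100`; invariant under a global
#' scaling of predictions and truths.
#'
#' @inheritParams mpe
#' @param eps Strictly positive guard for zero truths.
#' @return MAPE in percent.
#' @export
mape <- function(predictions, truths, eps = 1e-8) {
  check_metric_input(predictions, truths)
  mean(abs(predictions - truths) / pmax(eps, abs(truths))) * 100
}

#' Root mean square percentage error
#'
#' `sqrt(mean((x_i - y_i)^2)) / mean(y) * 100`: the denominator is the
#' mean of the true values (a single global normalizer, not per-sample).
#'
#' @inheritParams mpe
#' @return RMSPE in percent.
#' @export
rmspe <- function(predictions, truths) {
  check_metric_input(predictions, truths)
  ybar <- mean(truths)
  if (ybar == 0) abort_invalid("RMSPE is undefined when the mean truth is 0")
  sqrt(mean((predictions - truths)^2)) / ybar * 100
}

#' Comprehensive percentage error and accuracy rate
#'
#' `CPE = (MPE + MAPE + RMSPE) / 3`; `ACC = 100 - CPE` (both percent).
#'
#' @param mpe,mape,rmspe Component percentages (non-negative).
#' @return List with elements `cpe` and `acc`.
#' @export
cpe_acc <- function(mpe, mape, rmspe) {
  cpe <- (mpe + mape + rmspe) / 3
  list(cpe = cpe, acc = 100 - cpe)
}

#' Root mean squared error and coefficient of determination
#'
#' Standard definitions: `RMSE = sqrt(mean((x - y)^2))`;
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @inheritParams mpe
#' @return List with elements `rmse` and `r2`.
#' @export
rmse_r2 <- function(predictions, truths) {
  check_metric_input(predictions, truths)
  rmse <- sqrt(mean((predictions - truths)^2))
  if (length(truths) < 2) abort_invalid("R^2 requires n >= 2")
  ss_tot <- sum((truths - mean(truths))^2)
  if (ss_tot == 0) abort_invalid("R^2 is undefined for zero target variance")
  list(rmse = rmse, r2 = 1 - sum((predictions - truths)^2) / ss_tot)
}

#' Full metric report for one prediction set
#'
#' @inheritParams mpe
#' @return One-row data.frame: `RMSE`, `R2`, `MPE`, `MAPE`, `RMSPE`,
#'   `CPE`, `ACC`.
#' @export
metric_report <- function(predictions, truths) {
  rr <- rmse_r2(predictions, truths)
  m1 <- mpe(predictions, truths)
  m2 <- mape(predictions, truths)
  m3 <- rmspe(predictions, truths)
  ca <- cpe_acc(m1, m2, m3)
  data.frame(RMSE = rr$rmse, R2 = rr$r2, MPE = m1, MAPE = m2,
             RMSPE = m3, CPE = ca$cpe, ACC = ca$acc)
}
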