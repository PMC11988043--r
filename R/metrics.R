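## Evaluation metrics for weight regression: MAE, RMSE and the coefficient
## of determination R^2, all computed in kg on de-normalized predictions.

check_lengths <- function(y, y_hat) {
  if (length(y) == 0L) stop("metrics: empty input")
  if (length(y) != length(y_hat))
    stop("metrics: y and y_hat lengths differ (", length(y), " vs ",
         length(y_hat), ")")
}

#' Mean absolute error
#' @param y true weights (kg).
#' @param y_hat estimated weights (kg), same length.
#' @return `(1/n) * sum(|y_hat - y|)` in kg.
#' @export
mae <- function(y, y_hat) {
  check_lengths(y, y_hat)
  mean(abs(y_hat - y))
}

#' Root mean square error
#' @inheritParams mae
#' @return `sqrt((1/n) * sum((y_hat - y)^2))` in kg.
#' @export
rmse <- function(y, y_hat) {
  check_lengths(y, y_hat)
  sqrt(mean((y_hat - y)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((y_hat - y)^2) / sum((mean(y) - y)^2)`. May be negative when the
#' model predicts worse than the mean of the true values; not clamped.
#' @inheritParams mae
#' @return dimensionless R^2 (<= 1).
#' @export
r2 <- function(y, y_hat) {
  check_lengths(y, y_hat)
  if (length(y) < 2L) stop("r2: needs at least two observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("r2: true values have zero variance")
  1 - sum((y_hat - y)^2) / ss_tot
}

#' Full metrics report over an evaluation set
#' @inheritParams mae
#' @return list of class `metrics_report` with `mae`, `rmse`, `r2`, `n`.
#' @export
metrics_report <- function(y, y_hat) {
  rep <- list(mae = mae(y, y_hat), rmse = rmse(y, y_hat),
              r2 = r2(y, y_hat), n = length(y))
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n    : %d\nMAE  : %.4f kg\nRMSE : %.4f kg\nR2   : %.4f\n",
              x$n, x$mae, x$rmse, x$r2))
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report a `metrics_report`.
#' @param path output path.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
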