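# Regression evaluation metrics: MAE, RMSE, MAPE, RMSLE, R^2.

#' Evaluate a prediction set
#'
#' Computes the five regression metrics used throughout the package:
#' \describe{
#'   \item{MAE}{\eqn{\frac1n \sum |y_i - \hat y_i|}, in target units (kJ/mol)}
#'   \item{RMSE}{\eqn{\sqrt{\frac1n \sum (y_i - \hat y_i)^2}}}
#'   \item{MAPE}{\eqn{\frac1n \sum |y_i - \hat y_i| / |y_i|}, reported as a
#'     fraction (multiply by 100 for percent)}
#'   \item{RMSLE}{root mean squared error of \eqn{\log(\cdot + 1)}}
#'   \item{R2}{\eqn{1 - \sum (y_i-\hat y_i)^2 / \sum (y_i - \bar y)^2}}
#' }
#' Targets are positive magnitudes of the combustion enthalpy so the
#' logarithm in RMSLE is defined.
#'
#' @param y actual target values
#' @param yhat predicted values
#' @param percent if TRUE, MAPE is reported in percent rather than as a
#'   fraction
#' @return object of class \code{metric_report}: list with \code{mae},
#'   \code{rmse}, \code{mape}, \code{rmsle}, \code{r2}, \code{n}.
#' @examples
#' evaluate_predictions(c(100, 200), c(110, 190))
#' @export
evaluate_predictions <- function(y, yhat, percent = FALSE) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("non-finite values in prediction set", call. = FALSE)
  if (any(y == 0))
    stop(sprintf("MAPE undefined: actual value is zero at index %d",
                 which(y == 0)[1L]), call. = FALSE)
  if (any(y < 0) || any(yhat < 0))
    stop("RMSLE undefined for negative values; targets are positive -dcH magnitudes",
         call. = FALSE)
  res <- y - yhat
  mape <- mean(abs(res) / abs(y))
  out <- list(
    mae = mean(abs(res)),
    rmse = sqrt(mean(res^2)),
    mape = if (percent) 100 * mape else mape,
    rmsle = sqrt(mean((log1p(yhat) - log1p(y))^2)),
    r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
    n = n)
  structure(out, class = "metric_report", percent = percent)
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Metric report (n = %d)\n  R2    %.*f\n  MAE   %.*f kJ/mol\n  MAPE  %.*f%s\n  RMSE  %.*f kJ/mol\n  RMSLE %.*f\n",
    x$n, digits, x$r2, digits, x$mae, digits, x$mape,
    if (isTRUE(attr(x, "percent"))) " %" else "", digits, x$rmse,
    digits, x$rmsle))
  invisible(x)
}

#' Serialize a metric report to JSON
#'
#' @param x a \code{metric_report}
#' @return JSON string with keys \code{mae, rmse, mape, rmsle, r2}.
#' @export
metric_report_json <- function(x) {
  stopifnot(inherits(x, "metric_report"))
  jsonlite::toJSON(x[c("mae", "rmse", "mape", "rmsle", "r2")],
                   auto_unbox = TRUE, digits = NA)
}
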