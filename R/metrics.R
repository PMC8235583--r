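#' Prediction-error metrics
#'
#' Mean absolute error, mean squared error and root-mean-squared error over
#' paired predictions and ground truth: `MAE = mean(|yhat - y|)`,
#' `MSE = mean((yhat - y)^2)`, `RMSE = sqrt(MSE)`.  In this package
#' predictions and truth are in MET units, so MAE and RMSE are METs and MSE
#' is MET squared.
#'
#' @param predicted,truth Equal-length, non-empty numeric vectors.
#' @return A single non-negative number.
#' @export
mae <- function(predicted, truth) {
  check_metric_args(predicted, truth)
  mean(abs(predicted - truth))
}

#' @rdname mae
#' @export
mse <- function(predicted, truth) {
  check_metric_args(predicted, truth)
  mean((predicted - truth)^2)
}

#' @rdname mae
#' @export
rmse <- function(predicted, truth) sqrt(mse(predicted, truth))

check_metric_args <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (!length(truth)) stop("empty input", call. = FALSE)
  invisible(NULL)
}

#' Build one row of a metrics report
#'
#' @param predicted,truth Paired predictions and ground truth (MET).
#' @param view,family,activity,pca Grouping keys: camera view, model family,
#'   activity (or `"general"`), and whether PCA reduction was applied.
#' @return A one-row data frame of class `metrics_report` with columns
#'   `view`, `family`, `activity`, `pca`, `mae`, `mse`, `rmse`, `n`.
#' @export
metrics_report <- function(predicted, truth, view = NA_character_,
                           family = NA_character_, activity = "general",
                           pca = FALSE) {
  structure(
    data.frame(view = view, family = family, activity = activity, pca = pca,
               mae = mae(predicted, truth), mse = mse(predicted, truth),
               rmse = rmse(predicted, truth), n = length(truth),
               stringsAsFactors = FALSE),
    class = c("metrics_report", "data.frame"))
}

#' Validate metric identities on a report
#'
#' Asserts, on every row, that all metrics are non-negative, that
#' `RMSE = sqrt(MSE)` to numerical tolerance and that `MAE <= RMSE`
#' (Jensen's inequality).
#'
#' @param report A data frame with columns `mae`, `mse`, `rmse`.
#' @param tol Numerical tolerance.
#' @return `report`, invisibly; errors if any identity fails.
#' @export
validate_report <- function(report, tol = 1e-8) {
  stopifnot(all(c("mae", "mse", "rmse") %in% names(report)))
  if (any(report$mae < 0 | report$mse < 0 | report$rmse < 0)) {
    stop("metrics must be non-negative", call. = FALSE)
  }
  if (any(abs(report$rmse - sqrt(report$mse)) > tol * (1 + report$rmse))) {
    stop("RMSE != sqrt(MSE) in report", call. = FALSE)
  }
  if (any(report$mae > report$rmse + tol * (1 + report$rmse))) {
    stop("MAE > RMSE in report", call. = FALSE)
  }
  invisible(report)
}
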