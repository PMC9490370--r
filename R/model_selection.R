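# Cross-validation machinery and the two model-selection statistics.

#' Root mean squared error of cross-validation
#'
#' `RMSECV = sqrt( sum_i (y_i - ytilde_i)^2 / m )` where `ytilde_i` is the
#' cross-validated prediction for calibration sample `i` and `m` the number
#' of calibration samples. The same formula with fitted or test-set values
#' gives RMSEC and RMSEP (see [rmse()]).
#'
#' @param actual,predicted Numeric vectors of equal length `m >= 1`.
#' @return Non-negative scalar.
#' @export
rmsecv <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("need at least one sample", call. = FALSE)
  sqrt(mean((actual - predicted)^2))
}

#' Predicted residual error sum of squares
#'
#' `PRESS = sum_i (y_i - yhat_i)^2` over cross-validated predictions;
#' algebraically `PRESS = m * RMSECV^2`.
#'
#' @param actual,predicted Numeric vectors of equal length `m >= 1`.
#' @return Non-negative scalar.
#' @export
press <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("need at least one sample", call. = FALSE)
  sum((actual - predicted)^2)
}

#' Leave-one-out cross-validated predictions
#'
#' For each sample `i`, a model is fitted on all remaining samples and
#' applied to the removed one; the vector of these held-out predictions is
#' what RMSECV and PRESS are computed from. `X_like` may be a matrix
#' (rows = samples) or a 3-way array (first axis = samples); subsetting
#' keeps the remaining dimensions.
#'
#' @param fit_fn `function(X_train, y_train) -> model`.
#' @param predict_fn `function(model, X_test) -> numeric`; `X_test` holds a
#'   single sample (one row / one first-axis slice).
#' @param X_like Matrix or 3-way array of predictors.
#' @param y Numeric response, one value per sample.
#' @return Numeric vector of length `length(y)` aligned to the input order.
#' @export
loo_predictions <- function(fit_fn, predict_fn, X_like, y) {
  m <- length(y)
  if (m < 2L) stop("leave-one-out needs at least 2 samples", call. = FALSE)
  take <- function(X, idx) {
    if (length(dim(X)) == 3L) X[idx, , , drop = FALSE]
    else X[idx, , drop = FALSE]
  }
  out <- numeric(m)
  for (i in seq_len(m)) {
    rest <- setdiff(seq_len(m), i)
    model <- tryCatch(fit_fn(take(X_like, rest), y[rest]),
                      error = function(e) {
                        stop(sprintf("leave-one-out fold %d failed: %s",
                                     i, conditionMessage(e)), call. = FALSE)
                      })
    out[i] <- as.numeric(predict_fn(model, take(X_like, i)))
  }
  out
}
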