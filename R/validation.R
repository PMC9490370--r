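# Model-quality statistics (Rc, Rp, RMSEC, RMSEP), spike recovery, and the
# cross-method comparison tables.

#' Pearson correlation between actual and calculated concentrations
#'
#' The linearity measure reported as Rc on the calibration set and Rp on
#' the prediction set.
#'
#' @param actual,predicted Numeric vectors of equal length >= 2.
#' @return Scalar in [-1, 1].
#' @export
correlation_r <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2L) {
    stop("need two equal-length vectors with >= 2 values", call. = FALSE)
  }
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(actual, predicted)
}

#' Root mean squared error (m-denominator)
#'
#' `sqrt(sum (y - yhat)^2 / m)` with no degrees-of-freedom correction;
#' applied to fitted values it is RMSEC, to test-set predictions RMSEP, and
#' to cross-validated predictions it coincides with [rmsecv()].
#'
#' @param actual,predicted Numeric vectors of equal length >= 1.
#' @return Non-negative scalar (ug/ml when inputs are concentrations).
#' @export
rmse <- function(actual, predicted) rmsecv(actual, predicted)

#' Spike recovery
#'
#' `recovery_pct = 100 (Con1 - Con0) / Cons`: the percentage of a known
#' added amount that the calibrated model sees. Values outside [0, 100] are
#' reported as-is.
#'
#' @param con1 Calculated concentration of the spiked sample (ug/ml).
#' @param con0 Calculated concentration of the unspiked sample (ug/ml).
#' @param cons Spike amount added (ug/ml), > 0.
#' @param sample_id,analyte Optional labels carried into the result.
#' @return A `recovery_result` (also a one-row data frame) with fields
#'   `con1`, `con0`, `cons`, `recovery_pct`.
#' @export
recovery <- function(con1, con0, cons, sample_id = NA_character_,
                     analyte = NA_character_) {
  if (any(cons <= 0)) stop("spike amount must be positive", call. = FALSE)
  out <- data.frame(sample_id = sample_id, analyte = analyte,
                    con0 = con0, con1 = con1, cons = cons,
                    recovery_pct = 100 * (con1 - con0) / cons)
  class(out) <- c("recovery_result", class(out))
  out
}

#' Evaluate a fitted calibration model on calibration and prediction sets
#'
#' Computes the four headline statistics: Rc and RMSEC from the fitted
#' calibration-set values, Rp and RMSEP from the prediction-set values.
#' Replicate measurements of one physical sample (duplicated ids in
#' `pred_ids`) are averaged on the predicted-concentration scale before the
#' metrics are formed.
#'
#' @param model A fitted `lar_model`, `ipls_model`, or `npls_model` (or any
#'   object with a `predict` method taking the representation used here).
#' @param cal_x,pred_x Model inputs for the two sets: contour matrices for
#'   LAR/iPLS, cubes for N-PLS. `pred_x` may be NULL for a
#'   calibration-only report.
#' @param cal_y,pred_y Actual concentrations.
#' @param analyte,method Labels for the report.
#' @param cal_ids,pred_ids Optional sample ids; duplicates are treated as
#'   replicates and averaged.
#' @return A `validation_report` with `Rc`, `RMSEC`, `Rp`, `RMSEP` and the
#'   per-sample actual/predicted pairs of both sets.
#' @export
evaluate_model <- function(model, cal_x, cal_y, pred_x = NULL, pred_y = NULL,
                           analyte = "analyte", method = class(model)[1],
                           cal_ids = NULL, pred_ids = NULL) {
  avg_replicates <- function(ids, actual, predicted) {
    if (is.null(ids)) ids <- as.character(seq_along(actual))
    agg <- function(v) as.numeric(tapply(v, factor(ids, levels = unique(ids)), mean))
    data.frame(sample_id = unique(ids), actual = agg(actual),
               predicted = agg(predicted))
  }
  cal_pred <- as.numeric(stats::predict(model, cal_x))
  cal_tab <- avg_replicates(cal_ids, cal_y, cal_pred)
  out <- list(analyte = analyte, method = method,
              Rc = correlation_r(cal_tab$actual, cal_tab$predicted),
              RMSEC = rmse(cal_tab$actual, cal_tab$predicted),
              Rp = NA_real_, RMSEP = NA_real_,
              calibration = cal_tab, prediction = NULL,
              prediction_empty = is.null(pred_x))
  if (!is.null(pred_x)) {
    pred_pred <- as.numeric(stats::predict(model, pred_x))
    pred_tab <- avg_replicates(pred_ids, pred_y, pred_pred)
    out$Rp <- correlation_r(pred_tab$actual, pred_tab$predicted)
    out$RMSEP <- rmse(pred_tab$actual, pred_tab$predicted)
    out$prediction <- pred_tab
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s / %s\n", x$method, x$analyte))
  cat(sprintf("  Rc = %.4f, RMSEC = %.4f", x$Rc, x$RMSEC))
  if (!x$prediction_empty) {
    cat(sprintf(";  Rp = %.4f, RMSEP = %.4f", x$Rp, x$RMSEP))
  } else {
    cat("  (no prediction set)")
  }
  cat("\n")
  invisible(x)
}

#' Cross-method comparison tables
#'
#' Assembles validation reports into a long-format statistics table
#' (method x analyte x statistic) and binds the recovery results into one
#' recovery table, the shape in which multi-method EEM calibration studies
#' tabulate their results.
#'
#' @param reports List of `validation_report` objects.
#' @param recoveries Optional list (or data frame) of `recovery_result`
#'   rows, each carrying a `method` column.
#' @return List of data frames `statistics` (columns method, analyte,
#'   statistic, value) and `recoveries`.
#' @export
compare_methods <- function(reports, recoveries = NULL) {
  if (length(reports) == 0L) stop("need at least one report", call. = FALSE)
  stats_tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r$method, analyte = r$analyte,
               statistic = c("Rc", "RMSEC", "Rp", "RMSEP"),
               value = c(r$Rc, r$RMSEC, r$Rp, r$RMSEP))
  }))
  rec_tab <- if (is.null(recoveries)) {
    NULL
  } else if (is.data.frame(recoveries)) {
    recoveries
  } else {
    do.call(rbind, recoveries)
  }
  list(statistics = stats_tab, recoveries = rec_tab)
}

#' Actual-vs-calculated scatter plot for a validation report
#'
#' @param x A `validation_report`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.validation_report <- function(x, ...) {
  cal <- x$calibration
  prd <- x$prediction
  all_v <- c(cal$actual, cal$predicted, prd$actual, prd$predicted)
  graphics::plot(cal$actual, cal$predicted, pch = 16,
                 xlim = range(all_v), ylim = range(all_v),
                 xlab = "actual concentration (ug/ml)",
                 ylab = "calculated concentration (ug/ml)",
                 main = sprintf("%s / %s", x$method, x$analyte), ...)
  if (!is.null(prd)) graphics::points(prd$actual, prd$predicted, pch = 1, col = 2)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
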