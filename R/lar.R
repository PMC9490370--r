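# Lasso regression on contour vectors: penalized least squares with an L1
# constraint, which zeroes the coefficients of uninformative emission
# wavelengths and leaves a sparse, interpretable calibration equation
# C = b0 + sum_lambda b(lambda) V_lambda.

#' Fit a lasso calibration model on contour values
#'
#' Solves the Lagrangian lasso
#' `min_b0,b (1/(2m)) ||y - b0 - X b||^2 + penalty * ||b||_1`
#' by cyclic coordinate descent on standardized predictors (columns centered
#' and scaled to unit population sd; y centered), with coefficients
#' back-transformed to the raw intensity scale. Sufficiently large penalties
#' drive coefficients exactly to zero; wavelengths with zero coefficient are
#' dropped from the model.
#'
#' @param X Matrix, samples x emission variables; column names (emission nm)
#'   are carried into the coefficient map.
#' @param y Concentrations (ug/ml), one per row of X.
#' @param penalty Non-negative regularization strength.
#' @param tol Convergence threshold on the maximum standardized-coefficient
#'   change per sweep.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @return A `lar_model`: `intercept`, named `coefficients` (only nonzero
#'   entries), `penalty`, and the full-universe coefficient vector `beta`.
#' @export
lar_fit <- function(X, y, penalty, tol = 1e-10, max_iter = 100000L) {
  lar_path(X, y, penalty, tol = tol, max_iter = max_iter)[[1]]
}

#' Fit lasso models along a penalty path with warm starts
#'
#' Fits [lar_fit()]'s problem at each penalty, reusing the previous
#' solution as the starting point (penalties are processed in decreasing
#' order internally), which is substantially faster than independent fits.
#'
#' @inheritParams lar_fit
#' @param penalties Non-negative penalty values.
#' @return List of `lar_model` objects, in the order of `penalties`.
#' @export
lar_path <- function(X, y, penalties, tol = 1e-10, max_iter = 100000L) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (m < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(penalties < 0)) stop("penalty must be >= 0", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  ybar <- mean(y)
  yc <- y - ybar
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  scale <- sqrt(colMeans(Xc^2))
  active_cols <- which(scale > 0)
  degenerate <- stats::var(y) == 0 || length(active_cols) == 0L

  models <- vector("list", length(penalties))
  ord <- order(penalties, decreasing = TRUE)
  if (!degenerate) {
    Xs <- sweep(Xc[, active_cols, drop = FALSE], 2, scale[active_cols], `/`)
    G <- crossprod(Xs) / m           # Gram matrix for covariance updates
    xy <- as.numeric(crossprod(Xs, yc)) / m
    b <- numeric(ncol(Xs))
  }
  for (idx in ord) {
    beta_orig <- stats::setNames(numeric(ncol(X)), colnames(X))
    if (!degenerate) {
      b <- lar_cd(G, xy, Xs, yc, penalties[idx], b, tol, max_iter)
      beta_orig[active_cols] <- b / scale[active_cols]
    }
    intercept <- ybar - sum(xbar * beta_orig)
    nz <- beta_orig[beta_orig != 0]
    models[[idx]] <- structure(
      list(intercept = intercept, coefficients = nz,
           beta = beta_orig, penalty = penalties[idx],
           variables = colnames(X),
           x_center = xbar, y_center = ybar, x_scale = scale),
      class = "lar_model")
  }
  models
}

# Cyclic coordinate descent with covariance (Gram) updates; the compiled
# kernel maintains g = xy - G b = (1/m) X'r incrementally and stops when
# the maximum coefficient change over a full sweep is <= tol or the duality
# gap of the penalized objective drops below 1e-8 relative to the null
# objective.
lar_cd <- function(G, xy, Xs, yc, lambda, b, tol, max_iter) {
  .lar_cd_cpp(G, xy, Xs, yc, lambda, b, tol, as.integer(max_iter))
}

soft_threshold <- function(z, gamma) sign(z) * max(abs(z) - gamma, 0)

#' Smallest penalty that zeroes every lasso coefficient
#'
#' `lambda_max = max_j |(1/m) <x_j, y - ybar>|` on standardized predictors;
#' at or above it [lar_fit()] returns the null model (intercept = mean y).
#'
#' @inheritParams lar_fit
#' @return Non-negative scalar.
#' @export
lar_lambda_max <- function(X, y) {
  X <- as.matrix(X)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  scale <- sqrt(colMeans(Xc^2))
  keep <- scale > 0
  if (!any(keep) || stats::var(y) == 0) return(0)
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, scale[keep], `/`)
  max(abs(crossprod(Xs, yc)) / nrow(X))
}

#' Verify the lasso subgradient (KKT) conditions of a fitted model
#'
#' On the standardized problem the optimum satisfies
#' `(1/m) <x_j, r> = penalty * sign(b_j)` for active coordinates and
#' `|(1/m) <x_j, r>| <= penalty` for zero ones. Returns the largest
#' violation, which should be ~0 for a converged fit.
#'
#' @param model A `lar_model`.
#' @param X,y The training data.
#' @return Maximum absolute KKT violation (scalar).
#' @export
lar_kkt_violation <- function(model, X, y) {
  X <- as.matrix(X)
  m <- nrow(X)
  keep <- model$x_scale > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, model$x_center[keep]),
              2, model$x_scale[keep], `/`)
  b_std <- model$beta[keep] * model$x_scale[keep]
  r <- (y - model$y_center) - Xs %*% b_std
  g <- as.numeric(crossprod(Xs, r)) / m
  viol <- ifelse(b_std != 0,
                 abs(g - model$penalty * sign(b_std)),
                 pmax(abs(g) - model$penalty, 0))
  if (length(viol) == 0L) 0 else max(viol)
}

#' Select the lasso penalty by leave-one-out RMSECV
#'
#' Evaluates a log-spaced penalty grid from `lambda_max` down four decades,
#' computes leave-one-out RMSECV at each point, and returns the minimizer
#' (ties go to the larger penalty, i.e. the sparser model).
#'
#' @inheritParams lar_fit
#' @param grid_size Number of penalty values (>= 2).
#' @return List: `penalty` (selected), `cv_curve` (data frame of penalty and
#'   rmsecv), and `model` (the fit at the selected penalty).
#' @export
select_penalty <- function(X, y, grid_size = 30L) {
  if (grid_size < 2L) stop("grid_size must be >= 2", call. = FALSE)
  lmax <- lar_lambda_max(X, y)
  if (lmax == 0) lmax <- 1e-3
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = grid_size))
  # one warm-started path per leave-one-out fold covers the whole grid
  X <- as.matrix(X)
  m <- nrow(X)
  preds <- matrix(NA_real_, m, grid_size)
  for (i in seq_len(m)) {
    rest <- setdiff(seq_len(m), i)
    path <- tryCatch(lar_path(X[rest, , drop = FALSE], y[rest], grid),
                     error = function(e) {
                       stop(sprintf("leave-one-out fold %d failed: %s",
                                    i, conditionMessage(e)), call. = FALSE)
                     })
    preds[i, ] <- vapply(path, function(mod) {
      as.numeric(lar_predict(mod, X[i, , drop = FALSE]))
    }, 0)
  }
  curve <- vapply(seq_len(grid_size), function(k) rmsecv(y, preds[, k]), 0)
  best <- which.min(curve)  # first index = largest penalty among ties
  list(penalty = grid[best],
       cv_curve = data.frame(penalty = grid, rmsecv = curve),
       model = lar_fit(X, y, grid[best]))
}

#' Predict concentrations from contour vectors
#'
#' Applies the sparse affine formula `C = b0 + sum_lambda b(lambda)
#' V_lambda`. Predictions may be negative (recovery arithmetic needs the raw
#' values); a `negative` attribute flags them.
#'
#' @param model A `lar_model`.
#' @param contours Matrix (samples x emission variables) or a single contour
#'   vector whose length matches the model's variable universe.
#' @return Numeric vector of predicted concentrations (ug/ml).
#' @export
lar_predict <- function(model, contours) {
  if (is.null(dim(contours))) contours <- matrix(contours, nrow = 1)
  contours <- as.matrix(contours)
  if (ncol(contours) != length(model$beta)) {
    stop(sprintf("contour length %d does not match model universe %d",
                 ncol(contours), length(model$beta)), call. = FALSE)
  }
  pred <- as.numeric(model$intercept + contours %*% model$beta)
  attr(pred, "negative") <- any(pred < 0)
  pred
}

#' @export
predict.lar_model <- function(object, newdata, ...) lar_predict(object, newdata)

#' @export
print.lar_model <- function(x, ...) {
  cat(sprintf("<lar_model> penalty %.4g, %d nonzero wavelengths, intercept %.4g\n",
              x$penalty, length(x$coefficients), x$intercept))
  invisible(x)
}
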