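# Interval PLS: equal-width subintervals of the contour spectrum, one local
# PLS1 model per interval, and joint selection of the (interval, component
# count) pair with minimum leave-one-out RMSECV.

#' Partition spectral variables into equal-width intervals
#'
#' Splits `n_variables` contiguous variables into `n_intervals` contiguous,
#' disjoint, exhaustive intervals whose sizes differ by at most one; when
#' the division is not exact the remainder goes to the trailing intervals
#' (41 variables in 8 intervals gives seven of width 5 and a final width 6).
#'
#' @param n_variables Number of spectral variables.
#' @param n_intervals Number of intervals, `1 <= n_intervals <= n_variables`.
#' @return An `interval_scheme` with a data frame `bounds` of 1-based
#'   inclusive `start`/`end` indices.
#' @export
make_intervals <- function(n_variables, n_intervals) {
  n_variables <- as.integer(n_variables)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L || n_intervals > n_variables) {
    stop("need 1 <= n_intervals <= n_variables", call. = FALSE)
  }
  base <- n_variables %/% n_intervals
  r <- n_variables %% n_intervals
  sizes <- c(rep(base, n_intervals - r), rep(base + 1L, r))
  end <- cumsum(sizes)
  start <- c(1L, utils::head(end, -1L) + 1L)
  structure(list(n_variables = n_variables, n_intervals = n_intervals,
                 bounds = data.frame(interval = seq_len(n_intervals),
                                     start = start, end = end,
                                     width = sizes)),
            class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf("<interval_scheme> %d variables in %d intervals (widths %s)\n",
              x$n_variables, x$n_intervals,
              paste(x$bounds$width, collapse = ", ")))
  invisible(x)
}

#' Fit a PLS1 model (NIPALS)
#'
#' Standard single-response partial least squares on column-centered X and
#' centered y: per component, the weight is the covariance direction
#' `w = X'y/||X'y||`, scores `t = Xw`, loadings `p = X't/(t't)`,
#' `q = y't/(t't)`, then X and y are deflated. The regression vector is
#' `b = W (P'W)^-1 q`.
#'
#' @param X Matrix, samples x variables.
#' @param y Numeric response.
#' @param n_components Number of latent components,
#'   `1 <= n_components <= min(nrow - 1, ncol)`.
#' @return A `pls1_model` with the regression vector and centering offsets.
#' @export
pls1_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(m - 1L, ncol(X))) {
    stop(sprintf("n_components must be in [1, %d]", min(m - 1L, ncol(X))),
         call. = FALSE)
  }
  xbar <- colMeans(X)
  ybar <- mean(y)
  E <- sweep(X, 2, xbar)
  f <- y - ybar
  p_var <- ncol(X)
  W <- P <- matrix(0, p_var, n_components)
  q <- numeric(n_components)
  a_used <- 0L
  # degeneracy thresholds relative to the data scale, so exhausted residual
  # structure (all-zero intervals, constant y) ends extraction cleanly
  w_scale <- sqrt(sum(crossprod(E, f)^2))
  t_scale <- sum(E^2)
  for (a in seq_len(n_components)) {
    w <- as.numeric(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(w_scale, 1e-300)) break
    w <- w / nw
    t_sc <- as.numeric(E %*% w)
    tt <- sum(t_sc^2)
    if (tt <= 1e-24 * max(t_scale, 1e-300)) break
    p_load <- as.numeric(crossprod(E, t_sc)) / tt
    q_a <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - t_sc * q_a
    W[, a] <- w; P[, a] <- p_load; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) {
    b <- numeric(p_var)
  } else {
    Wa <- W[, seq_len(a_used), drop = FALSE]
    Pa <- P[, seq_len(a_used), drop = FALSE]
    PtW <- crossprod(Pa, Wa)
    g <- tryCatch(solve(PtW, q[seq_len(a_used)]),
                  error = function(e) qr.coef(qr(PtW), q[seq_len(a_used)]))
    g[is.na(g)] <- 0
    b <- as.numeric(Wa %*% g)
  }
  structure(list(n_components = a_used, coefficients = b,
                 x_center = xbar, y_center = ybar,
                 intercept = ybar - sum(xbar * b)),
            class = "pls1_model")
}

#' Predict from a PLS1 model
#' @param model A `pls1_model`.
#' @param X Matrix (samples x variables) or a single spectrum vector.
#' @return Numeric predictions.
#' @export
pls1_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients)) {
    stop("variable count does not match the fitted model", call. = FALSE)
  }
  as.numeric(model$intercept + X %*% model$coefficients)
}

#' @export
predict.pls1_model <- function(object, newdata, ...) pls1_predict(object, newdata)

#' Joint interval/component selection by minimum RMSECV
#'
#' For every interval of the scheme and every admissible component count
#' (capped by the interval width, `m - 2`, and `max_components`), fits the
#' local PLS1 model under leave-one-out cross-validation and tabulates
#' RMSECV; the returned model is the exact argmin of that table. Ties are
#' broken toward fewer components, then the lower interval index.
#'
#' @param X Contour matrix, samples x variables.
#' @param y Concentrations.
#' @param scheme An `interval_scheme`; default 8 intervals.
#' @param max_components Upper bound on components considered (default 10).
#' @param wavelengths Optional variable wavelengths (nm) used to report the
#'   selected range.
#' @return An `ipls_model`: the selected interval and component count, the
#'   refitted local model, and the full `rmsecv_table`.
#' @export
ipls_select <- function(X, y, scheme = make_intervals(ncol(X), 8L),
                        max_components = 10L, wavelengths = NULL) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (max_components < 1L) stop("max_components must be >= 1", call. = FALSE)
  if (scheme$n_variables != ncol(X)) {
    stop("interval scheme does not match ncol(X)", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(scheme$n_intervals)) {
    b <- scheme$bounds[i, ]
    Xi <- X[, b$start:b$end, drop = FALSE]
    a_max <- min(max_components, b$width, m - 2L)
    for (a in seq_len(a_max)) {
      pred <- loo_predictions(function(Xt, yt) pls1_fit(Xt, yt, a),
                              function(mod, Xt) pls1_predict(mod, Xt),
                              Xi, y)
      rows[[length(rows) + 1L]] <- data.frame(interval = i, n_components = a,
                                              rmsecv = rmsecv(y, pred))
    }
  }
  tab <- do.call(rbind, rows)
  # argmin with ties broken by fewer components then lower interval index
  ord <- order(tab$rmsecv, tab$n_components, tab$interval)
  sel <- tab[ord[1], ]
  b <- scheme$bounds[sel$interval, ]
  local <- pls1_fit(X[, b$start:b$end, drop = FALSE], y, sel$n_components)
  range_nm <- if (!is.null(wavelengths)) {
    c(wavelengths[b$start], wavelengths[b$end])
  } else c(NA_real_, NA_real_)
  structure(list(scheme = scheme, selected_interval = sel$interval,
                 interval_start = b$start, interval_end = b$end,
                 wavelength_range = range_nm,
                 n_components = sel$n_components,
                 local = local, rmsecv_table = tab),
            class = "ipls_model")
}

#' Predict from an iPLS model
#' @param model An `ipls_model`.
#' @param X Full contour matrix (the model slices its own interval) or a
#'   single full contour vector.
#' @return Numeric predictions.
#' @export
ipls_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$scheme$n_variables) {
    stop("contour length does not match the fitted scheme", call. = FALSE)
  }
  pls1_predict(model$local, X[, model$interval_start:model$interval_end,
                              drop = FALSE])
}

#' @export
predict.ipls_model <- function(object, newdata, ...) ipls_predict(object, newdata)

#' @export
print.ipls_model <- function(x, ...) {
  rng <- if (all(is.finite(x$wavelength_range))) {
    sprintf(" (%g-%g nm)", x$wavelength_range[1], x$wavelength_range[2])
  } else ""
  cat(sprintf("<ipls_model> interval %d%s, %d component(s), RMSECV %.4g\n",
              x$selected_interval, rng, x$n_components,
              min(x$rmsecv_table$rmsecv)))
  invisible(x)
}
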