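# Trilinear N-PLS (tri-PLS1): PLS regression of one response on a
# three-way (sample x emission x excitation) cube. Each latent variable
# carries a unit-norm emission weight and a unit-norm excitation weight; the
# weight pair is the leading singular pair of the y-weighted covariance
# slab Z_jk = sum_i y_i X_ijk, scores are the cube's projections on the
# rank-1 weight matrix, and y is regressed on all scores accumulated so far.

# leading singular pair of a matrix with the deterministic sign convention:
# the largest-magnitude element of the left (emission) vector is positive,
# and the right vector is flipped with it so the rank-1 product is unchanged.
leading_singular_pair <- function(Z) {
  sv <- svd(Z, nu = 1, nv = 1)
  wj <- sv$u[, 1]
  wk <- sv$v[, 1]
  s <- sign(wj[which.max(abs(wj))])
  if (s < 0) { wj <- -wj; wk <- -wk }
  list(wj = wj, wk = wk, sigma = sv$d[1])
}

# scores of every sample of a (possibly deflated) cube on one weight pair
cube_scores <- function(cube, wj, wk) {
  n <- dim(cube)[1]
  vapply(seq_len(n), function(i) sum(cube[i, , ] * tcrossprod(wj, wk)), 0)
}

#' Fit a trilinear N-PLS (tri-PLS1) model
#'
#' The cube is centered across the sample mode (mean slab subtracted) and y
#' is centered; no scaling is applied. Per factor `f`: assemble
#' `Z = sum_i y_res,i X_res,i`, take its leading singular pair as the
#' emission/excitation weights `(w_J, w_K)` (both unit norm), compute scores
#' `t_i = <X_res,i, w_J w_K'>`, regress centered y on all scores so far,
#' then deflate the cube by `t (x) w_J (x) w_K` and y by its fit. The SVD
#' sign ambiguity is resolved by making the largest-magnitude element of
#' each `w_J` positive, so fitting is fully deterministic.
#'
#' @param cube 3-way array, samples x emission x excitation, or an
#'   `eem_dataset` (its cube is used).
#' @param y Concentrations, one per sample.
#' @param n_lv Number of latent variables, `1 <= n_lv <= samples - 1`.
#' @return An `npls_model`: weights `Wj`/`Wk` (columns per factor),
#'   per-factor regression coefficient history, centering offsets, and
#'   training scores.
#' @export
npls_fit <- function(cube, y, n_lv) {
  if (inherits(cube, "eem_dataset")) cube <- cube$cube
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  n <- dim(cube)[1]
  if (n != length(y)) stop("cube sample count must equal length(y)", call. = FALSE)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > n - 1L) {
    stop(sprintf("n_lv must be in [1, %d]", n - 1L), call. = FALSE)
  }
  J <- dim(cube)[2]; K <- dim(cube)[3]
  mean_slab <- apply(cube, c(2, 3), mean)
  ybar <- mean(y)
  Xr <- sweep(cube, c(2, 3), mean_slab)
  yc <- y - ybar
  yr <- yc
  Wj <- matrix(0, J, 0); Wk <- matrix(0, K, 0)
  Tmat <- matrix(0, n, 0)
  b_history <- list()
  f_used <- 0L
  for (f in seq_len(n_lv)) {
    Z <- matrix(0, J, K)
    for (i in seq_len(n)) Z <- Z + yr[i] * Xr[i, , ]
    if (sqrt(sum(Z^2)) < 1e-14) break  # nothing left correlated with y
    sp <- leading_singular_pair(Z)
    t_f <- cube_scores(Xr, sp$wj, sp$wk)
    Wj <- cbind(Wj, sp$wj); Wk <- cbind(Wk, sp$wk)
    Tmat <- cbind(Tmat, t_f)
    # regress centered y on all scores so far
    b <- tryCatch(as.numeric(solve(crossprod(Tmat), crossprod(Tmat, yc))),
                  error = function(e) as.numeric(qr.coef(qr(Tmat), yc)))
    b[is.na(b)] <- 0
    b_history[[f]] <- b
    yr <- yc - as.numeric(Tmat %*% b)
    # deflate the cube by the rank-1 factor
    WW <- tcrossprod(sp$wj, sp$wk)
    for (i in seq_len(n)) Xr[i, , ] <- Xr[i, , ] - t_f[i] * WW
    f_used <- f
  }
  if (f_used == 0L) b_history <- list(numeric(0))
  structure(list(n_lv = f_used, Wj = Wj, Wk = Wk,
                 b_history = b_history,
                 coefficients = b_history[[length(b_history)]],
                 mean_slab = mean_slab, y_center = ybar,
                 scores = Tmat),
            class = "npls_model")
}

#' Predict concentrations from an N-PLS model
#'
#' Each sample is centered with the training mean slab, scores are computed
#' through the stored deflation pipeline (same weights, same order as in
#' fitting), and the regression coefficients plus the training mean of y
#' give the prediction. Applying the model to its own training cube
#' reproduces the training fitted values exactly.
#'
#' @param model An `npls_model`.
#' @param cube 3-way array (samples x emission x excitation), a single
#'   emission x excitation matrix, or an `eem_dataset`.
#' @param n_lv Number of latent variables to use (defaults to the fitted
#'   count; must not exceed it).
#' @return Numeric vector of predicted concentrations.
#' @export
npls_predict <- function(model, cube, n_lv = model$n_lv) {
  if (inherits(cube, "eem_dataset")) cube <- cube$cube
  if (is.matrix(cube)) cube <- array(cube, dim = c(1, dim(cube)))
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  if (dim(cube)[2] != nrow(model$mean_slab) ||
      dim(cube)[3] != ncol(model$mean_slab)) {
    stop("cube emission/excitation axes do not match the trained model",
         call. = FALSE)
  }
  if (model$n_lv == 0L) {
    return(rep(model$y_center, dim(cube)[1]))
  }
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > model$n_lv) {
    stop(sprintf("n_lv must be in [1, %d]", model$n_lv), call. = FALSE)
  }
  n <- dim(cube)[1]
  Xr <- sweep(cube, c(2, 3), model$mean_slab)
  Tmat <- matrix(0, n, n_lv)
  for (f in seq_len(n_lv)) {
    t_f <- cube_scores(Xr, model$Wj[, f], model$Wk[, f])
    Tmat[, f] <- t_f
    WW <- tcrossprod(model$Wj[, f], model$Wk[, f])
    for (i in seq_len(n)) Xr[i, , ] <- Xr[i, , ] - t_f[i] * WW
  }
  b <- model$b_history[[n_lv]]
  as.numeric(model$y_center + Tmat %*% b)
}

#' @export
predict.npls_model <- function(object, newdata, ...) npls_predict(object, newdata)

#' @export
print.npls_model <- function(x, ...) {
  cat(sprintf("<npls_model> %d latent variable(s), %d x %d weight grid\n",
              x$n_lv, nrow(x$Wj), nrow(x$Wk)))
  invisible(x)
}

#' Select the number of latent variables by cross-validated PRESS
#'
#' Leave-one-out cross-validation: for each left-out sample a model with
#' `max_lv` factors is fitted on the rest and the held-out sample is
#' predicted with every truncation `a = 1..max_lv`; `PRESS(a)` is the sum of
#' squared held-out errors. The default rule takes the global minimum of
#' the curve; `rule = "local"` takes the first local minimum (the first `a`
#' whose PRESS is below both neighbours, the convention sometimes used when
#' the curve keeps creeping down with overfit factors).
#'
#' @param cube 3-way array or `eem_dataset`.
#' @param y Concentrations.
#' @param max_lv Largest latent-variable count examined (capped at
#'   samples - 2 so every fold can fit it).
#' @param rule `"global"` or `"local"`.
#' @return List: `n_lv` (selected), `press_curve` (data frame of n_lv and
#'   press), `rule`.
#' @export
select_lv_by_press <- function(cube, y, max_lv = 8L, rule = c("global", "local")) {
  rule <- match.arg(rule)
  if (inherits(cube, "eem_dataset")) cube <- cube$cube
  n <- dim(cube)[1]
  if (max_lv < 1L) stop("max_lv must be >= 1", call. = FALSE)
  max_lv <- min(as.integer(max_lv), n - 2L)
  preds <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    model <- npls_fit(cube[rest, , , drop = FALSE], y[rest], max_lv)
    for (a in seq_len(max_lv)) {
      a_eff <- min(a, model$n_lv)
      preds[i, a] <- if (a_eff == 0L) model$y_center else {
        npls_predict(model, cube[i, , , drop = FALSE], n_lv = a_eff)
      }
    }
  }
  curve <- vapply(seq_len(max_lv), function(a) press(y, preds[, a]), 0)
  # floating-point tie-break: among PRESS values indistinguishable from the
  # minimum (within a tiny tolerance), take the fewest latent variables
  tol <- 1e-9 * max(curve, .Machine$double.xmin)
  n_lv <- if (rule == "global" || max_lv <= 2L) {
    which(curve <= min(curve) + tol)[1]
  } else {
    loc <- which(vapply(seq_len(max_lv), function(a) {
      left_ok <- a == 1L || curve[a] < curve[a - 1L]
      right_ok <- a == max_lv || curve[a] < curve[a + 1L]
      left_ok && right_ok
    }, TRUE))
    if (length(loc)) loc[1] else which.min(curve)
  }
  list(n_lv = as.integer(n_lv),
       press_curve = data.frame(n_lv = seq_len(max_lv), press = curve),
       rule = rule)
}
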