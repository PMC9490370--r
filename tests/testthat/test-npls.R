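# helper: random cube and a y correlated with it
random_cube <- function(n, J, K, seed) {
  set.seed(seed)
  array(rnorm(n * J * K), dim = c(n, J, K))
}

test_that("one latent variable fits rank-1 trilinear data exactly", {
  set.seed(14)
  conc <- runif(10, 0.1, 2)
  wj <- abs(rnorm(7)); wk <- abs(rnorm(5))
  cube <- array(0, c(10, 7, 5))
  for (i in 1:10) cube[i, , ] <- conc[i] * tcrossprod(wj, wk)
  m <- npls_fit(cube, conc, 1)
  expect_equal(npls_predict(m, cube), conc, tolerance = 1e-8)
})

test_that("first-factor weights match the SVD of the assembled Z matrix", {
  cube <- random_cube(5, 6, 7, seed = 21)
  set.seed(22)
  y <- rnorm(5)
  m <- npls_fit(cube, y, 2)
  # independent assembly: Z = sum_i yc_i * Xc_i on centered data
  yc <- y - mean(y)
  Xc <- sweep(cube, c(2, 3), apply(cube, c(2, 3), mean))
  Z <- matrix(0, 6, 7)
  for (i in 1:5) Z <- Z + yc[i] * Xc[i, , ]
  sv <- svd(Z)
  expect_lt(min(max(abs(m$Wj[, 1] - sv$u[, 1])),
                max(abs(m$Wj[, 1] + sv$u[, 1]))), 1e-8)
  expect_lt(min(max(abs(m$Wk[, 1] - sv$v[, 1])),
                max(abs(m$Wk[, 1] + sv$v[, 1]))), 1e-8)
})

test_that("weights are unit norm and the sign convention fixes the fit", {
  cube <- random_cube(8, 5, 6, seed = 31)
  set.seed(32)
  y <- rnorm(8)
  m <- npls_fit(cube, y, 3)
  for (f in 1:3) {
    expect_equal(sum(m$Wj[, f]^2), 1, tolerance = 1e-10)
    expect_equal(sum(m$Wk[, f]^2), 1, tolerance = 1e-10)
    expect_gt(m$Wj[which.max(abs(m$Wj[, f])), f], 0)
  }
  m2 <- npls_fit(cube, y, 3)
  expect_identical(m$Wj, m2$Wj)
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("degenerate cubes predict the mean response", {
  cube <- array(5, c(6, 4, 4))  # constant: centered cube is all zero
  y <- c(1, 2, 3, 4, 5, 6)
  m <- npls_fit(cube, y, 2)
  expect_equal(m$n_lv, 0L)
  expect_equal(npls_predict(m, cube), rep(mean(y), 6))
})

test_that("predicting the training cube reproduces the fitted values", {
  cube <- random_cube(9, 6, 5, seed = 41)
  set.seed(42)
  y <- rnorm(9)
  m <- npls_fit(cube, y, 3)
  fitted_vals <- m$y_center + as.numeric(m$scores %*% m$coefficients)
  expect_equal(npls_predict(m, cube), fitted_vals, tolerance = 1e-10)
})

test_that("a sample equal to the training mean slab predicts mean(y)", {
  cube <- random_cube(7, 5, 5, seed = 51)
  set.seed(52)
  y <- rnorm(7)
  m <- npls_fit(cube, y, 2)
  mean_slab <- apply(cube, c(2, 3), mean)
  expect_equal(as.numeric(npls_predict(m, mean_slab)), mean(y),
               tolerance = 1e-10)
})

test_that("training residuals are non-increasing in the latent count", {
  cube <- random_cube(10, 6, 6, seed = 61)
  set.seed(62)
  y <- rnorm(10)
  rss <- vapply(1:5, function(a) {
    m <- npls_fit(cube, y, a)
    sum((y - npls_predict(m, cube))^2)
  }, 0)
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("axis mismatches and invalid LV counts are rejected", {
  cube <- random_cube(6, 5, 4, seed = 71)
  y <- rnorm(6)
  m <- npls_fit(cube, y, 2)
  expect_error(npls_predict(m, random_cube(2, 4, 5, seed = 1)), "axes")
  expect_error(npls_fit(cube, y, 6), "n_lv")
  expect_error(npls_fit(cube, rnorm(5), 2), "sample count")
})

test_that("two overlapping analytes are resolved with two latent variables", {
  d <- noiseless_design(seed = 9)
  sp <- split_calibration(generate_dataset(d))
  for (a in c("A", "B")) {
    m <- npls_fit(sp$calibration, sp$calibration$concentrations[[a]], 2)
    pred <- npls_predict(m, sp$prediction)
    truth <- sp$prediction$concentrations[[a]]
    expect_lt(max(abs(pred - truth) / abs(truth)), 1e-6)
  }
})

test_that("PRESS selects two latent variables for a noiseless binary mixture", {
  d <- noiseless_design(n_samples = 16, seed = 5)
  ds <- generate_dataset(d)
  sel <- select_lv_by_press(ds, ds$concentrations$A, max_lv = 6)
  expect_equal(sel$n_lv, 2L)
  expect_true(all(sel$press_curve$press >= 0))
  expect_equal(nrow(sel$press_curve), 6)
  # single-candidate boundary case
  one <- select_lv_by_press(ds, ds$concentrations$A, max_lv = 1)
  expect_equal(one$n_lv, 1L)
})

test_that("the local-minimum rule picks the first dip of the PRESS curve", {
  d <- simulation_design(seed = 3)
  ds <- generate_dataset(d)
  std <- preprocess_dataset(ds, build_scatter_mask(d$grid))
  y <- std$concentrations$A
  glob <- select_lv_by_press(std, y, max_lv = 6, rule = "global")
  loc <- select_lv_by_press(std, y, max_lv = 6, rule = "local")
  expect_identical(glob$press_curve, loc$press_curve)
  expect_lte(loc$n_lv, glob$n_lv)
  cv <- loc$press_curve$press
  k <- loc$n_lv
  if (k > 1) expect_lt(cv[k], cv[k - 1])
  if (k < length(cv)) expect_lt(cv[k], cv[k + 1])
})
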