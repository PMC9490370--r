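test_that("scatter mask ridge cells are counted correctly on the 10 nm grid", {
  g <- default_grid()
  # first-order band of half-width 10 nm: the diagonal plus one off-diagonal
  # on each side
  m <- build_scatter_mask(g, w1 = 10, w2 = 0, wR = 0)
  expect_equal(sum(m$components$first_order), 41 + 40 + 40)
  # zero widths keep exactly the ridge lines
  m0 <- build_scatter_mask(g, w1 = 0, w2 = 0, wR = 0)
  expect_equal(sum(m0$components$first_order), 41)
  expect_true(all(which(m0$components$first_order) ==
                    which(outer(g$emission, g$excitation, `==`))))
  # second-order line em = 2 ex stays on the grid only for ex <= 300
  expect_equal(sum(m0$components$second_order), 11)
  # the Raman line at 3400 cm-1 passes through no exact grid point
  expect_equal(sum(m0$components$raman), 0)
  expect_error(build_scatter_mask(g, w1 = -1), ">= 0")
})

test_that("mask growth is monotone in the widths", {
  g <- default_grid()
  small <- build_scatter_mask(g, 5, 5, 5)
  for (m2 in list(build_scatter_mask(g, 15, 5, 5),
                  build_scatter_mask(g, 5, 25, 5),
                  build_scatter_mask(g, 5, 5, 20))) {
    expect_true(all(m2$mask[small$mask]))
  }
})

test_that("infill reproduces affine surfaces exactly on interior cells", {
  g <- default_grid()
  plane <- outer(g$emission, g$excitation, function(em, ex) {
    3.5 * em - 1.25 * ex + 40
  })
  l <- eem_landscape(g, plane, "plane")
  mask <- build_scatter_mask(g)  # default widths
  out <- excise_and_interpolate(l, mask)
  for (k in seq_along(g$excitation)) {
    mk <- mask$mask[, k]
    if (!any(mk)) next
    anchors <- g$emission[!mk]
    interior <- mk & g$emission >= min(anchors) & g$emission <= max(anchors)
    expect_lt(max(abs(out$intensity[interior, k] - plane[interior, k]), 0),
              1e-9)
    # masked cells beyond the outermost anchors hold the anchor value
    below <- mk & g$emission < min(anchors)
    if (any(below)) {
      expect_equal(unname(out$intensity[below, k]),
                   rep(plane[which(!mk)[1], k], sum(below)))
    }
  }
})

test_that("an empty mask leaves the landscape untouched", {
  g <- default_grid()
  set.seed(2)
  l <- eem_landscape(g, matrix(rnorm(41 * 41), 41, 41), "s")
  none <- build_scatter_mask(g, 0, 0, 0)
  none$mask[] <- FALSE
  out <- excise_and_interpolate(l, none)
  expect_identical(out$intensity, l$intensity)
})

test_that("triangle zeroing clears below-diagonal cells outside the bands", {
  g <- default_grid()
  l <- eem_landscape(g, matrix(1, 41, 41), "s")
  mask <- build_scatter_mask(g)
  out <- zero_nonfluorescent(l, mask)
  tri <- outer(g$emission, g$excitation, `<`)
  expect_true(all(out$intensity[tri & !mask$mask] == 0))
  expect_true(all(out$intensity[!tri] == 1))
  expect_true(all(out$intensity[tri & mask$mask] == 1))
})

test_that("excision + infilling is idempotent", {
  d <- simulation_design(seed = 8)
  l <- simulate_eem(list(A = 0.5, B = 2), d)
  mask <- build_scatter_mask(d$grid)
  once <- excise_and_interpolate(l, mask)
  twice <- excise_and_interpolate(once, mask)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-12)
})

test_that("masking plus infilling restores a scatter-laden landscape", {
  # reference standard mixture: 0.16 ug/ml of A with 1.0 ug/ml of B
  d_clean <- noiseless_design(n_samples = 2, seed = 31)
  d_dirty <- simulation_design(n_samples = 2, noise_sd = 0, seed = 31)
  conc <- list(A = 0.16, B = 1.0)
  clean <- simulate_eem(conc, d_clean)
  dirty <- simulate_eem(conc, d_dirty)
  mask <- build_scatter_mask(d_dirty$grid)
  fixed <- excise_and_interpolate(dirty, mask)
  peak <- max(clean$intensity)
  expect_lt(max(abs(fixed$intensity - clean$intensity)) / peak, 0.05)
})

test_that("dataset-level preprocessing equals the per-landscape operations", {
  d <- simulation_design(n_samples = 4, seed = 23)
  ds <- generate_dataset(d)
  mask <- build_scatter_mask(d$grid)
  fast <- preprocess_dataset(ds, mask)
  for (i in seq_len(n_samples(ds))) {
    slow <- zero_nonfluorescent(
      excise_and_interpolate(dataset_landscape(ds, i), mask), mask)
    expect_equal(fast$cube[i, , ], unname(slow$intensity), tolerance = 1e-9)
  }
})

test_that("contour extraction returns the stated excitation column", {
  g <- default_grid()
  zero <- eem_landscape(g, matrix(0, 41, 41), "z")
  cz <- extract_contour(zero, contour_policy("fixed", excitation = 300))
  expect_equal(cz$values, rep(0, 41))
  expect_equal(cz$excitation_used, 300)

  set.seed(9)
  l <- eem_landscape(g, matrix(runif(41 * 41), 41, 41), "r")
  c340 <- extract_contour(l, contour_policy("fixed", excitation = 340))
  expect_equal(c340$values, unname(l$intensity[, g$excitation == 340]))
  expect_length(c340$values, 41)
  expect_error(extract_contour(l, contour_policy("fixed", excitation = 345)),
               "not on the grid")
})

test_that("max-energy contour of a single analyte matches its emission profile", {
  d <- single_analyte_design()
  l <- simulate_eem(list(A = 0.5), d)
  ct <- extract_contour(l, contour_policy("max_energy"))
  emp <- d$analytes$A$emission_profile$values
  cosine <- sum(ct$values * emp) / sqrt(sum(ct$values^2) * sum(emp^2))
  expect_gte(cosine, 0.999)
})

test_that("dataset contours share one excitation chosen on calibration samples", {
  d <- simulation_design(n_samples = 6, seed = 19)
  ds <- generate_dataset(d)
  cc <- extract_contours(ds, contour_policy("max_energy"))
  expect_equal(dim(cc$X), c(6, 41))
  k <- which(ds$grid$excitation == cc$excitation_used)
  expect_equal(unname(cc$X[3, ]), ds$cube[3, , k])
})

test_that("calibration split sizes follow round-half-up with clamping", {
  mk <- function(n, seed = 1) generate_dataset(noiseless_design(n, seed))
  s21 <- split_calibration(mk(21), 3 / 4)
  expect_equal(n_samples(s21$calibration), 16)
  expect_equal(n_samples(s21$prediction), 5)
  s20 <- split_calibration(mk(20), 3 / 4)
  expect_equal(n_samples(s20$calibration), 15)
  expect_equal(n_samples(s20$prediction), 5)
  s2 <- split_calibration(mk(2), 0.99)
  expect_equal(n_samples(s2$calibration), 1)
  expect_equal(n_samples(s2$prediction), 1)
})

test_that("split parts are disjoint, exhaustive, and span the range", {
  ds <- generate_dataset(simulation_design(n_samples = 21, seed = 29))
  sp <- split_calibration(ds)
  ids <- c(sp$calibration$concentrations$sample_id,
           sp$prediction$concentrations$sample_id)
  expect_setequal(ids, ds$concentrations$sample_id)
  expect_equal(anyDuplicated(ids), 0L)
  # deterministic given the dataset
  sp2 <- split_calibration(ds)
  expect_identical(sp$prediction$concentrations$sample_id,
                   sp2$prediction$concentrations$sample_id)
  # stratification: held-out concentrations are interior quantiles, not all
  # from one end
  a_pred <- sp$prediction$concentrations$A
  a_all <- ds$concentrations$A
  expect_gt(max(a_pred), stats::median(a_all))
  expect_lt(min(a_pred), stats::median(a_all))
})
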