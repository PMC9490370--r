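test_that("correlation reproduces hand-computed and limiting values", {
  a <- c(1, 2, 3)
  expect_equal(correlation_r(a, 2 * a + 3), 1)
  expect_equal(correlation_r(a, -a), -1)
  expect_equal(correlation_r(a, c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-10)
  expect_equal(correlation_r(a, c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_error(correlation_r(a, c(2, 2, 2)), "zero variance")
  # invariance under positive affine maps of either argument
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(correlation_r(3 * x + 1, y), correlation_r(x, y))
  expect_equal(correlation_r(x, 0.2 * y - 5), correlation_r(x, y))
})

test_that("rmse shares the m-denominator formula and is symmetric", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(c(3, 4), c(0, 0)), rmse(c(0, 0), c(3, 4)))
  v <- rnorm(5)
  expect_equal(rmse(v, v), 0)
  expect_equal(rmse(v, v + 1), rmsecv(v, v + 1))
})

test_that("spike recovery follows (Con1 - Con0)/Cons exactly", {
  expect_equal(recovery(2.9, 0.9, 2.0)$recovery_pct, 100)
  expect_equal(recovery(0.7, 0.7, 1.3)$recovery_pct, 0)
  expect_equal(recovery(1.20, 0.30, 1.00)$recovery_pct, 90)
  # negative and >100% values pass through unclipped
  expect_equal(recovery(0.1, 0.3, 1.0)$recovery_pct, -20)
  expect_error(recovery(1, 0.5, 0), "positive")
})

test_that("a perfect model scores Rc = Rp = 1 with zero errors", {
  d <- noiseless_design(seed = 9)
  sp <- split_calibration(generate_dataset(d))
  y_cal <- sp$calibration$concentrations$A
  m <- npls_fit(sp$calibration, y_cal, 2)
  rep <- evaluate_model(m, sp$calibration, y_cal,
                        sp$prediction, sp$prediction$concentrations$A,
                        analyte = "A", method = "npls")
  expect_equal(rep$Rc, 1, tolerance = 1e-9)
  expect_equal(rep$Rp, 1, tolerance = 1e-9)
  expect_lt(rep$RMSEC, 1e-7)
  expect_lt(rep$RMSEP, 1e-7)
})

test_that("a constant-mean model has RMSEC equal to the population sd", {
  set.seed(31)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- runif(12)
  null_model <- lar_fit(X, y, lar_lambda_max(X, y) * 1.01)  # mean-only
  expect_length(null_model$coefficients, 0)
  pred <- lar_predict(null_model, X)
  expect_equal(rmse(y, pred), sqrt(mean((y - mean(y))^2)), tolerance = 1e-10)
})

test_that("replicate predictions are averaged before metrics", {
  d <- noiseless_design(seed = 9)
  sp <- split_calibration(generate_dataset(d))
  y_cal <- sp$calibration$concentrations$A
  m <- npls_fit(sp$calibration, y_cal, 2)
  # triplicate measurement of each prediction sample
  idx <- rep(seq_len(n_samples(sp$prediction)), each = 3)
  trip <- dataset_subset(sp$prediction, idx)
  rep3 <- evaluate_model(m, sp$calibration, y_cal,
                         trip, trip$concentrations$A,
                         analyte = "A", method = "npls",
                         pred_ids = trip$concentrations$sample_id)
  expect_equal(nrow(rep3$prediction), n_samples(sp$prediction))
})

test_that("calibration-only reports flag the missing prediction set", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- lar_fit(X, y, 0.01)
  rep <- evaluate_model(m, X, y, analyte = "A", method = "lar")
  expect_true(rep$prediction_empty)
  expect_true(is.na(rep$Rp))
  expect_false(is.na(rep$Rc))
})

test_that("comparison tables have the method x analyte x statistic layout", {
  mk_rep <- function(method, analyte) {
    structure(list(analyte = analyte, method = method,
                   Rc = 0.99, RMSEC = 0.1, Rp = 0.98, RMSEP = 0.2,
                   calibration = NULL, prediction = NULL,
                   prediction_empty = FALSE),
              class = "validation_report")
  }
  reports <- list(mk_rep("lar", "A"), mk_rep("lar", "B"),
                  mk_rep("ipls", "A"), mk_rep("ipls", "B"),
                  mk_rep("npls", "A"), mk_rep("npls", "B"))
  recs <- do.call(rbind, lapply(c("lar", "ipls", "npls"), function(meth) {
    r <- recovery(con1 = c(2.9, 1.2), con0 = c(0.9, 0.3), cons = c(2, 1),
                  sample_id = c("r1", "r2"), analyte = "A")
    r$method <- meth
    r
  }))
  cmp <- compare_methods(reports, recs)
  expect_equal(nrow(cmp$statistics), 24)  # 3 methods x 2 analytes x 4 stats
  expect_setequal(unique(cmp$statistics$statistic),
                  c("Rc", "RMSEC", "Rp", "RMSEP"))
  expect_equal(nrow(cmp$recoveries), 6)  # 2 samples x 3 methods x 1 analyte
  expect_error(compare_methods(list()), "at least one")
})
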