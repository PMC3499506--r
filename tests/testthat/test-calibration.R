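test_that("normalize_score is the strictly-smaller empirical CDF rank", {
  expect_equal(normalize_score(2.5, c(1, 2, 3, 4)), 0.5)
  expect_equal(normalize_score(0, c(1, 2, 3, 4)), 0)
  # a raw equal to the maximum counts only the strictly smaller ones
  expect_equal(normalize_score(4, c(1, 2, 3, 4)), 3 / 4)
  # ties deflate, never inflate
  expect_equal(normalize_score(2, c(2, 2, 2, 5)), 0)
  expect_equal(normalize_score(c(1.5, 10), c(1, 2, 3, 4)), c(0.25, 1))
})

test_that("training ncs values form a near-uniform grid for distinct raws", {
  set.seed(4)
  raws <- rnorm(50)
  ncs <- normalize_score(raws, raws)
  expect_equal(sort(ncs), (0:49) / 50)
  expect_true(all(ncs >= 0 & ncs < 1))
})

test_that("error_pool windows, truncates and falls back as specified", {
  # uniform ncs grid of 100 entries; window 0.1 around 0.5 holds 21
  tab <- grid_table(errors = (1:100) / 10, min_pool = 10)
  pool <- error_pool(0.5, tab)
  expect_length(pool, 21)
  expect_equal(sort(pool), (41:61) / 10)  # ncs 0.40..0.60 entries
  # boundary query draws one-sidedly from the low end
  pool0 <- error_pool(0, tab)
  expect_equal(sort(pool0), sort((1:11) / 10))
  # deficient windows expand to the min_pool nearest entries
  tab30 <- grid_table(errors = (1:100) / 10, min_pool = 30)
  expect_length(error_pool(0.5, tab30), 30)
  # tiny table: the whole table is the pool
  tab_small <- grid_table(errors = 1:10)
  expect_length(error_pool(0.5, tab_small), 10)
  expect_error(error_pool(0.5, list()), "calibration_table")
})

test_that("empirical_quantile uses the nearest-rank definition", {
  v <- c(-2, -1, 0, 1, 2)
  expect_equal(empirical_quantile(v, 0.1), -2)
  expect_equal(empirical_quantile(v, 0.9), 2)
  expect_equal(empirical_quantile(v, 0), -2)
  expect_equal(empirical_quantile(v, 1), 2)
  expect_equal(empirical_quantile(v, 0.5), 0)   # ceiling(2.5) = 3rd smallest
  expect_error(empirical_quantile(numeric(0), 0.5), "empty")
})

test_that("score_interval shifts the prediction by pooled error quantiles", {
  tab <- calibration_table(1:5, c(-2, -1, 0, 1, 2), alpha = 0.2,
                           window_halfwidth = 0.5, min_pool = 5)
  ci <- score_interval(10, 0.5, tab)
  expect_equal(ci$lower, 8)
  expect_equal(ci$upper, 12)
  expect_s3_class(ci, "confident_prediction")
  # all-zero errors collapse the interval onto the prediction
  tab0 <- calibration_table(1:5, rep(0, 5), alpha = 0.2,
                            window_halfwidth = 0.5, min_pool = 5)
  ci0 <- score_interval(3, 0.5, tab0)
  expect_equal(c(ci0$lower, ci0$upper), c(3, 3))
  # an all-positive pool (model locally biased low) sits above the prediction
  tabp <- calibration_table(1:5, c(1, 2, 3, 4, 5), alpha = 0.2,
                            window_halfwidth = 0.5, min_pool = 5)
  cip <- score_interval(0, 0.5, tabp)
  expect_gt(cip$lower, 0)
  expect_gte(cip$upper, cip$lower)
})

test_that("general_interval ignores scores and keeps a constant width", {
  tab <- calibration_table(1:3, c(-1, 0, 1), alpha = 2 / 3,
                           window_halfwidth = 0.5, min_pool = 3)
  gi <- general_interval(0, tab)
  # nearest-rank quantiles of (-1, 0, 1) at p = 1/3 and 2/3 are -1 and 0
  expect_equal(gi$lower, -1)
  expect_equal(gi$upper, 0)
  expect_equal(gi$ncs, -1)  # sentinel
  gi2 <- general_interval(5, tab)
  expect_equal(gi2$upper - gi2$lower, gi$upper - gi$lower)
  # alpha -> 0 spans the full error range
  tab_tiny <- calibration_table(1:3, c(-1, 0, 1), alpha = 1e-9,
                                window_halfwidth = 0.5, min_pool = 3)
  gi3 <- general_interval(0, tab_tiny)
  expect_equal(c(gi3$lower, gi3$upper), c(-1, 1))
})

test_that("intervals nest as the miss level alpha decreases", {
  set.seed(6)
  errs <- rnorm(200)
  for (ncs in c(0, 0.3, 0.77)) {
    prev <- c(-Inf, Inf)
    for (a in c(0.01, 0.05, 0.2, 0.5, 0.9)) {
      tab <- calibration_table(1:200, errs, alpha = a)
      ci <- score_interval(0, ncs, tab)
      # wider (smaller alpha) intervals contain narrower ones
      expect_gte(ci$lower, prev[1] - 1e-12)
      expect_lte(ci$upper, prev[2] + 1e-12)
      prev <- c(ci$lower, ci$upper)
    }
  }
})

test_that("batch interval offsets agree with the scalar construction", {
  set.seed(7)
  raws <- rnorm(80)
  errs <- rnorm(80)
  tab <- calibration_table(raws, errs, alpha = 0.2)
  ncs_q <- c(0, 0.05, 0.33, 0.5, 0.91, 1)
  off <- regconf:::.interval_offsets(ncs_q, tab)
  for (i in seq_along(ncs_q)) {
    pool <- error_pool(ncs_q[i], tab)
    expect_equal(unname(off[i, "lower"]), empirical_quantile(pool, 0.1))
    expect_equal(unname(off[i, "upper"]), empirical_quantile(pool, 0.9))
  }
})

test_that("build_calibration excludes each training row from its own score", {
  d <- standardize(generate_friedman(50, 5, 1, seed = 13))
  errs <- training_errors(d, ols(), "cv", 5, seed = 2)
  tab <- build_calibration(d, estimator_spec("confine", k = 3), ols(), errors = errs)
  expect_equal(tab$n, 50)
  # oracle for row 1: confine with self-exclusion via the public API
  raw1 <- -mean(errs$squared_error[
    nearest_neighbors(d$features[1, ], d, 3, exclude_index = 1)$indices])
  expect_equal(tab$training_raws[1], raw1, tolerance = 1e-12)
})

test_that("narrow intervals go with high confidence scores on Friedman data", {
  wins <- 0
  for (s in 1:20) {
    sp <- friedman_split(500, 300, m_total = 8, sigma = 1, seed = 7000 + s)
    cr <- conf_regressor(sp$train, ols(), estimator_spec("confine", k = 10), seed = s)
    pr <- predict(cr, sp$test)
    w <- pr$upper - pr$lower
    hi <- w[pr$ncs > 0.8]
    lo <- w[pr$ncs < 0.2]
    if (length(hi) && length(lo)) wins <- wins + (mean(hi) <= mean(lo))
  }
  expect_gt(wins, 10)
})
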