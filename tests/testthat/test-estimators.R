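# Small geometric fixture: 1-D training points at 0, 1, 2, ... so the
# neighbor structure of any query is obvious by hand.
line_train <- function(y) conf_dataset(matrix(seq_along(y) - 1, ncol = 1), y)

test_that("confine transfers the local mean squared error", {
  tr <- line_train(c(0, 0, 0, 0))
  errs <- data.frame(index = 1:4, prediction = 0,
                     signed_error = c(1, 2, 10, 10),
                     squared_error = c(1, 4, 100, 100))
  spec <- estimator_spec("confine", k = 2)
  # query at 0.5: neighbors 1 and 2 with signed errors (1, 2)
  expect_equal(confine_score(0.5, tr, errs, spec), -2.5)
  # zero local error is the maximum attainable score
  errs0 <- transform(errs, signed_error = 0, squared_error = 0)
  expect_equal(confine_score(0.5, tr, errs0, spec), 0)
  # k = n: the whole-training MSE, independent of the query
  spec_n <- estimator_spec("confine", k = 4)
  expect_equal(confine_score(0.5, tr, errs, spec_n), -mean(errs$squared_error))
  expect_equal(confine_score(100, tr, errs, spec_n), -mean(errs$squared_error))
})

test_that("kernel-weighted confine concentrates on the closest point as bandwidth shrinks", {
  tr <- line_train(c(0, 0, 0))
  e <- 3
  errs <- data.frame(index = 1:3, prediction = 0,
                     signed_error = c(e, 5, 7), squared_error = c(e^2, 25, 49))
  spec <- estimator_spec("confine", weighting = "kernel", bandwidth = 0.05)
  # query sits exactly on training point 1 (error e)
  expect_equal(confine_score(0, tr, errs, spec), -e^2, tolerance = 1e-6)
  # vanishing bandwidth underflows every weight for off-grid queries far away
  spec_tiny <- estimator_spec("confine", weighting = "kernel", bandwidth = 1e-4)
  expect_error(confine_score(1000, tr, errs, spec_tiny), "degenerate")
})

test_that("confive scores the local response variance", {
  tr <- line_train(c(0, 2, 50, 50))
  spec <- estimator_spec("confive", k = 2)
  # query at 0.5: neighbor responses (0, 2), sample variance 2
  expect_equal(confive_score(0.5, tr, spec), -2)
  tr2 <- line_train(c(1, 2, 3, 99))
  expect_equal(confive_score(1, tr2, estimator_spec("confive", k = 3)), -1)
  # equal neighbor responses give the maximum score
  expect_equal(confive_score(2.5, line_train(c(0, 1, 7, 7)), spec), 0)
  expect_error(estimator_spec("confive", k = 1), "k >= 2")
})

test_that("density, neighbor-difference and distance baselines follow their formulas", {
  tr <- line_train(c(1, 2, 3, 2, 2))  # points at 0..4
  # nonn: query 0 with radius 1.5 counts the rows at distances 0 and 1
  expect_equal(neighborhood_baseline_score("nonn", 0, tr,
                                           spec = estimator_spec("nonn", radius = 1.5)), 2)
  expect_equal(neighborhood_baseline_score("nonn", -0.8, tr,
                                           spec = estimator_spec("nonn", radius = 1)), 1)
  # diffnn: |prediction - mean of 5 NN responses (1,2,3,2,2)| = |3 - 2|
  expect_equal(neighborhood_baseline_score("diffnn", 2, tr, prediction = 3,
                                           spec = estimator_spec("diffnn", k = 5)), -1)
  expect_error(neighborhood_baseline_score("diffnn", 2, tr), "prediction")
  # avgdist: query -1 sees distances (1,2,3,4,5), mean 3
  expect_equal(neighborhood_baseline_score("avgdist", -1, tr), -3)
})

test_that("bagging variance is zero for interpolatable data and seed-stable", {
  d <- linear_dataset(30)
  spec <- estimator_spec("bagging", n_bootstrap = 10)
  s1 <- bagging_score(0.5, d, ols(), spec, seed = 7)
  expect_equal(s1, 0, tolerance = 1e-16)
  noisy <- generate_friedman(40, 5, 2, seed = 1)
  q <- rep(0.5, 5)
  b1 <- bagging_score(q, noisy, ols(), spec, seed = 7)
  b2 <- bagging_score(q, noisy, ols(), spec, seed = 7)
  b3 <- bagging_score(q, noisy, ols(), spec, seed = 8)
  expect_identical(b1, b2)
  expect_false(identical(b1, b3))
  expect_lt(b1, 0)
})

test_that("localcv matches a hand-rolled leave-one-out oracle", {
  set.seed(21)
  X <- matrix(runif(30), ncol = 2)
  tr <- conf_dataset(X, rowSums(X) + rnorm(15, sd = 0.3))
  q <- c(0.5, 0.5)
  k <- 4
  spec <- estimator_spec("localcv", k = k)
  got <- localcv_score(q, tr, ols(), spec)
  # oracle: brute-force neighbor search + lm refits
  dist <- sqrt(colSums((t(X) - q)^2))
  nb <- order(dist)[1:k]
  a <- sapply(nb, function(i) {
    fit <- lm(y ~ ., data.frame(y = tr$response[-i], X[-i, , drop = FALSE]))
    abs(tr$response[i] - predict(fit, data.frame(X[i, , drop = FALSE])))
  })
  w <- 1 / (dist[nb] + 1e-8)
  expect_equal(got, -sum(w * a) / sum(w), tolerance = 1e-8)
  # perfect local fits give the maximum score
  expect_equal(localcv_score(0.5, linear_dataset(20), ols(), spec), 0, tolerance = 1e-12)
})

test_that("localvar matches a hand-rolled perturb-and-refit oracle", {
  set.seed(22)
  X <- matrix(runif(40), ncol = 2)
  tr <- conf_dataset(X, rowSums(X) + rnorm(20, sd = 0.5))
  q <- c(0.4, 0.6)
  fr <- c(-0.5, -0.1, 0.1, 0.5)
  spec <- estimator_spec("localvar", perturbation_fractions = fr)
  got <- localvar_score(q, tr, ols(), spec)
  qdf <- setNames(data.frame(rbind(q)), c("X1", "X2"))
  base <- lm(y ~ ., data.frame(y = tr$response, X))
  yhat0 <- unname(predict(base, qdf))
  rng <- diff(range(tr$response))
  preds <- sapply(fr, function(f) {
    df <- data.frame(y = c(tr$response, yhat0 + f * rng), rbind(X, q))
    unname(predict(lm(y ~ ., df), qdf))
  })
  expect_equal(got, -var(preds), tolerance = 1e-8)
  expect_error(localvar_score(q, conf_dataset(X, rep(1, 20)), ols(), spec),
               "degenerate")
  # one added point barely moves a model fitted on many: score near zero
  big <- linear_dataset(400)
  expect_lt(abs(localvar_score(0.5, big, ols(), spec)), 1e-4)
})

test_that("raw scores are finite and respect the sign convention", {
  d <- standardize(generate_friedman(60, 6, 1, seed = 5))
  errs <- training_errors(d, ols(), "cv", 5, seed = 1)
  fitted <- fit_predictor(ols(), d)
  q <- d$features[1, ] * 0.9
  pred <- predict(fitted, matrix(q, nrow = 1))
  scores <- c(
    confine = confine_score(q, d, errs, estimator_spec("confine", k = 5)),
    confive = confive_score(q, d, estimator_spec("confive", k = 5)),
    nonn = neighborhood_baseline_score("nonn", q, d),
    diffnn = neighborhood_baseline_score("diffnn", q, d, prediction = pred),
    avgdist = neighborhood_baseline_score("avgdist", q, d),
    localcv = localcv_score(q, d, ols(), estimator_spec("localcv", k = 5)),
    localvar = localvar_score(q, d, ols(), estimator_spec("localvar")),
    bagging = bagging_score(q, d, ols(), seed = 3)
  )
  expect_true(all(is.finite(scores)))
  # shrinking all training errors never decreases the confine score
  errs_small <- transform(errs, signed_error = signed_error / 2,
                          squared_error = squared_error / 4)
  expect_gte(confine_score(q, d, errs_small, estimator_spec("confine", k = 5)),
             scores[["confine"]])
  # compressing the local responses never decreases the confive score
  d_flat <- d; d_flat$response <- d$response * 0.5
  expect_gte(confive_score(q, d_flat, estimator_spec("confive", k = 5)),
             scores[["confive"]])
  # moving the training cloud closer never decreases avgdist's score
  d_near <- d; d_near$features <- d$features * 0.5
  q0 <- rep(0, ncol(d$features))
  expect_gte(neighborhood_baseline_score("avgdist", q0, d_near),
             neighborhood_baseline_score("avgdist", q0, d))
})

test_that("tune_k is deterministic and honors a single candidate", {
  d <- generate_friedman(60, 5, 1, seed = 8)
  expect_equal(tune_k(d, estimator_spec("confine"), ols(), candidates = 7, seed = 1), 7L)
  k1 <- tune_k(d, estimator_spec("confine"), ols(), seed = 4)
  k2 <- tune_k(d, estimator_spec("confine"), ols(), seed = 4)
  expect_identical(k1, k2)
  expect_error(tune_k(d, estimator_spec("confine"), ols(), candidates = 60, seed = 1),
               "infeasible")
})

test_that("tune_k prefers small neighborhoods when the error signal is local", {
  # two well-separated clusters whose models err very differently: small-k
  # neighborhoods carry that signal, cluster-spanning ones destroy it
  wins <- 0
  for (s in 1:20) {
    set.seed(3000 + s)
    n2 <- 40
    x <- c(runif(n2), runif(n2) + 10)
    curve <- 4 * sin(3 * x)            # unmodelable by OLS: large errors
    y <- c(rnorm(n2, sd = 0.05), curve[(n2 + 1):(2 * n2)] + rnorm(n2, sd = 1))
    d <- conf_dataset(matrix(x, ncol = 1), y)
    k <- tune_k(d, estimator_spec("confine"), ols(), candidates = c(2, 39), seed = s)
    wins <- wins + (abs(k - 2) < abs(k - 39))
  }
  expect_gt(wins, 10)
})

test_that("kernel bandwidth tuning is seeded and feeds the kernel pipeline", {
  d <- generate_friedman(80, 5, 1, seed = 14)
  est <- estimator_spec("confine", weighting = "kernel")
  b1 <- tune_bandwidth(standardize(d), est, ols(), seed = 6)
  b2 <- tune_bandwidth(standardize(d), est, ols(), seed = 6)
  expect_identical(b1, b2)
  expect_gt(b1, 0)
  expect_error(tune_bandwidth(standardize(d), estimator_spec("confine"), ols()),
               "kernel")
  # end to end: kernel-weighted estimator through the calibrated regressor
  sp <- friedman_split(120, 30, m_total = 5, sigma = 1, seed = 15)
  cr <- conf_regressor(sp$train, ols(), est, seed = 4)
  pr <- predict(cr, sp$test)
  expect_true(all(is.finite(pr$raw_score)))
  expect_true(all(pr$lower <= pr$upper))
})
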