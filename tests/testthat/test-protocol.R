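test_that("forward selection finds the informative feature and drops pure noise", {
  hits <- 0
  for (s in 1:20) {
    set.seed(4000 + s)
    X <- matrix(runif(1000), ncol = 2)
    y <- 3 * X[, 1] + rnorm(500, sd = 0.3)
    sel <- forward_feature_selection(conf_dataset(X, y), ols(), seed = s)
    hits <- hits + identical(sel, 1L)
  }
  # the 1e-6 relative-improvement stop admits a chance noise feature in a
  # minority of seeds; the informative feature must dominate clearly
  expect_gte(hits, 12)
})

test_that("forward selection keeps adding while CV MSE strictly drops", {
  set.seed(41)
  X <- matrix(runif(600), ncol = 3)
  y <- X[, 1] + X[, 2]          # exactly linear in two features
  sel <- forward_feature_selection(conf_dataset(X, y), ols(), seed = 1)
  expect_setequal(sel[1:2], c(1L, 2L))
  # single-feature data returns that feature
  expect_equal(forward_feature_selection(conf_dataset(X[, 1, drop = FALSE], y),
                                         ols(), seed = 1), 1L)
})

test_that("nested CV is reproducible and partitions the data", {
  d <- generate_friedman(60, 5, 1, seed = 17)
  ests <- list(confine = estimator_spec("confine", k = 5),
               confive = estimator_spec("confive", k = 5))
  r1 <- nested_cv_evaluate(d, ols(), ests, repetitions = 2, outer_folds = 3, seed = 9)
  r2 <- nested_cv_evaluate(d, ols(), ests, repetitions = 2, outer_folds = 3, seed = 9)
  keep <- setdiff(names(r1), "runtime_ms")   # wall-clock differs, results must not
  expect_identical(r1[keep], r2[keep])
  expect_false(identical(
    r1[keep], nested_cv_evaluate(d, ols(), ests, repetitions = 2,
                                 outer_folds = 3, seed = 10)[keep]))
  # outer folds partition every repetition: test sizes sum to n, near-equal
  for (r in 1:2) for (est in names(ests)) {
    sizes <- r1$n_test[r1$repetition == r & r1$estimator == est]
    expect_equal(sum(sizes), 60)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(r1$n_train[r1$repetition == r & r1$estimator == est], 60 - sizes)
  }
})

test_that("outer-test rows never influence training-side artifacts", {
  sp <- friedman_split(80, 20, m_total = 6, sigma = 1, seed = 23)
  ests <- list(confine = estimator_spec("confine"),
               bagging = estimator_spec("bagging", n_bootstrap = 5))
  a <- regconf:::.evaluate_split(sp$train, sp$test, ols(), ests, seed = 3, detail = TRUE)
  # canary: permute the held-out responses; train-side state must not move
  test_perm <- sp$test
  test_perm$response <- rev(test_perm$response)
  b <- regconf:::.evaluate_split(sp$train, test_perm, ols(), ests, seed = 3, detail = TRUE)
  expect_identical(a$selected_features, b$selected_features)
  expect_identical(a$training_errors, b$training_errors)
  expect_identical(a$chosen_k, b$chosen_k)
  expect_identical(a$tables, b$tables)
  # the held-out metrics do move
  expect_false(identical(a$rows$cec, b$rows$cec))
})

test_that("failed estimators are reported, not fabricated", {
  d <- generate_friedman(30, 5, 1, seed = 3)
  d$response <- rep(1, 30)   # constant response breaks localvar
  ests <- list(localvar = estimator_spec("localvar"),
               confive = estimator_spec("confive", k = 3))
  r <- nested_cv_evaluate(d, ols(), ests, repetitions = 1, outer_folds = 2,
                          seed = 5, select_features = FALSE)
  lv <- r[r$estimator == "localvar", ]
  expect_true(all(is.na(lv$cec)))
  expect_true(all(grepl("degenerate", lv$error)))
  cv <- r[r$estimator == "confive", ]
  expect_true(all(is.na(cv$error)))
})

test_that("grid summary bins rows by size, selected features and noise", {
  rows <- data.frame(
    estimator = "confine",
    cec = c(0.1, 0.3, 0.5, 0.7), capi = c(0, 0.2, 0.4, 0.6),
    m_selected = c(4, 12, 5, 5),
    n = c(50, 200, 500, 500), sigma = c(0.5, 2, 0.5, 0.5))
  s <- summarize_grid(rows, grid = data.frame(n = c(50, 500), sigma = c(0.5, 2)))
  g <- function(bin) s$avg_cec[s$bin == bin]
  expect_equal(g("n_le_100"), 0.1)
  expect_equal(g("n_gt_100"), mean(c(0.3, 0.5, 0.7)))
  expect_equal(g("m_gt_10"), 0.3)   # the 12-feature fold lands in m > 10
  expect_equal(g("sigma_lt_1"), mean(c(0.1, 0.5, 0.7)))
  expect_equal(g("best"), mean(c(0.5, 0.7)))  # largest n, m <= 10, smallest sigma
})

test_that("a one-cell grid reduces to a nested CV aggregation", {
  ests <- list(confine = estimator_spec("confine", k = 5))
  g <- data.frame(n = 50, m_total = 5, sigma = 1, replicate = 1)
  gs <- grid_study(g, ests, seed = 21, repetitions = 1, outer_folds = 3)
  expect_equal(nrow(gs$results), 3)
  expect_equal(gs$summary$avg_cec[gs$summary$bin == "n_le_100"],
               mean(gs$results$cec))
})

test_that("per-prediction scoring cost separates fast and refitting estimators", {
  d <- standardize(generate_friedman(500, 10, 1, seed = 31))
  errs <- training_errors(d, ols(), "cv", 5, seed = 1)
  fitted <- fit_predictor(ols(), d)
  queries <- matrix(runif(100 * 10), ncol = 10)
  sp_confine <- estimator_spec("confine", k = 10)
  sp_confive <- estimator_spec("confive", k = 10)
  sp_nonn <- estimator_spec("nonn", radius = 1)
  sp_diffnn <- estimator_spec("diffnn")
  sp_avgdist <- estimator_spec("avgdist")
  sp_localcv <- estimator_spec("localcv", k = 10)
  sp_localvar <- estimator_spec("localvar")
  model <- ols()
  time_per_call <- function(fn) {
    fn(queries[1, ])  # warm up: exclude one-time byte-compilation
    # best of five passes with a GC fence: per-call cost without jitter
    min(vapply(1:5, function(r) {
      gc(FALSE)
      t0 <- proc.time()[[3]]
      for (i in seq_len(nrow(queries))) fn(queries[i, ])
      (proc.time()[[3]] - t0) / nrow(queries)
    }, 0))
  }
  fast <- c(
    confine = time_per_call(function(q) confine_score(q, d, errs, sp_confine)),
    confive = time_per_call(function(q) confive_score(q, d, sp_confive)),
    nonn = time_per_call(function(q)
      neighborhood_baseline_score("nonn", q, d, spec = sp_nonn)),
    diffnn = time_per_call(function(q)
      neighborhood_baseline_score("diffnn", q, d, prediction = 1, spec = sp_diffnn)),
    avgdist = time_per_call(function(q)
      neighborhood_baseline_score("avgdist", q, d, spec = sp_avgdist))
  )
  slow <- c(
    localcv = time_per_call(function(q) localcv_score(q, d, model, sp_localcv)),
    localvar = time_per_call(function(q) localvar_score(q, d, model, sp_localvar))
  )
  expect_gte(min(slow), 10 * max(fast))
})

test_that("config round trip rebuilds model and estimators", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "alpha: 0.1",
    "model:",
    "  family: svr_rbf",
    "  cost: 4",
    "estimators:",
    "  - name: confine",
    "    k: 7",
    "  - name: bagging",
    "    n_bootstrap: 5"), cfg_file)
  cfg <- read_config(cfg_file)
  expect_equal(cfg$alpha, 0.1)
  m <- config_model(cfg)
  expect_equal(m$family, "svr_rbf")
  expect_equal(m$hyperparameters$cost, 4)
  ests <- config_estimators(cfg)
  expect_named(ests, c("confine", "bagging"))
  expect_equal(ests$confine$k, 7L)
  expect_equal(ests$bagging$n_bootstrap, 5L)
  # defaults survive when no file is given
  expect_equal(read_config()$alpha, 0.2)
})

test_that("prediction and report writers emit valid files", {
  sp <- friedman_split(60, 10, m_total = 5, sigma = 1, seed = 3)
  cr <- conf_regressor(sp$train, ols(), estimator_spec("confine", k = 5), seed = 2)
  pr <- predict(cr, sp$test)
  expect_named(pr, c("prediction", "raw_score", "ncs", "lower", "upper", "alpha"))
  expect_true(all(pr$lower <= pr$upper))
  expect_true(all(pr$ncs >= 0 & pr$ncs <= 1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(pr, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 10)
  expect_equal(back$prediction, pr$prediction, tolerance = 1e-9)
  ests <- list(confine = estimator_spec("confine", k = 5))
  r <- nested_cv_evaluate(sp$train, ols(), ests, repetitions = 1,
                          outer_folds = 3, seed = 2)
  js <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(r, js, config = default_config(), seed = 2)
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed$rows), nrow(r))
  expect_equal(parsed$seed, 2)
})
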