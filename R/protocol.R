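#' Greedy forward feature selection by cross-validated MSE
#'
#' Starts from the single best feature and repeatedly adds the feature
#' whose inclusion most reduces the seeded k-fold cross-validation MSE,
#' stopping when no addition improves the MSE by at least 1e-6 relative.
#' The fold assignment is drawn once per call, so all candidate sets are
#' compared on identical splits.
#'
#' @param train `conf_dataset`.
#' @param model `predictor_spec`.
#' @param folds number of CV folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return Integer vector of selected feature indices (length >= 1), in
#'   the order of inclusion.
#' @export
forward_feature_selection <- function(train, model, folds = 5, seed = 1) {
  stopifnot(inherits(train, "conf_dataset"))
  n <- nrow(train$features)
  d <- ncol(train$features)
  if (d == 1) return(1L)
  if (!.is_count(folds) || folds < 2 || n < folds) .stop_arg("need 2 <= folds <= n")
  assign_fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  X <- train$features
  y <- train$response
  ols <- model$family == "ols_linear"
  if (ols) {
    # Gram-matrix evaluation: one column-augmented normal-equation solve
    # per candidate instead of an O(n p^2) refit. Per fold, precompute
    # X'X / X'y on the training part and on the held part; the held-fold
    # SSE of coefficients b over columns C is
    #   y'y - 2 b' (H_C' y) + b' (H_C' H_C) b.
    Z <- cbind(1, X)
    pf <- lapply(seq_len(folds), function(f) {
      hold <- assign_fold == f
      list(G = crossprod(Z[!hold, , drop = FALSE]),
           gy = drop(crossprod(Z[!hold, , drop = FALSE], y[!hold])),
           Gh = crossprod(Z[hold, , drop = FALSE]),
           ghy = drop(crossprod(Z[hold, , drop = FALSE], y[hold])),
           yyh = sum(y[hold]^2))
    })
    cv_mse <- function(cols) {
      C <- c(1L, cols + 1L)
      err2 <- 0
      for (f in seq_len(folds)) {
        p <- pf[[f]]
        b <- tryCatch(solve(p$G[C, C, drop = FALSE], p$gy[C]),
                      error = function(e) NULL)
        if (is.null(b)) return(NA_real_)
        err2 <- err2 + p$yyh - 2 * sum(b * p$ghy[C]) +
          drop(crossprod(b, p$Gh[C, C, drop = FALSE] %*% b))
      }
      err2 / n
    }
  } else {
    cv_mse <- function(cols) {
      err2 <- 0
      for (f in seq_len(folds)) {
        hold <- assign_fold == f
        fit <- tryCatch(fit_predictor(model, X[!hold, cols, drop = FALSE], y[!hold]),
                        error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        p <- predict(fit, X[hold, cols, drop = FALSE])
        err2 <- err2 + sum((y[hold] - p)^2)
      }
      err2 / n
    }
  }
  selected <- integer(0)
  best_mse <- Inf
  repeat {
    remaining <- setdiff(seq_len(d), selected)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(j) cv_mse(c(selected, j)), 0)
    if (all(is.na(scores))) {
      if (length(selected)) break
      .stop_arg("model fit failed for every single-feature candidate")
    }
    if (any(is.na(scores)))
      warning("skipped ", sum(is.na(scores)), " candidate feature(s) with failing fits")
    j <- remaining[which.min(scores)]
    new_mse <- min(scores, na.rm = TRUE)
    if (length(selected) > 0 && new_mse > best_mse * (1 - 1e-6)) break
    selected <- c(selected, j)
    best_mse <- new_mse
  }
  selected
}

# ---- single train/test split evaluation --------------------------------

# Evaluate a list of estimators on one train/test split: feature
# selection, standardization, model fit, out-of-fold errors, k tuning,
# calibration, test scoring and metrics, all computed strictly from the
# training part. This is the building block nested CV repeats per fold.
.evaluate_split <- function(train, test, model, estimators, alpha = 0.2,
                            window_halfwidth = 0.1, min_pool = 30, seed = 1,
                            select_features = TRUE, fs_folds = 5,
                            candidates = NULL, top_fraction = 0.5,
                            detail = FALSE) {
  if (is.null(names(estimators)))
    names(estimators) <- vapply(estimators, `[[`, "", "name")
  fs_idx <- if (select_features)
    forward_feature_selection(train, model, folds = fs_folds, seed = .subseed(seed, 1))
  else seq_len(ncol(train$features))
  tr <- .subset_cols(train, fs_idx)
  te <- .subset_cols(test, fs_idx)
  tr_std <- standardize(tr)
  Xte <- .apply_standardization(te$features, tr_std$standardization)
  errs <- training_errors(tr_std, model, "cv", folds = 5, seed = .subseed(seed, 2))
  fitted <- fit_predictor(model, tr_std)
  pred_test <- predict(fitted, Xte)
  abs_err <- abs(te$response - pred_test)
  sq_err <- (te$response - pred_test)^2

  auto <- which(vapply(estimators, function(e)
    identical(e$k, "auto") && e$weighting == "uniform" &&
      e$name %in% c("confine", "confive", "localcv"), TRUE))
  if (length(auto)) {
    ks <- .tune_k_multi(tr_std, estimators[auto], model, candidates = candidates,
                        seed = .subseed(seed, 3), alpha = alpha,
                        window_halfwidth = window_halfwidth, min_pool = min_pool)
    for (j in seq_along(auto)) estimators[[auto[j]]]$k <- ks[[j]]
  }
  for (j in seq_along(estimators)) {
    e <- estimators[[j]]
    if (e$weighting == "kernel" && is.null(e$bandwidth))
      estimators[[j]]$bandwidth <- tune_bandwidth(
        tr_std, e, model, seed = .subseed(seed, 5), alpha = alpha,
        window_halfwidth = window_halfwidth, min_pool = min_pool)
  }
  ctx <- .make_ctx(tr_std, model = model, fitted = fitted, errors = errs,
                   seed = .subseed(seed, 4))
  est_names <- vapply(estimators, `[[`, "", "name")
  needs_geom <- any(est_names %in%
                      c("confine", "confive", "nonn", "diffnn", "avgdist", "localcv"))
  kmax <- 0L
  for (e in estimators)
    if (e$name %in% c("confine", "confive", "diffnn", "localcv") && is.numeric(e$k))
      kmax <- max(kmax, e$k)
  kmax <- min(kmax, ctx$n - 1L)
  geom_tr <- if (needs_geom) .query_geom(tr_std$features, ctx, self = TRUE, kmax = kmax) else NULL
  geom_te <- if (needs_geom) .query_geom(Xte, ctx, self = FALSE, kmax = min(kmax, ctx$n)) else NULL
  # general interval: same construction over all training errors
  g_lo <- empirical_quantile(errs$signed_error, alpha / 2)
  g_hi <- empirical_quantile(errs$signed_error, 1 - alpha / 2)
  cov_gen <- mean(pred_test + g_lo <= te$response & te$response <= pred_test + g_hi)

  rows <- vector("list", length(estimators))
  tables <- list()
  for (ei in seq_along(estimators)) {
    est <- estimators[[ei]]
    if (identical(est$k, "auto")) est$k <- .spec_k(est, ctx$n - 1L)
    res <- tryCatch({
      raws_tr <- .batch_scores(est, tr_std$features, ctx, self = TRUE,
                               pred_q = errs$prediction, geom = geom_tr)
      tab <- calibration_table(raws_tr, errs$signed_error, alpha = alpha,
                               window_halfwidth = window_halfwidth,
                               min_pool = min_pool)
      t0 <- proc.time()[[3]]
      raws_te <- .batch_scores(est, Xte, ctx, self = FALSE, pred_q = pred_test,
                               geom = geom_te)
      ncs_te <- normalize_score(raws_te, raws_tr)
      off <- .interval_offsets(ncs_te, tab)
      ms <- (proc.time()[[3]] - t0) * 1000
      widths <- off[, "upper"] - off[, "lower"]
      lower <- pred_test + off[, "lower"]
      upper <- pred_test + off[, "upper"]
      tables[[names(estimators)[ei]]] <- tab
      list(row = data.frame(
        estimator = est$name,
        cec = as.numeric(cec(abs_err, widths)),
        capi = capi(sq_err, widths, top_fraction),
        coverage_score = mean(lower <= te$response & te$response <= upper),
        coverage_general = cov_gen,
        chosen_k = if (is.na(est$k)) NA_integer_ else as.integer(est$k),
        m_selected = length(fs_idx),
        n_train = ctx$n, n_test = length(pred_test),
        runtime_ms = ms, error = NA_character_,
        stringsAsFactors = FALSE),
        scored = data.frame(prediction = pred_test, raw_score = raws_te,
                            ncs = ncs_te, lower = lower, upper = upper,
                            alpha = alpha))
    }, error = function(e) {
      list(row = data.frame(
        estimator = est$name, cec = NA_real_, capi = NA_real_,
        coverage_score = NA_real_, coverage_general = cov_gen,
        chosen_k = NA_integer_, m_selected = length(fs_idx),
        n_train = ctx$n, n_test = length(pred_test),
        runtime_ms = NA_real_, error = conditionMessage(e),
        stringsAsFactors = FALSE), scored = NULL)
    })
    rows[[ei]] <- res
  }
  out <- list(rows = do.call(rbind, lapply(rows, `[[`, "row")))
  if (detail) {
    out$selected_features <- fs_idx
    out$tables <- tables
    out$training_errors <- errs
    out$chosen_k <- vapply(estimators, function(e)
      if (is.numeric(e$k)) as.integer(e$k) else NA_integer_, 0L)
    out$scored <- lapply(rows, `[[`, "scored")
    names(out$scored) <- names(estimators)
  }
  out
}

#' Nested cross-validation evaluation of confidence estimators
#'
#' Repeats an outer k-fold cross-validation: on each outer-training part
#' the pipeline performs feature selection, model fitting, out-of-fold
#' error computation, neighborhood-size tuning (five two-fold CVs) and
#' calibration; the outer-test part is then scored, interval-ized and
#' evaluated with CEC, CAPI and coverage. Outer-test rows never
#' influence any training-side artifact. All randomness derives from
#' `seed`, so identical calls give identical results.
#'
#' @param data `conf_dataset`.
#' @param model `predictor_spec`.
#' @param estimators list of `estimator_spec`s.
#' @param repetitions number of repeated outer CVs (default 5).
#' @param outer_folds outer fold count (default 5).
#' @param alpha interval miss level (default 0.2: 80% intervals).
#' @param seed integer seed.
#' @param select_features run forward selection per fold (default TRUE).
#' @param window_halfwidth,min_pool calibration settings.
#' @param candidates optional candidate k grid for tuning.
#' @param top_fraction CAPI selection fraction (default 0.5).
#' @return data.frame of class `benchmark_result`: one row per
#'   (repetition, outer fold, estimator) with CEC, CAPI, both coverages,
#'   the chosen k, the number of selected features and the scoring
#'   runtime; a failed estimator carries its error message and NA
#'   metrics.
#' @export
nested_cv_evaluate <- function(data, model, estimators, repetitions = 5,
                               outer_folds = 5, alpha = 0.2, seed = 1,
                               select_features = TRUE, window_halfwidth = 0.1,
                               min_pool = 30, candidates = NULL,
                               top_fraction = 0.5) {
  stopifnot(inherits(data, "conf_dataset"))
  n <- nrow(data$features)
  if (n < 2 * outer_folds) .stop_arg("need n >= 2 * outer_folds")
  if (!.is_count(repetitions) || repetitions < 1) .stop_arg("repetitions must be >= 1")
  all_rows <- list()
  for (r in seq_len(repetitions)) {
    assign_fold <- with_seed(.subseed(seed, 7000 + r),
                             sample(rep_len(seq_len(outer_folds), n)))
    for (f in seq_len(outer_folds)) {
      hold <- assign_fold == f
      es <- .evaluate_split(.subset_rows(data, !hold), .subset_rows(data, hold),
                            model, estimators, alpha = alpha,
                            window_halfwidth = window_halfwidth,
                            min_pool = min_pool,
                            seed = .subseed(seed, r * 131 + f),
                            select_features = select_features,
                            candidates = candidates,
                            top_fraction = top_fraction)
      rows <- es$rows
      rows$repetition <- r
      rows$fold <- f
      all_rows[[length(all_rows) + 1]] <- rows
    }
  }
  out <- do.call(rbind, all_rows)
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Default grid of synthetic study conditions
#'
#' One row per (dataset size, total feature count, noise level,
#' replicate) cell: n in {50, 100, 200, 500}, m_total in {5, 10, 25, 50},
#' sigma in {0.5, 1, 2}, with 3 seeded replicates per combination. The
#' grid populates every marginal bin of the summary table.
#'
#' @param n,m_total,sigma,replicates axis values.
#' @return data.frame with columns `n`, `m_total`, `sigma`, `replicate`.
#' @export
default_grid <- function(n = c(50, 100, 200, 500), m_total = c(5, 10, 25, 50),
                         sigma = c(0.5, 1, 2), replicates = 3) {
  expand.grid(n = n, m_total = m_total, sigma = sigma,
              replicate = seq_len(replicates), KEEP.OUT.ATTRS = FALSE)
}

#' Default set of all eight confidence estimators
#'
#' @return Named list of `estimator_spec`s (confine, confive, nonn,
#'   diffnn, avgdist, localcv, localvar, bagging).
#' @export
default_estimators <- function() {
  names <- c("confine", "confive", "nonn", "diffnn", "avgdist",
             "localcv", "localvar", "bagging")
  stats::setNames(lapply(names, estimator_spec), names)
}

#' Grid study of confidence estimation on synthetic data
#'
#' Generates a seeded Friedman dataset for every grid cell, runs
#' [nested_cv_evaluate()] on it, and aggregates average CEC/CAPI into
#' marginal bins: dataset size (n <= 100 vs n > 100), *selected* feature
#' count (m <= 10 vs m > 10, recorded per fold), noise (sigma < 1 vs
#' >= 1), plus a best-conditions aggregate (largest n, selected m <= 10,
#' smallest sigma).
#'
#' @param grid data.frame as from [default_grid()].
#' @param estimators list of `estimator_spec`s (default: all eight).
#' @param model `predictor_spec` (default OLS).
#' @param seed integer seed.
#' @param repetitions,outer_folds,alpha,... forwarded to
#'   [nested_cv_evaluate()].
#' @return An object of class `grid_study`: list with `results` (fold
#'   rows across all cells), `summary` (per-estimator bin averages) and
#'   `grid`.
#' @export
grid_study <- function(grid = default_grid(), estimators = default_estimators(),
                       model = predictor_spec("ols_linear"), seed = 1,
                       repetitions = 5, outer_folds = 5, alpha = 0.2, ...) {
  all_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    data <- generate_friedman(cell$n, cell$m_total, cell$sigma,
                              seed = .subseed(seed, 50000 + i))
    rows <- tryCatch(
      nested_cv_evaluate(data, model, estimators, repetitions = repetitions,
                         outer_folds = outer_folds, alpha = alpha,
                         seed = .subseed(seed, 60000 + i), ...),
      error = function(e) {
        warning("grid cell ", i, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(rows)) next
    rows$cell <- i
    rows$n <- cell$n
    rows$m_total <- cell$m_total
    rows$sigma <- cell$sigma
    rows$replicate <- cell$replicate
    all_rows[[i]] <- rows
  }
  results <- do.call(rbind, all_rows)
  structure(list(results = results, summary = summarize_grid(results, grid),
                 grid = grid),
            class = "grid_study")
}

#' Aggregate grid-study fold rows into marginal bins
#'
#' @param results fold rows as produced by [grid_study()].
#' @param grid the grid the rows came from (defines "largest n" and
#'   "smallest sigma" for the best-conditions bin); defaults to the
#'   ranges present in `results`.
#' @return data.frame with one row per (estimator, bin): `avg_cec`,
#'   `avg_capi`, `n_folds`.
#' @export
summarize_grid <- function(results, grid = NULL) {
  n_best <- if (is.null(grid)) max(results$n) else max(grid$n)
  s_best <- if (is.null(grid)) min(results$sigma) else min(grid$sigma)
  bins <- list(
    n_le_100 = results$n <= 100,
    n_gt_100 = results$n > 100,
    m_le_10 = results$m_selected <= 10,
    m_gt_10 = results$m_selected > 10,
    sigma_lt_1 = results$sigma < 1,
    sigma_ge_1 = results$sigma >= 1,
    best = results$n == n_best & results$m_selected <= 10 & results$sigma == s_best
  )
  out <- list()
  for (est in unique(results$estimator)) {
    e_rows <- results$estimator == est
    for (b in names(bins)) {
      sel <- e_rows & bins[[b]]
      out[[length(out) + 1]] <- data.frame(
        estimator = est, bin = b,
        avg_cec = mean(results$cec[sel], na.rm = TRUE),
        avg_capi = mean(results$capi[sel], na.rm = TRUE),
        n_folds = sum(sel & !is.na(results$cec)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.grid_study <- function(x, ...) {
  cat("<grid_study>", nrow(x$grid), "cells,",
      if (is.null(x$results)) 0 else nrow(x$results), "fold rows\n")
  cec_wide <- stats::reshape(x$summary[, c("estimator", "bin", "avg_cec")],
                             idvar = "estimator", timevar = "bin",
                             direction = "wide")
  names(cec_wide) <- sub("^avg_cec\\.", "", names(cec_wide))
  cat("average CEC by bin:\n")
  print(cec_wide, digits = 2, row.names = FALSE)
  invisible(x)
}

# ---- train + calibrate + predict convenience ---------------------------

#' Train a model with a calibrated confidence estimator
#'
#' Fits the regression model, computes out-of-fold training errors,
#' resolves the estimator's neighborhood size, and builds the calibration
#' table — everything needed to emit predictions with normalized
#' confidence scores and empirical confidence intervals for new data.
#'
#' @param train `conf_dataset` (raw features; standardization is handled
#'   internally and reapplied to new data).
#' @param model `predictor_spec`.
#' @param estimator `estimator_spec`.
#' @param alpha interval miss level (default 0.2).
#' @param window_halfwidth,min_pool calibration settings.
#' @param select_features run forward feature selection first.
#' @param seed integer seed.
#' @return An object of class `conf_regressor` with a `predict()` method.
#' @export
conf_regressor <- function(train, model = predictor_spec("ols_linear"),
                           estimator = estimator_spec("confine"), alpha = 0.2,
                           window_halfwidth = 0.1, min_pool = 30,
                           select_features = FALSE, seed = 1) {
  stopifnot(inherits(train, "conf_dataset"))
  fs_idx <- if (select_features)
    forward_feature_selection(train, model, seed = .subseed(seed, 1))
  else seq_len(ncol(train$features))
  tr_std <- standardize(.subset_cols(train, fs_idx))
  errs <- training_errors(tr_std, model, "cv", folds = 5, seed = .subseed(seed, 2))
  est <- estimator
  if (identical(est$k, "auto") && est$weighting == "uniform" &&
      est$name %in% c("confine", "confive", "localcv"))
    est$k <- .tune_k_multi(tr_std, list(est), model,
                           seed = .subseed(seed, 3), alpha = alpha,
                           window_halfwidth = window_halfwidth,
                           min_pool = min_pool)[[1]]
  if (est$weighting == "kernel" && is.null(est$bandwidth))
    est$bandwidth <- tune_bandwidth(tr_std, est, model,
                                    seed = .subseed(seed, 5), alpha = alpha,
                                    window_halfwidth = window_halfwidth,
                                    min_pool = min_pool)
  fitted <- fit_predictor(model, tr_std)
  ctx <- .make_ctx(tr_std, model = model, fitted = fitted, errors = errs,
                   seed = .subseed(seed, 4))
  raws_tr <- .batch_scores(est, tr_std$features, ctx, self = TRUE,
                           pred_q = errs$prediction)
  tab <- calibration_table(raws_tr, errs$signed_error, alpha = alpha,
                           window_halfwidth = window_halfwidth, min_pool = min_pool)
  structure(list(model = model, estimator = est, fitted = fitted, ctx = ctx,
                 table = tab, training_raws = raws_tr,
                 selected_features = fs_idx,
                 standardization = tr_std$standardization, alpha = alpha),
            class = "conf_regressor")
}

#' @export
print.conf_regressor <- function(x, ...) {
  cat(sprintf("<conf_regressor> %s model + %s estimator (k = %s), %d training instances\n",
              x$model$family, x$estimator$name, paste(x$estimator$k, collapse = ","),
              x$ctx$n))
  invisible(x)
}

#' Predict with confidence scores and intervals
#'
#' @param object `conf_regressor`.
#' @param newdata `conf_dataset` or numeric feature matrix with the same
#'   columns as the training data (before feature selection).
#' @param ... unused.
#' @return data.frame with one row per query: `prediction`, `raw_score`,
#'   `ncs`, `lower`, `upper`, `alpha`.
#' @export
predict.conf_regressor <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "conf_dataset")) newdata$features else as.matrix(newdata)
  X <- X[, object$selected_features, drop = FALSE]
  Xq <- .apply_standardization(X, object$standardization)
  pred <- predict(object$fitted, Xq)
  raws <- .batch_scores(object$estimator, Xq, object$ctx, self = FALSE, pred_q = pred)
  ncs <- normalize_score(raws, object$training_raws)
  off <- .interval_offsets(ncs, object$table)
  data.frame(prediction = pred, raw_score = raws, ncs = ncs,
             lower = pred + off[, "lower"], upper = pred + off[, "upper"],
             alpha = object$alpha)
}
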