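#' Normalize a raw confidence score against the training distribution
#'
#' The normalized confidence score (ncs) is the fraction of training
#' instances whose raw score is *strictly* smaller than the query's raw
#' score: an empirical-CDF rank in `[0, 1]`. Ties contribute nothing, so
#' tied scores deflate the ncs, never inflate it. The training raw scores
#' must have been computed with self-exclusion (a training row never
#' counts itself among its own neighbors).
#'
#' @param raw raw score(s) to normalize (vectorized).
#' @param training_raws nonempty vector of training raw scores.
#' @return ncs value(s) in `[0, 1]`.
#' @export
normalize_score <- function(raw, training_raws) {
  if (length(training_raws) == 0) .stop_arg("training_raws must be nonempty")
  s <- sort.int(training_raws, method = "radix")
  findInterval(raw, s, left.open = TRUE) / length(s)
}

# strictly-smaller count via findInterval on (t_i, t_{i+1}] intervals:
# findInterval(x, s, left.open = TRUE) == #{s < x} for sorted s.

#' Build a calibration table from training data
#'
#' The state needed to turn new raw scores into normalized scores and
#' empirical confidence intervals: one entry per training instance
#' holding its self-excluded raw score, its ncs, and its signed
#' out-of-fold error. Entries are kept sorted by ncs.
#'
#' @param raw_scores per-training-instance raw scores, computed with
#'   self-exclusion (see [build_calibration()] for the high-level path).
#' @param signed_errors matching signed out-of-fold errors (`y - yhat`).
#' @param alpha interval miss level in (0, 1); `1 - alpha` is the target
#'   coverage (default 0.2, i.e. 80% intervals).
#' @param window_halfwidth half-width of the ncs window used to pool
#'   errors of similarly scored instances (default 0.1).
#' @param min_pool minimum error-pool size; windows with fewer entries
#'   are expanded to the `min_pool` nearest-ncs entries (default 30, or
#'   n when n < 30).
#' @return An object of class `calibration_table`.
#' @export
calibration_table <- function(raw_scores, signed_errors, alpha = 0.2,
                              window_halfwidth = 0.1, min_pool = 30) {
  n <- length(raw_scores)
  if (n == 0) .stop_arg("empty calibration table")
  if (length(signed_errors) != n) .stop_arg("raw_scores and signed_errors lengths differ")
  if (!(alpha > 0 && alpha < 1)) .stop_arg("alpha must be in (0, 1)")
  if (!(window_halfwidth > 0 && window_halfwidth <= 0.5))
    .stop_arg("window_halfwidth must be in (0, 0.5]")
  ncs <- normalize_score(raw_scores, raw_scores)
  ord <- order(ncs, seq_len(n), method = "radix")
  entries <- data.frame(index = ord, raw_score = raw_scores[ord],
                        ncs = ncs[ord], signed_error = signed_errors[ord])
  structure(list(entries = entries, alpha = alpha,
                 window_halfwidth = window_halfwidth,
                 min_pool = as.integer(min(min_pool, n)),
                 training_raws = raw_scores, n = n,
                 s_ncs = entries$ncs, s_err = entries$signed_error),
            class = "calibration_table")
}

# Lean table for hot loops (k tuning): same fields .interval_offsets
# needs, no data.frame construction.
.cal_table_fast <- function(raw_scores, signed_errors, alpha, window_halfwidth,
                            min_pool) {
  n <- length(raw_scores)
  ncs <- findInterval(raw_scores, sort.int(raw_scores, method = "radix"),
                      left.open = TRUE) / n
  ord <- order(ncs, method = "radix")
  list(alpha = alpha, window_halfwidth = window_halfwidth,
       min_pool = as.integer(min(min_pool, n)), n = n,
       s_ncs = ncs[ord], s_err = signed_errors[ord])
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table> %d entries, alpha = %g, window = %g, min_pool = %d\n",
              x$n, x$alpha, x$window_halfwidth, x$min_pool))
  invisible(x)
}

#' Collect the error pool for a normalized confidence score
#'
#' Returns the signed out-of-fold errors of the training instances whose
#' ncs lies within the table's window of the query ncs. If fewer than
#' `min_pool` entries qualify, the window is expanded to the `min_pool`
#' entries with nearest ncs (ties by table index), so the pool never
#' falls below `min(min_pool, n)`. At the boundaries of the ncs scale the
#' pool is one-sidedly truncated.
#'
#' @param ncs normalized confidence score in `[0, 1]`.
#' @param table `calibration_table`.
#' @return Numeric vector of signed errors.
#' @export
error_pool <- function(ncs, table) {
  if (!inherits(table, "calibration_table")) .stop_arg("table must be a calibration_table")
  e <- table$entries
  inside <- abs(e$ncs - ncs) <= table$window_halfwidth + 1e-12
  if (sum(inside) >= table$min_pool) return(e$signed_error[inside])
  ord <- order(abs(e$ncs - ncs), seq_len(nrow(e)), method = "radix")
  e$signed_error[sort(ord[seq_len(table$min_pool)])]
}

#' Nearest-rank empirical quantile
#'
#' The p-quantile of a sample as the `ceiling(p * m)`-th smallest value
#' (the minimum for p = 0), with no interpolation and no distributional
#' assumption.
#'
#' @param values nonempty numeric vector.
#' @param p probability in `[0, 1]`.
#' @return One element of `values`.
#' @export
empirical_quantile <- function(values, p) {
  if (length(values) == 0) .stop_arg("empirical_quantile of empty input")
  if (!(p >= 0 && p <= 1)) .stop_arg("p must be in [0, 1]")
  s <- sort(values)
  s[max(1L, ceiling(p * length(s)))]
}

#' Score-based empirical confidence interval for one prediction
#'
#' Pools the signed errors of training instances with similar ncs and
#' shifts the prediction by their `alpha/2` and `1 - alpha/2` nearest-rank
#' quantiles. Because the pool holds signed errors, the interval may be
#' asymmetric around the prediction (it absorbs local bias).
#'
#' @param prediction model prediction (response units).
#' @param ncs normalized confidence score of this prediction, produced
#'   with the same estimator the table was built from.
#' @param table `calibration_table`.
#' @param raw_score optional raw score to record on the result.
#' @return A one-row data.frame of class `confident_prediction` with
#'   columns `prediction`, `raw_score`, `ncs`, `lower`, `upper`, `alpha`.
#' @export
score_interval <- function(prediction, ncs, table, raw_score = NA_real_) {
  pool <- error_pool(ncs, table)
  q_lo <- empirical_quantile(pool, table$alpha / 2)
  q_hi <- empirical_quantile(pool, 1 - table$alpha / 2)
  .confident_prediction(prediction, raw_score, ncs,
                        prediction + q_lo, prediction + q_hi, table$alpha)
}

#' General (score-independent) empirical confidence interval
#'
#' Same quantile construction as [score_interval()] but over the signed
#' errors of *all* training instances, ignoring confidence scores: the
#' general interval has the same width for every prediction and serves as
#' the uninformed reference. The returned `ncs` field is the sentinel -1.
#'
#' @inheritParams score_interval
#' @return A one-row `confident_prediction` data.frame.
#' @export
general_interval <- function(prediction, table) {
  if (!inherits(table, "calibration_table")) .stop_arg("table must be a calibration_table")
  errs <- table$entries$signed_error
  q_lo <- empirical_quantile(errs, table$alpha / 2)
  q_hi <- empirical_quantile(errs, 1 - table$alpha / 2)
  .confident_prediction(prediction, NA_real_, -1,
                        prediction + q_lo, prediction + q_hi, table$alpha)
}

.confident_prediction <- function(prediction, raw_score, ncs, lower, upper, alpha) {
  out <- data.frame(prediction = prediction, raw_score = raw_score, ncs = ncs,
                    lower = lower, upper = upper, alpha = alpha)
  class(out) <- c("confident_prediction", "data.frame")
  out
}

# ---- vectorized interval bounds (harness hot path) ----------------------

# Lower/upper interval offsets for a vector of ncs values against one
# table. Entries are sorted by ncs, so the window is a contiguous slice
# and the whole batch runs in compiled code; windows with fewer than
# min_pool entries are expanded to the min_pool nearest-ncs entries
# (nearer side first, left on ties), matching error_pool().
.interval_offsets <- function(ncs_vec, table) {
  out <- .cpp_interval_offsets(table$s_ncs, table$s_err, as.numeric(ncs_vec),
                               table$window_halfwidth, table$min_pool,
                               table$alpha / 2, 1 - table$alpha / 2)
  colnames(out) <- c("lower", "upper")
  out
}

#' Build a calibration table with an estimator
#'
#' High-level constructor: computes self-excluded raw scores for every
#' training instance with the given estimator, pairs them with signed
#' out-of-fold errors, and returns the [calibration_table()]. The
#' training features are expected to be standardized (the harness does
#' this; see [standardize()]).
#'
#' @param train `conf_dataset` (standardized features).
#' @param estimator `estimator_spec` with a concrete `k` where needed.
#' @param model `predictor_spec` (fitted internally when the estimator
#'   or the error computation needs it).
#' @param errors optional data.frame from [training_errors()]; computed
#'   in cv mode (5 folds) when missing.
#' @param alpha,window_halfwidth,min_pool see [calibration_table()].
#' @param seed integer seed (error folds, bootstrap resamples).
#' @return A `calibration_table`.
#' @export
build_calibration <- function(train, estimator, model = predictor_spec("ols_linear"),
                              errors = NULL, alpha = 0.2, window_halfwidth = 0.1,
                              min_pool = 30, seed = 1) {
  stopifnot(inherits(train, "conf_dataset"), inherits(estimator, "estimator_spec"))
  if (is.null(errors)) errors <- training_errors(train, model, "cv", folds = 5, seed = seed)
  fitted <- fit_predictor(model, train)
  ctx <- .make_ctx(train, model = model, fitted = fitted, errors = errors, seed = seed)
  spec <- estimator
  if (identical(spec$k, "auto")) spec$k <- .spec_k(spec, nrow(train$features) - 1L)
  raws <- .batch_scores(spec, train$features, ctx, self = TRUE,
                        pred_q = errors$prediction[order(errors$index)])
  calibration_table(raws, errors$signed_error[order(errors$index)],
                    alpha = alpha, window_halfwidth = window_halfwidth,
                    min_pool = min_pool)
}
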