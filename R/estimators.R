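#' Specify a confidence estimator
#'
#' Configuration for one of the eight per-prediction confidence
#' estimators. All estimators return a *raw score* in which larger means
#' more confident (errors, variances and distances are negated), so that
#' downstream rank normalization and interval calibration treat them
#' uniformly.
#'
#' Estimators:
#' \describe{
#'   \item{confine}{negated mean squared out-of-fold error of the k
#'     nearest training neighbors (error transfer from the local
#'     environment); `weighting = "kernel"` replaces the fixed
#'     neighborhood by Gaussian kernel-density weights over all rows.}
#'   \item{confive}{negated sample variance of the k nearest neighbors'
#'     response values; model-independent; kernel variant as above.}
#'   \item{nonn}{number of training rows within `radius` (a density
#'     estimate of the applicability domain).}
#'   \item{diffnn}{negated absolute difference between the model
#'     prediction and the mean response of the k nearest neighbors
#'     (default k = 5).}
#'   \item{avgdist}{negated average Euclidean distance to all training
#'     rows.}
#'   \item{localcv}{negated distance-weighted mean of the leave-one-out
#'     absolute errors of the k nearest neighbors.}
#'   \item{localvar}{negated variance of re-predictions after the query
#'     is injected into the training set with perturbed response values
#'     (local sensitivity of the model).}
#'   \item{bagging}{negated variance of the predictions of
#'     `n_bootstrap` bootstrap-resampled models.}
#' }
#'
#' @param name estimator name (see above).
#' @param k neighborhood size where applicable. `"auto"` (the default for
#'   confine/confive) means: tuned by [tune_k()] inside the evaluation
#'   protocol, or `min(10, n - 1)` when scored directly. diffnn defaults
#'   to 5, localcv to 10.
#' @param weighting `"uniform"` or `"kernel"` (confine/confive only).
#' @param bandwidth Gaussian kernel bandwidth for the kernel variants;
#'   `NULL` means the median pairwise training distance.
#' @param radius neighborhood radius for nonn; `NULL` means the median
#'   5th-nearest-neighbor distance of the training rows.
#' @param n_bootstrap number of bootstrap models for bagging (>= 2).
#' @param perturbation_fractions response perturbations for localvar, as
#'   fractions of the training response range; must be symmetric about 0.
#' @param localcv_scope `"full"` (leave-one-out refits use the full
#'   training set minus one neighbor; default) or `"neighborhood"`
#'   (refits use only the k-neighborhood minus one).
#' @return An object of class `estimator_spec`.
#' @export
estimator_spec <- function(name = c("confine", "confive", "nonn", "diffnn",
                                    "avgdist", "localcv", "localvar", "bagging"),
                           k = NULL,
                           weighting = c("uniform", "kernel"),
                           bandwidth = NULL, radius = NULL,
                           n_bootstrap = 20,
                           perturbation_fractions = c(-0.5, -0.1, -0.01, 0.01, 0.1, 0.5),
                           localcv_scope = c("full", "neighborhood")) {
  name <- match.arg(name)
  weighting <- match.arg(weighting)
  localcv_scope <- match.arg(localcv_scope)
  if (is.null(k)) {
    k <- switch(name, confine = "auto", confive = "auto", diffnn = 5,
                localcv = 10, NA)
  }
  if (is.numeric(k)) {
    if (!.is_count(k) || k < 1) .stop_arg("k must be a positive integer")
    if (name == "confive" && k < 2) .stop_arg("confive needs k >= 2")
    k <- as.integer(k)
  }
  if (!is.null(bandwidth) && (!is.numeric(bandwidth) || bandwidth <= 0))
    .stop_arg("bandwidth must be a positive real")
  if (!is.null(radius) && (!is.numeric(radius) || radius <= 0))
    .stop_arg("radius must be a positive real")
  if (!.is_count(n_bootstrap) || n_bootstrap < 2)
    .stop_arg("n_bootstrap must be an integer >= 2")
  pf <- as.numeric(perturbation_fractions)
  if (length(pf) == 0) .stop_arg("perturbation_fractions must be nonempty")
  if (max(abs(sort(pf) + rev(sort(pf)))) > 1e-12)
    .stop_arg("perturbation_fractions must be symmetric about 0")
  structure(list(name = name, k = k, weighting = weighting,
                 bandwidth = bandwidth, radius = radius,
                 n_bootstrap = as.integer(n_bootstrap),
                 perturbation_fractions = pf,
                 localcv_scope = localcv_scope),
            class = "estimator_spec")
}

#' @export
print.estimator_spec <- function(x, ...) {
  cat(sprintf("<estimator_spec> %s (k = %s, weighting = %s)\n",
              x$name, paste(x$k, collapse = ","), x$weighting))
  invisible(x)
}

# Concrete k for direct scoring: "auto" falls back to min(10, n_avail).
.spec_k <- function(spec, n_avail) {
  k <- if (identical(spec$k, "auto")) min(10L, n_avail) else spec$k
  if (!is.na(k) && k > n_avail)
    .stop_arg("k = ", k, " exceeds the ", n_avail, " available training rows")
  as.integer(k)
}

.gauss_weights <- function(d2, bandwidth) exp(-d2 / (2 * bandwidth^2))

# ---- public single-prediction scoring functions -------------------------

#' Neighborhood-error confidence score (CONFINE)
#'
#' Raw confidence of a single prediction based on the mean squared
#' out-of-fold error of the query's nearest training neighbors: the local
#' error of the model is transferred to the query. Uniform weighting
#' averages over the k nearest neighbors; kernel weighting averages over
#' all training rows with Gaussian distance weights.
#'
#' @param query numeric feature row (standardized like `train`).
#' @param train `conf_dataset` (standardized features).
#' @param errors data.frame from [training_errors()] covering every
#'   training row.
#' @param spec `estimator_spec` with `name = "confine"`.
#' @return Raw score (<= 0; larger = more confident; 0 = perfect local fit).
#' @export
confine_score <- function(query, train, errors, spec = estimator_spec("confine")) {
  stopifnot(inherits(train, "conf_dataset"))
  n <- nrow(train$features)
  if (nrow(errors) != n) .stop_arg("errors must cover all training rows")
  err2 <- if (is.unsorted(errors$index)) errors$squared_error[order(errors$index)]
          else errors$squared_error
  if (spec$weighting == "uniform") {
    k <- .spec_k(spec, n)
    idx <- .cpp_query_topk(train$features, as.numeric(query), k)
    -mean(err2[idx])
  } else {
    d2 <- .cpp_query_dist2(train$features, as.numeric(query))
    bw <- if (is.null(spec$bandwidth)) .median_pairwise_dist(train$features) else spec$bandwidth
    w <- .gauss_weights(d2, bw)
    if (all(w < 1e-300)) .stop_arg("degenerate neighborhood: all kernel weights underflow")
    -sum(w * err2) / sum(w)
  }
}

#' Local response-variance confidence score (CONFIVE)
#'
#' Raw confidence based on the sample variance of the response values of
#' the k nearest training neighbors: a locally heterogeneous response is
#' hard to model, so large variance means low confidence. Independent of
#' the regression model.
#'
#' @inheritParams confine_score
#' @param spec `estimator_spec` with `name = "confive"` (k >= 2).
#' @return Raw score (<= 0; 0 when all neighbor responses are equal).
#' @export
confive_score <- function(query, train, spec = estimator_spec("confive")) {
  stopifnot(inherits(train, "conf_dataset"))
  n <- nrow(train$features)
  if (spec$weighting == "uniform") {
    k <- .spec_k(spec, n)
    if (k < 2) .stop_arg("confive needs k >= 2")
    idx <- .cpp_query_topk(train$features, as.numeric(query), k)
    -stats::var(train$response[idx])
  } else {
    d2 <- .cpp_query_dist2(train$features, as.numeric(query))
    bw <- if (is.null(spec$bandwidth)) .median_pairwise_dist(train$features) else spec$bandwidth
    w <- .gauss_weights(d2, bw)
    if (all(w < 1e-300)) .stop_arg("degenerate neighborhood: all kernel weights underflow")
    mu <- sum(w * train$response) / sum(w)
    -sum(w * (train$response - mu)^2) / sum(w)
  }
}

#' Density, neighbor-difference and distance baseline scores
#'
#' The three fast applicability-domain baselines: `nonn` counts training
#' rows within `radius` of the query; `diffnn` negates the absolute
#' difference between the model prediction and the mean response of the
#' k nearest neighbors; `avgdist` negates the mean Euclidean distance to
#' all training rows.
#'
#' @param method `"nonn"`, `"diffnn"` or `"avgdist"`.
#' @inheritParams confine_score
#' @param prediction model prediction for the query (required by diffnn).
#' @param spec `estimator_spec` of the matching name.
#' @return Raw score (larger = more confident).
#' @export
neighborhood_baseline_score <- function(method = c("nonn", "diffnn", "avgdist"),
                                        query, train, prediction = NULL,
                                        spec = estimator_spec(method)) {
  method <- match.arg(method)
  stopifnot(inherits(train, "conf_dataset"))
  switch(method,
    nonn = {
      r <- if (is.null(spec$radius)) .default_radius(train$features) else spec$radius
      d2 <- .cpp_query_dist2(train$features, as.numeric(query))
      sum(d2 <= r * r)
    },
    diffnn = {
      if (is.null(prediction)) .stop_arg("diffnn requires the model prediction")
      k <- .spec_k(spec, nrow(train$features))
      idx <- .cpp_query_topk(train$features, as.numeric(query), k)
      -abs(prediction - mean(train$response[idx]))
    },
    avgdist = -mean(sqrt(.cpp_query_dist2(train$features, as.numeric(query))))
  )
}

#' Bootstrap-ensemble variance confidence score
#'
#' Fits the model on `n_bootstrap` seeded with-replacement resamples of
#' the training data, predicts the query with each, and negates the
#' sample variance of those predictions: disagreement among the ensemble
#' signals low confidence.
#'
#' @inheritParams confine_score
#' @param model `predictor_spec`.
#' @param spec `estimator_spec` with `name = "bagging"`.
#' @param seed integer seed for the resamples.
#' @return Raw score (<= 0; 0 when all bootstrap predictions agree).
#' @export
bagging_score <- function(query, train, model, spec = estimator_spec("bagging"),
                          seed = 1) {
  stopifnot(inherits(train, "conf_dataset"), inherits(model, "predictor_spec"))
  models <- .bagging_models(train, model, spec$n_bootstrap, seed)
  preds <- vapply(models, function(f) predict(f, matrix(query, nrow = 1)), 0)
  -stats::var(preds)
}

# Fit the bootstrap ensemble; a resample whose fit fails is redrawn up to
# 10 times before erroring.
.bagging_models <- function(train, model, B, seed) {
  n <- nrow(train$features)
  lapply(seq_len(B), function(b) {
    for (attempt in 1:10) {
      idx <- with_seed(.subseed(seed, b * 100 + attempt), sample(n, n, replace = TRUE))
      f <- tryCatch(fit_predictor(model, .subset_rows(train, idx)), error = function(e) NULL)
      if (!is.null(f)) return(f)
    }
    .stop_arg("bootstrap resample ", b, ": model fit failed 10 times")
  })
}

#' Local cross-validation confidence score
#'
#' For each of the query's k nearest neighbors, refits the model on the
#' training data minus that neighbor, predicts it, and combines the
#' absolute leave-one-out errors with inverse-distance weights
#' `1/(d + 1e-8)`.
#'
#' @inheritParams bagging_score
#' @param spec `estimator_spec` with `name = "localcv"` (k >= 2).
#' @return Raw score (<= 0).
#' @export
localcv_score <- function(query, train, model, spec = estimator_spec("localcv")) {
  stopifnot(inherits(train, "conf_dataset"), inherits(model, "predictor_spec"))
  n <- nrow(train$features)
  k <- .spec_k(spec, n)
  if (k < 2) .stop_arg("localcv needs k >= 2")
  nb <- nearest_neighbors(query, train, k)
  a <- vapply(seq_len(k), function(j) {
    i <- nb$indices[j]
    pool <- if (spec$localcv_scope == "full") setdiff(seq_len(n), i)
            else setdiff(nb$indices, i)
    f <- tryCatch(fit_predictor(model, .subset_rows(train, pool)),
                  error = function(e) .stop_arg("localcv refit failed for neighbor ", i,
                                                ": ", conditionMessage(e)))
    abs(train$response[i] - predict(f, train$features[i, , drop = FALSE]))
  }, 0)
  w <- 1 / (nb$distances + 1e-8)
  -sum(w * a) / sum(w)
}

#' Local sensitivity confidence score
#'
#' Measures how strongly the model reacts to the query being added to the
#' training data: for each perturbation fraction f, the query is appended
#' with response `yhat0 + f * (max(y) - min(y))`, the model is refitted
#' and the query re-predicted. The raw score is the negated sample
#' variance of the re-predictions.
#'
#' @inheritParams bagging_score
#' @param spec `estimator_spec` with `name = "localvar"`.
#' @return Raw score (<= 0; 0 for a model insensitive to one added point).
#' @export
localvar_score <- function(query, train, model, spec = estimator_spec("localvar")) {
  stopifnot(inherits(train, "conf_dataset"), inherits(model, "predictor_spec"))
  rng <- range(train$response)
  if (diff(rng) == 0) .stop_arg("degenerate response range: constant training response")
  fitted <- fit_predictor(model, train)
  q <- matrix(as.numeric(query), nrow = 1)
  yhat0 <- predict(fitted, q)
  Xa <- rbind(train$features, q)
  preds <- vapply(yhat0 + spec$perturbation_fractions * diff(rng), function(t) {
    f <- fit_predictor(model, Xa, c(train$response, t))
    predict(f, q)
  }, 0)
  -stats::var(preds)
}

# Refit under each perturbed response and re-predict the query. OLS uses
# one QR factorization with a matrix response; other families loop.
.localvar_repredict <- function(Xa, y, targets, model, q) {
  if (model$family == "ols_linear") {
    Ymat <- rbind(matrix(y, nrow = length(y), ncol = length(targets)), targets)
    co <- .fit_ols_multi(Xa, Ymat)
    as.numeric(cbind(1, q) %*% co)
  } else {
    vapply(targets, function(t) {
      f <- fit_predictor(model, Xa, c(y, t))
      predict(f, q)
    }, 0)
  }
}

# ---- defaults derived from the training geometry ------------------------

.median_pairwise_dist <- function(X) {
  n <- nrow(X)
  idx <- if (n > 300) with_seed(7L, sample(n, 300)) else seq_len(n)
  D <- .dist_mat(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
  stats::median(D[upper.tri(D)])
}

# NoNN default radius: median distance to the 5th nearest neighbor
# (self-excluded) among training rows.
.default_radius <- function(X) {
  n <- nrow(X)
  k <- min(5L, n - 1L)
  D <- .dist_mat(X, X)
  diag(D) <- Inf
  d5 <- apply(D, 1, function(r) sort(r, partial = k)[k])
  stats::median(d5)
}

# ---- batch scoring engine (used by calibration and the harness) ---------

# Context shared by all batch scorers for one training set: standardized
# features, responses, out-of-fold errors, a fitted model, and a cache
# for quantities reusable across query batches (bootstrap ensembles,
# leave-one-out errors, default radius/bandwidth).
.make_ctx <- function(train_std, model = NULL, fitted = NULL, errors = NULL, seed = 1L) {
  err2 <- signed <- NULL
  if (!is.null(errors)) {
    ord <- order(errors$index)
    err2 <- errors$squared_error[ord]
    signed <- errors$signed_error[ord]
  }
  list(X = train_std$features, y = train_std$response, n = nrow(train_std$features),
       train = train_std, model = model, fitted = fitted,
       err2 = err2, signed = signed, seed = as.integer(seed), cache = new.env(parent = emptyenv()))
}

.ctx_radius <- function(spec, ctx) {
  if (!is.null(spec$radius)) return(spec$radius)
  if (is.null(ctx$cache$radius)) ctx$cache$radius <- .default_radius(ctx$X)
  ctx$cache$radius
}

.ctx_bandwidth <- function(spec, ctx) {
  if (!is.null(spec$bandwidth)) return(spec$bandwidth)
  if (is.null(ctx$cache$bandwidth)) ctx$cache$bandwidth <- .median_pairwise_dist(ctx$X)
  ctx$cache$bandwidth
}

# All-row leave-one-out absolute errors for localcv ("full" scope): the
# refit leaves out the predicted row itself, so the errors do not depend
# on the query and are computed once per training set.
.ctx_loo_abs <- function(ctx) {
  if (!is.null(ctx$cache$loo)) return(ctx$cache$loo)
  n <- ctx$n
  a <- vapply(seq_len(n), function(i) {
    f <- fit_predictor(ctx$model, ctx$X[-i, , drop = FALSE], ctx$y[-i])
    abs(ctx$y[i] - predict(f, ctx$X[i, , drop = FALSE]))
  }, 0)
  ctx$cache$loo <- a
  a
}

.ctx_bagging <- function(spec, ctx) {
  key <- paste0("bag", spec$n_bootstrap)
  if (is.null(ctx$cache[[key]]))
    ctx$cache[[key]] <- .bagging_models(ctx$train, ctx$model, spec$n_bootstrap, ctx$seed)
  ctx$cache[[key]]
}

# Distance matrix plus row-wise neighbor order for a query batch,
# computable once and shared by several estimators.
.query_geom <- function(Xq, ctx, self = FALSE, kmax = 0L) {
  D2 <- .dist2_mat(Xq, ctx$X)
  if (self) D2[cbind(seq_len(nrow(Xq)), seq_len(nrow(Xq)))] <- Inf
  list(D2 = D2, ord = if (kmax > 0) .cpp_topk_indices(D2, as.integer(kmax)) else NULL)
}

# Raw scores for a matrix of queries. `self = TRUE` means the queries ARE
# the training rows (in order); neighbor-based estimators then exclude
# each row from its own neighborhood. `pred_q` carries the model
# predictions for the queries (needed by diffnn and localvar); `geom` an
# optional precomputed .query_geom() for the same (Xq, self).
.batch_scores <- function(spec, Xq, ctx, self = FALSE, pred_q = NULL, geom = NULL) {
  nq <- nrow(Xq)
  n <- ctx$n
  n_avail <- n - as.integer(self)
  name <- spec$name

  if (name == "bagging") {
    models <- .ctx_bagging(spec, ctx)
    P <- vapply(models, function(f) predict(f, Xq), numeric(nq))
    P <- matrix(P, nrow = nq)
    return(-.row_vars(P))
  }
  if (name == "localvar") {
    rng <- range(ctx$y)
    if (diff(rng) == 0) .stop_arg("degenerate response range: constant training response")
    if (is.null(pred_q)) pred_q <- predict(ctx$fitted, Xq)
    out <- numeric(nq)
    for (i in seq_len(nq)) {
      q <- Xq[i, , drop = FALSE]
      preds <- .localvar_repredict(rbind(ctx$X, q), ctx$y,
                                   pred_q[i] + spec$perturbation_fractions * diff(rng),
                                   ctx$model, q)
      out[i] <- -stats::var(preds)
    }
    return(out)
  }

  D2 <- if (!is.null(geom)) geom$D2 else {
    D <- .dist2_mat(Xq, ctx$X)
    if (self) D[cbind(seq_len(nq), seq_len(nq))] <- Inf
    D
  }

  if (name == "avgdist") {
    D <- sqrt(D2)
    if (self) D[cbind(seq_len(nq), seq_len(nq))] <- 0
    return(-rowSums(D) / n_avail)
  }
  if (name == "nonn") {
    r <- .ctx_radius(spec, ctx)
    return(rowSums(sqrt(D2) <= r))
  }
  if (name %in% c("confine", "confive") && spec$weighting == "kernel") {
    bw <- .ctx_bandwidth(spec, ctx)
    W <- .gauss_weights(D2, bw)
    if (self) W[cbind(seq_len(nq), seq_len(nq))] <- 0
    sw <- rowSums(W)
    if (any(sw < 1e-300)) .stop_arg("degenerate neighborhood: all kernel weights underflow")
    if (name == "confine") return(-as.numeric(W %*% ctx$err2) / sw)
    mu <- as.numeric(W %*% ctx$y) / sw
    return(-rowSums(W * (outer(mu, ctx$y, function(a, b) (b - a)^2))) / sw)
  }

  k <- .spec_k(spec, n_avail)
  ordk <- if (!is.null(geom) && !is.null(geom$ord) && ncol(geom$ord) >= k)
    geom$ord[, seq_len(k), drop = FALSE]
  else .cpp_topk_indices(D2, k)
  switch(name,
    confine = {
      -rowMeans(matrix(ctx$err2[ordk], nrow = nq))
    },
    confive = {
      if (k < 2) .stop_arg("confive needs k >= 2")
      -.row_vars(matrix(ctx$y[ordk], nrow = nq))
    },
    diffnn = {
      if (is.null(pred_q)) pred_q <- predict(ctx$fitted, Xq)
      -abs(pred_q - rowMeans(matrix(ctx$y[ordk], nrow = nq)))
    },
    localcv = {
      if (k < 2) .stop_arg("localcv needs k >= 2")
      Dk <- matrix(D2[cbind(rep(seq_len(nq), k), as.vector(ordk))], nrow = nq)
      W <- 1 / (sqrt(Dk) + 1e-8)
      if (spec$localcv_scope == "full") {
        a <- .ctx_loo_abs(ctx)
        A <- matrix(a[ordk], nrow = nq)
        -rowSums(W * A) / rowSums(W)
      } else {
        out <- numeric(nq)
        for (i in seq_len(nq)) {
          nbrs <- ordk[i, ]
          a <- vapply(seq_len(k), function(j) {
            pool <- nbrs[-j]
            f <- fit_predictor(ctx$model, ctx$X[pool, , drop = FALSE], ctx$y[pool])
            abs(ctx$y[nbrs[j]] - predict(f, ctx$X[nbrs[j], , drop = FALSE]))
          }, 0)
          out[i] <- -sum(W[i, ] * a) / sum(W[i, ])
        }
        out
      }
    },
    .stop_arg("unknown estimator: ", name)
  )
}
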