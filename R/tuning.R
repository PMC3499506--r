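# Cumulative-statistics scoring over candidate neighborhood sizes: given
# the row-wise neighbor order, raw scores for every candidate k come from
# cumulative sums along the neighbor sequence, so one pass serves the
# whole candidate grid.

.confine_scores_all_k <- function(ordmat, err2, ks) {
  kmax <- max(ks)
  E <- matrix(err2[ordmat[, seq_len(kmax), drop = FALSE]], nrow = nrow(ordmat))
  cs <- .cpp_row_cumsum(E)
  vapply(ks, function(k) -cs[, k] / k, numeric(nrow(ordmat)))
}

.confive_scores_all_k <- function(ordmat, y, ks) {
  kmax <- max(ks)
  Y <- matrix(y[ordmat[, seq_len(kmax), drop = FALSE]], nrow = nrow(ordmat))
  s1 <- .cpp_row_cumsum(Y)
  s2 <- .cpp_row_cumsum(Y^2)
  vapply(ks, function(k) {
    v <- (s2[, k] - s1[, k]^2 / k) / (k - 1)
    -pmax(v, 0)
  }, numeric(nrow(ordmat)))
}

.localcv_scores_all_k <- function(ordmat, D2, loo_abs, ks) {
  nq <- nrow(ordmat)
  kmax <- max(ks)
  idx <- ordmat[, seq_len(kmax), drop = FALSE]
  W <- 1 / (sqrt(matrix(D2[cbind(rep(seq_len(nq), kmax), as.vector(idx))], nrow = nq)) + 1e-8)
  A <- matrix(loo_abs[idx], nrow = nq)
  cwa <- .cpp_row_cumsum(W * A)
  cw <- .cpp_row_cumsum(W)
  vapply(ks, function(k) -cwa[, k] / cw[, k], numeric(nq))
}

.default_k_grid <- function(n_max) {
  ks <- c(2L, 4L, 8L, 16L, 32L, 64L)
  ks <- ks[ks <= n_max]
  if (length(ks) == 0) .stop_arg("no feasible neighborhood size for n = ", n_max)
  ks
}

#' Tune the neighborhood size of a confidence estimator
#'
#' Selects k by five seeded two-fold cross-validations on the training
#' data: for each half-split, the estimator is calibrated on one half,
#' the other half is scored and interval-ized, and the CEC over the held
#' half is recorded for every candidate k. The per-fold argmax (first on
#' ties) is recorded, and the rounded mean of the ten argmaxes, clamped
#' to the candidate range, is returned. Two-fold splits keep the held
#' half large, which stabilizes the CEC.
#'
#' @param train `conf_dataset`.
#' @param estimator `estimator_spec` with a tunable k
#'   (confine/confive/localcv).
#' @param model `predictor_spec`.
#' @param candidates integer candidate values; `NULL` means a geometric
#'   grid `{2, 4, 8, 16, 32, 64}` clamped to the half-split size.
#' @param seed integer seed.
#' @param alpha,window_halfwidth,min_pool calibration settings used while
#'   scoring candidates.
#' @return The chosen k (integer).
#' @export
tune_k <- function(train, estimator, model, candidates = NULL, seed = 1,
                   alpha = 0.2, window_halfwidth = 0.1, min_pool = 30) {
  .tune_k_multi(train, list(estimator), model, candidates = candidates,
                seed = seed, alpha = alpha, window_halfwidth = window_halfwidth,
                min_pool = min_pool)[[1]]
}

# Joint tuning of several estimators over shared half-splits: the split,
# the standardization, the distance matrices and the out-of-fold errors
# are computed once per half and reused by every estimator.
.tune_k_multi <- function(train, estimators, model, candidates = NULL, seed = 1,
                          alpha = 0.2, window_halfwidth = 0.1, min_pool = 30) {
  stopifnot(inherits(train, "conf_dataset"))
  n <- nrow(train$features)
  if (n < 8) .stop_arg("tune_k needs at least 8 instances")
  n_half <- floor(n / 2)
  if (is.null(candidates)) candidates <- .default_k_grid(n_half - 1L)
  candidates <- sort(unique(as.integer(candidates)))
  min_k <- min(vapply(estimators, function(e)
    if (e$name %in% c("confive", "localcv")) 2L else 1L, 0L))
  if (any(candidates < min_k)) .stop_arg("candidate k below the estimator's minimum")
  candidates <- candidates[candidates <= n_half - 1L]
  if (length(candidates) == 0)
    .stop_arg("all candidate neighborhood sizes are infeasible for half-size ", n_half)
  picks <- replicate(length(estimators), integer(0), simplify = FALSE)
  for (rep_i in 1:5) {
    perm <- with_seed(.subseed(seed, rep_i), sample(n))
    halves <- list(perm[seq_len(n_half)], perm[(n_half + 1):n])
    for (h in 1:2) {
      A <- .subset_rows(train, halves[[h]])
      B <- .subset_rows(train, halves[[3 - h]])
      A_std <- standardize(A)
      Xb <- .apply_standardization(B$features, A_std$standardization)
      errs <- training_errors(A_std, model, "cv", folds = 5,
                              seed = .subseed(seed, rep_i * 10 + h))
      fitted <- fit_predictor(model, A_std)
      abs_B <- abs(B$response - predict(fitted, Xb))
      kmax <- max(candidates)
      Daa2 <- .dist2_mat(A_std$features, A_std$features)
      diag(Daa2) <- Inf
      orda <- .cpp_topk_indices(Daa2, kmax)
      Dba2 <- .dist2_mat(Xb, A_std$features)
      ordb <- .cpp_topk_indices(Dba2, kmax)
      err2 <- errs$squared_error
      signed <- errs$signed_error
      loo <- NULL
      for (ei in seq_along(estimators)) {
        est <- estimators[[ei]]
        ks <- candidates
        if (est$name %in% c("confive", "localcv")) ks <- ks[ks >= 2]
        rawsA <- switch(est$name,
          confine = .confine_scores_all_k(orda, err2, ks),
          confive = .confive_scores_all_k(orda, A_std$response, ks),
          localcv = {
            if (is.null(loo)) {
              ctx <- .make_ctx(A_std, model = model)
              loo <- .ctx_loo_abs(ctx)
            }
            .localcv_scores_all_k(orda, Daa2, loo, ks)
          },
          .stop_arg("tune_k does not apply to estimator '", est$name, "'")
        )
        rawsB <- switch(est$name,
          confine = .confine_scores_all_k(ordb, err2, ks),
          confive = .confive_scores_all_k(ordb, A_std$response, ks),
          localcv = .localcv_scores_all_k(ordb, Dba2, loo, ks)
        )
        cecs <- vapply(seq_along(ks), function(j) {
          tab <- .cal_table_fast(rawsA[, j], signed, alpha = alpha,
                                 window_halfwidth = window_halfwidth,
                                 min_pool = min_pool)
          ncsB <- findInterval(rawsB[, j],
                               sort.int(rawsA[, j], method = "radix"),
                               left.open = TRUE) / nrow(rawsA)
          off <- .interval_offsets(ncsB, tab)
          as.numeric(cec(abs_B, off[, 2L] - off[, 1L]))
        }, 0)
        picks[[ei]] <- c(picks[[ei]], ks[which.max(cecs)])
      }
    }
  }
  lapply(picks, function(p) {
    k <- as.integer(round(mean(p)))
    max(min(candidates), min(max(candidates), k))
  })
}

#' Tune the kernel bandwidth of a kernel-weighted estimator
#'
#' Same five two-fold cross-validation machinery as [tune_k()], applied
#' to the Gaussian bandwidth of the kernel-weighted neighborhood
#' estimators: candidate bandwidths are multiples of the median pairwise
#' training distance, each half-split is calibrated and the held half
#' scored, and the mean of the per-fold argmax multiples (clamped to the
#' candidate range) is applied to the full-data median distance.
#'
#' @param train `conf_dataset` (standardized features).
#' @param estimator `estimator_spec` for confine or confive with
#'   `weighting = "kernel"`.
#' @param model `predictor_spec` (needed for confine's training errors).
#' @param multiples positive candidate multipliers of the median pairwise
#'   distance.
#' @param seed integer seed.
#' @param alpha,window_halfwidth,min_pool calibration settings used while
#'   scoring candidates.
#' @return The chosen bandwidth (response-space units of the
#'   standardized feature distances).
#' @export
tune_bandwidth <- function(train, estimator, model,
                           multiples = c(0.25, 0.5, 1, 2, 4), seed = 1,
                           alpha = 0.2, window_halfwidth = 0.1, min_pool = 30) {
  stopifnot(inherits(train, "conf_dataset"))
  if (!(estimator$name %in% c("confine", "confive")) ||
      estimator$weighting != "kernel")
    .stop_arg("bandwidth tuning applies to kernel-weighted confine/confive only")
  if (any(multiples <= 0)) .stop_arg("multiples must be positive")
  multiples <- sort(unique(multiples))
  n <- nrow(train$features)
  if (n < 8) .stop_arg("tune_bandwidth needs at least 8 instances")
  n_half <- floor(n / 2)
  picks <- numeric(0)
  for (rep_i in 1:5) {
    perm <- with_seed(.subseed(seed, rep_i), sample(n))
    halves <- list(perm[seq_len(n_half)], perm[(n_half + 1):n])
    for (h in 1:2) {
      A <- .subset_rows(train, halves[[h]])
      B <- .subset_rows(train, halves[[3 - h]])
      A_std <- standardize(A)
      Xb <- .apply_standardization(B$features, A_std$standardization)
      errs <- training_errors(A_std, model, "cv", folds = 5,
                              seed = .subseed(seed, rep_i * 10 + h))
      fitted <- fit_predictor(model, A_std)
      abs_B <- abs(B$response - predict(fitted, Xb))
      med <- .median_pairwise_dist(A_std$features)
      Daa2 <- .dist2_mat(A_std$features, A_std$features)
      diag(Daa2) <- Inf
      Dba2 <- .dist2_mat(Xb, A_std$features)
      err2 <- errs$squared_error
      kernel_raws <- function(D2, self, bw) {
        W <- .gauss_weights(D2, bw)
        if (self) W[!is.finite(D2)] <- 0
        sw <- rowSums(W)
        sw[sw < 1e-300] <- 1e-300
        if (estimator$name == "confine") -as.numeric(W %*% err2) / sw
        else {
          mu <- as.numeric(W %*% A_std$response) / sw
          -rowSums(W * outer(mu, A_std$response, function(a, b) (b - a)^2)) / sw
        }
      }
      cecs <- vapply(multiples, function(mult) {
        bw <- mult * med
        rawsA <- kernel_raws(Daa2, TRUE, bw)
        rawsB <- kernel_raws(Dba2, FALSE, bw)
        tab <- .cal_table_fast(rawsA, errs$signed_error, alpha = alpha,
                               window_halfwidth = window_halfwidth,
                               min_pool = min_pool)
        ncsB <- findInterval(rawsB, sort.int(rawsA, method = "radix"),
                             left.open = TRUE) / length(rawsA)
        off <- .interval_offsets(ncsB, tab)
        as.numeric(cec(abs_B, off[, 2L] - off[, 1L]))
      }, 0)
      picks <- c(picks, multiples[which.max(cecs)])
    }
  }
  mult <- max(min(multiples), min(max(multiples), mean(picks)))
  mult * .median_pairwise_dist(train$features)
}
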