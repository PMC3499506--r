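#' Construct a regression dataset
#'
#' The universal input container of the package: a numeric feature matrix
#' with one continuous response per row. Row order is meaningful (training
#' indices are referenced throughout), and an optional per-column
#' standardization record (centers and scales learned from training data)
#' travels with the object so that distance computations on new data reuse
#' the training statistics.
#'
#' @param features numeric matrix (n rows, d columns), all values finite.
#' @param response numeric vector of length n, all values finite.
#' @param feature_names optional character vector of d column identifiers;
#'   defaults to the matrix column names or `x1..xd`.
#' @return An object of class `conf_dataset` with elements `features`,
#'   `response`, `feature_names`, `standardization` (NULL until
#'   [standardize()] is applied).
#' @seealso [standardize()], [read_dataset()], [generate_friedman()]
#' @export
conf_dataset <- function(features, response, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  response <- as.numeric(response)
  if (nrow(features) < 1) .stop_arg("dataset needs at least one row")
  if (length(response) != nrow(features))
    .stop_arg("response length (", length(response), ") does not match number of feature rows (",
              nrow(features), ")")
  if (!all(is.finite(features))) .stop_arg("features contain non-finite values")
  if (!all(is.finite(response))) .stop_arg("response contains non-finite values")
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features))
    .stop_arg("feature_names must have one entry per feature column")
  colnames(features) <- feature_names
  structure(
    list(features = features, response = response,
         feature_names = feature_names, standardization = NULL),
    class = "conf_dataset"
  )
}

#' @export
print.conf_dataset <- function(x, ...) {
  cat(sprintf("<conf_dataset> %d instances x %d features%s\n",
              nrow(x$features), ncol(x$features),
              if (is.null(x$standardization)) "" else " (standardized)"))
  invisible(x)
}

#' @export
dim.conf_dataset <- function(x) dim(x$features)

# Row subset of a dataset, keeping the standardization record.
.subset_rows <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[idx, , drop = FALSE]
  out$response <- ds$response[idx]
  out
}

# Column subset (feature selection), dropping any standardization record
# because centers/scales no longer line up by construction order.
.subset_cols <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[, idx, drop = FALSE]
  out$feature_names <- ds$feature_names[idx]
  if (!is.null(ds$standardization)) {
    out$standardization <- list(center = ds$standardization$center[idx],
                                scale = ds$standardization$scale[idx])
  }
  out
}

#' Standardize features using training statistics
#'
#' Centers and scales every feature column of `apply_to` by the mean and
#' sample (n-1) standard deviation computed on `train`. Zero-variance
#' columns are mapped to all-zeros rather than dividing by zero. The
#' training (mean, scale) pairs are recorded on the result so the same
#' transform can be reapplied. Standardization makes Euclidean distances
#' comparable across features with different units/scales; all neighbor
#' searches in this package expect standardized features.
#'
#' @param train `conf_dataset` supplying the statistics (at least 2 rows).
#' @param apply_to `conf_dataset` to transform; defaults to `train`. Must
#'   have the same number of feature columns.
#' @return `apply_to` with transformed features and a `standardization`
#'   record (`center`, `scale`; zero-variance columns keep scale 0).
#' @export
standardize <- function(train, apply_to = train) {
  stopifnot(inherits(train, "conf_dataset"), inherits(apply_to, "conf_dataset"))
  if (nrow(train$features) < 2) .stop_arg("standardize needs >= 2 training rows")
  if (ncol(train$features) != ncol(apply_to$features))
    .stop_arg("column-count mismatch: train has ", ncol(train$features),
              " features, apply_to has ", ncol(apply_to$features))
  center <- colMeans(train$features)
  scale <- apply(train$features, 2, stats::sd)  # sample sd, n-1
  Z <- sweep(apply_to$features, 2, center, "-")
  ok <- scale > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, scale[ok], "/")
  Z[, !ok] <- 0
  out <- apply_to
  out$features <- Z
  out$standardization <- list(center = center, scale = scale)
  out
}

# Apply a previously recorded standardization to a bare feature matrix.
.apply_standardization <- function(X, std) {
  Z <- sweep(X, 2, std$center, "-")
  ok <- std$scale > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, std$scale[ok], "/")
  Z[, !ok] <- 0
  Z
}

#' Find the k nearest training neighbors of a query point
#'
#' Plain Euclidean nearest-neighbor search over the rows of a dataset,
#' with deterministic tie-breaking: equidistant rows are returned in
#' ascending row-index order. Features are used as given; callers are
#' expected to pass standardized features (see [standardize()]) so that
#' no single descriptor dominates the metric.
#'
#' @param query numeric vector of length d (one feature row).
#' @param train `conf_dataset` to search.
#' @param k number of neighbors; must not exceed the available rows
#'   (after exclusion). Never silently clamped.
#' @param exclude_index optional row index to exclude (self-exclusion
#'   when the query is itself a training row).
#' @return An object of class `neighbor_set`: list with `indices`
#'   (training-row ids) and `distances` (nondecreasing).
#' @export
nearest_neighbors <- function(query, train, k, exclude_index = NULL) {
  stopifnot(inherits(train, "conf_dataset"))
  query <- as.numeric(query)
  if (length(query) != ncol(train$features))
    .stop_arg("query has ", length(query), " values; expected ", ncol(train$features))
  if (!all(is.finite(query))) .stop_arg("query contains non-finite values")
  n <- nrow(train$features)
  avail <- n - length(exclude_index)
  if (!.is_count(k) || k < 1) .stop_arg("k must be a positive integer")
  if (k > avail)
    .stop_arg("k = ", k, " exceeds the ", avail, " available training rows")
  d <- sqrt(.cpp_query_dist2(train$features, query))
  if (!is.null(exclude_index)) d[exclude_index] <- Inf
  ord <- drop(.cpp_topk_indices(matrix(d, nrow = 1), as.integer(k)))
  structure(list(indices = ord, distances = d[ord]), class = "neighbor_set")
}

#' Out-of-fold (or in-sample) training errors
#'
#' Computes, for every training instance, a prediction and its signed
#' error `y - yhat`. In `"cv"` mode each instance is predicted by a model
#' fitted on the folds that do not contain it (a seeded uniform
#' permutation split), giving the less optimistic error estimate that the
#' neighborhood error-transfer estimator uses by default. In
#' `"resubstitution"` mode one model is fitted on all of `train` and its
#' in-sample predictions are used.
#'
#' @param train `conf_dataset`.
#' @param model `predictor_spec`.
#' @param mode `"cv"` (default) or `"resubstitution"`.
#' @param folds number of folds in cv mode (>= 2, <= n).
#' @param seed integer seed for the fold assignment.
#' @return data.frame with one row per training instance: `index`,
#'   `prediction`, `signed_error`, `squared_error`.
#' @export
training_errors <- function(train, model, mode = c("cv", "resubstitution"),
                            folds = 5, seed = 1) {
  stopifnot(inherits(train, "conf_dataset"), inherits(model, "predictor_spec"))
  mode <- match.arg(mode)
  n <- nrow(train$features)
  pred <- numeric(n)
  if (mode == "resubstitution") {
    fitted <- fit_predictor(model, train)
    pred <- predict(fitted, train$features)
  } else {
    if (!.is_count(folds) || folds < 2) .stop_arg("cv mode needs folds >= 2")
    if (n < folds) .stop_arg("cv mode needs n >= folds")
    assign_fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
    for (f in seq_len(folds)) {
      hold <- assign_fold == f
      fitted <- tryCatch(
        fit_predictor(model, .subset_rows(train, !hold)),
        error = function(e) .stop_arg("model fit failed on fold ", f, ": ", conditionMessage(e))
      )
      pred[hold] <- predict(fitted, train$features[hold, , drop = FALSE])
    }
  }
  signed <- train$response - pred
  data.frame(index = seq_len(n), prediction = pred,
             signed_error = signed, squared_error = signed^2)
}

#' Read a dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header row into a [conf_dataset()]. The
#' response column is named (default `"response"`); every other numeric
#' column becomes a feature.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.tsv`/`.tab` means tab, otherwise comma) unless `sep` is given.
#' @param response name of the response column.
#' @param sep optional field separator override.
#' @return A `conf_dataset`.
#' @export
read_dataset <- function(path, response = "response", sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!response %in% names(df))
    .stop_arg("response column '", response, "' not found in ", path)
  y <- as.numeric(df[[response]])
  X <- as.matrix(df[setdiff(names(df), response)])
  conf_dataset(X, y)
}

#' Write a dataset to a delimited text file
#'
#' @param ds `conf_dataset`.
#' @param path output path; extension picks the delimiter as in
#'   [read_dataset()].
#' @param response name to use for the response column.
#' @param sep optional field separator override.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, response = "response", sep = NULL) {
  stopifnot(inherits(ds, "conf_dataset"))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(ds$features)
  df[[response]] <- ds$response
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
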