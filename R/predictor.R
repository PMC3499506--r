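#' Specify a regression model
#'
#' A lightweight model contract: a family plus hyperparameters, fitted
#' with [fit_predictor()] and used through `predict()`. Two families are
#' bundled: ordinary least squares (`"ols_linear"`) and support vector
#' regression with a Gaussian radial basis kernel (`"svr_rbf"`, via
#' \pkg{e1071}). Every confidence estimator in this package that needs a
#' model takes one of these specs, so any future family only has to
#' honor fit/predict.
#'
#' @param family `"ols_linear"` or `"svr_rbf"`.
#' @param ... hyperparameters for svr_rbf: `cost` (default 1), `epsilon`
#'   (default 0.1), `gamma` (kernel width, default `1/d`).
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(family = c("ols_linear", "svr_rbf"), ...) {
  family <- match.arg(family)
  hp <- list(...)
  known <- c("cost", "epsilon", "gamma")
  if (length(hp) && (is.null(names(hp)) || !all(names(hp) %in% known)))
    .stop_arg("unknown hyperparameters: ",
              paste(setdiff(names(hp), known), collapse = ", "))
  structure(list(family = family, hyperparameters = hp), class = "predictor_spec")
}

#' Fit a regression model to a dataset
#'
#' @param spec `predictor_spec`.
#' @param data a `conf_dataset`, or a numeric feature matrix (then `y`
#'   must be supplied).
#' @param y response vector when `data` is a bare matrix.
#' @return An object of class `fitted_predictor` supporting `predict()`.
#' @export
fit_predictor <- function(spec, data, y = NULL) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (inherits(data, "conf_dataset")) {
    X <- data$features
    y <- data$response
  } else {
    X <- as.matrix(data)
    if (is.null(y)) .stop_arg("y required when data is a matrix")
  }
  state <- switch(spec$family,
    ols_linear = .fit_ols(X, y),
    svr_rbf = .fit_svr(X, y, spec$hyperparameters)
  )
  structure(list(spec = spec, state = state, d = ncol(X)),
            class = "fitted_predictor")
}

#' @export
predict.fitted_predictor <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "conf_dataset")) newdata$features else as.matrix(newdata)
  if (ncol(X) != object$d)
    .stop_arg("newdata has ", ncol(X), " features; model was fitted on ", object$d)
  switch(object$spec$family,
    ols_linear = drop(cbind(1, X) %*% object$state$coef),
    svr_rbf = as.numeric(stats::predict(object$state$fit, X))
  )
}

# OLS via QR with pivoting; aliased (rank-deficient) coefficients are set
# to zero so prediction is always defined.
.fit_ols <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(coef = co)
}

# One QR factorization, many response vectors: used by the local
# sensitivity estimator, which refits the same design under several
# perturbed responses.
.fit_ols_multi <- function(X, Ymat) {
  fit <- stats::lm.fit(cbind(1, X), Ymat)
  co <- as.matrix(fit$coefficients)
  co[is.na(co)] <- 0
  co
}

.fit_svr <- function(X, y, hp) {
  cost <- if (is.null(hp$cost)) 1 else hp$cost
  epsilon <- if (is.null(hp$epsilon)) 0.1 else hp$epsilon
  gamma <- if (is.null(hp$gamma)) 1 / ncol(X) else hp$gamma
  fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                    cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE)
  list(fit = fit)
}
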