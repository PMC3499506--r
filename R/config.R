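#' Default run configuration
#'
#' The configuration consumed by the command-line interface and by
#' [config_model()] / [config_estimators()]: model family and
#' hyperparameters, estimator list, interval level, calibration window,
#' protocol settings and the synthetic grid axes.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    response_column = "response",
    alpha = 0.2,
    window_halfwidth = 0.1,
    min_pool = 30,
    top_fraction = 0.5,
    seed = 1,
    model = list(family = "ols_linear", cost = 1, epsilon = 0.1, gamma = NULL),
    estimators = list(list(name = "confine"), list(name = "confive")),
    protocol = list(repetitions = 5, outer_folds = 5, select_features = TRUE),
    grid = list(n = c(50, 100, 200, 500), m_total = c(5, 10, 25, 50),
                sigma = c(0.5, 1, 2), replicates = 3)
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML key/value file and merges it over [default_config()];
#' only keys present in the file are overridden.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (key in names(user)) {
    # nested named blocks merge key-wise; the estimator list replaces wholesale
    if (key %in% c("model", "protocol", "grid") && is.list(user[[key]]))
      cfg[[key]] <- utils::modifyList(cfg[[key]], user[[key]])
    else cfg[[key]] <- user[[key]]
  }
  cfg
}

#' Build the model spec from a configuration
#' @param config list as from [read_config()].
#' @return `predictor_spec`.
#' @export
config_model <- function(config) {
  m <- config$model
  if (identical(m$family, "svr_rbf")) {
    hp <- m[names(m) %in% c("cost", "epsilon", "gamma")]
    hp <- hp[!vapply(hp, is.null, TRUE)]
    do.call(predictor_spec, c(list(family = "svr_rbf"), hp))
  } else predictor_spec("ols_linear")
}

#' Build the estimator list from a configuration
#' @param config list as from [read_config()].
#' @return Named list of `estimator_spec`s.
#' @export
config_estimators <- function(config) {
  specs <- lapply(config$estimators, function(e) {
    if (identical(e$k, "auto")) e$k <- NULL
    do.call(estimator_spec, e)
  })
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Write an evaluation report as JSON
#'
#' Serializes benchmark rows (plus a configuration echo and the seed)
#' into a JSON document.
#'
#' @param results `benchmark_result` or `grid_study` object.
#' @param path output file.
#' @param config optional configuration list to echo.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(results, path, config = NULL, seed = NULL) {
  payload <- list(
    package_version = as.character(utils::packageVersion("regconf")),
    seed = seed, config = config)
  if (inherits(results, "grid_study")) {
    payload$summary <- results$summary
    payload$rows <- results$results
  } else payload$rows <- as.data.frame(results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Write per-prediction output as TSV
#'
#' @param predictions data.frame from [predict.conf_regressor()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  df <- cbind(id = seq_len(nrow(predictions)), predictions)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
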