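#' Confidence-error correlation (CEC)
#'
#' Pearson correlation between absolute prediction errors and the widths
#' of the corresponding confidence intervals, normalized by the
#' correlation a perfect confidence estimator would achieve. The perfect
#' estimator is simulated by sorting both vectors, which maximizes the
#' correlation; CEC = 1 therefore means the interval widths order the
#' errors as well as is possible for their marginal distributions.
#'
#' If either vector is constant the correlation is undefined; the
#' convention here is to return 0 with attribute `degenerate = TRUE`, so
#' that batch evaluations never abort on a pathological fold.
#'
#' @param abs_errors nonnegative absolute prediction errors.
#' @param widths matching nonnegative interval widths (length >= 3).
#' @return CEC in `[-1, 1]` (attribute `degenerate` when the guard fired).
#' @export
cec <- function(abs_errors, widths) {
  if (length(abs_errors) != length(widths)) .stop_arg("length mismatch in cec()")
  if (length(abs_errors) < 3) .stop_arg("cec needs at least 3 pairs")
  if (stats::sd(abs_errors) == 0 || stats::sd(widths) == 0)
    return(structure(0, degenerate = TRUE))
  r <- stats::cor(abs_errors, widths)
  r_perfect <- stats::cor(sort.int(abs_errors, method = "radix"),
                          sort.int(widths, method = "radix"))
  if (!is.finite(r_perfect) || r_perfect == 0) return(structure(0, degenerate = TRUE))
  r / r_perfect
}

#' Confidence-associated prediction improvement (CAPI)
#'
#' Fractional reduction of the mean squared error when only the top
#' fraction of predictions — those with the smallest confidence
#' intervals — is kept: `1 - MSE(selected) / MSE(all)`. Positive values
#' mean the estimator concentrates the good predictions; a perfect-width
#' ordering attains the maximum over all orderings.
#'
#' @param squared_errors nonnegative squared prediction errors.
#' @param widths matching nonnegative interval widths.
#' @param top_fraction fraction of predictions kept, in (0, 1]
#'   (default 0.5); ties in width are broken by index.
#' @return CAPI (<= 1); defined as 0 when `MSE(all)` is 0.
#' @export
capi <- function(squared_errors, widths, top_fraction = 0.5) {
  if (length(squared_errors) != length(widths)) .stop_arg("length mismatch in capi()")
  if (!(top_fraction > 0 && top_fraction <= 1)) .stop_arg("top_fraction must be in (0, 1]")
  n <- length(squared_errors)
  m <- ceiling(top_fraction * n)
  sel <- order(widths, seq_len(n), method = "radix")[seq_len(m)]
  mse_all <- mean(squared_errors)
  if (mse_all == 0) return(0)
  1 - mean(squared_errors[sel]) / mse_all
}

#' Empirical coverage of confidence intervals
#'
#' Fraction of true responses falling inside their (closed) predicted
#' interval.
#'
#' @param truths true response values.
#' @param intervals data.frame with columns `lower` and `upper` (e.g.
#'   rows of `confident_prediction`), one per truth.
#' @return Coverage fraction in `[0, 1]`.
#' @export
coverage <- function(truths, intervals) {
  if (length(truths) == 0) .stop_arg("coverage of empty input")
  if (nrow(intervals) != length(truths)) .stop_arg("length mismatch in coverage()")
  mean(intervals$lower <= truths & truths <= intervals$upper)
}

#' Predictability of estimation performance
#'
#' Pearson correlation between CEC values measured on training data and
#' the CEC values later obtained on the corresponding test data (one pair
#' per dataset or fold): high correlation means the training-side CEC is
#' an educated guess of how well the estimator will do on new data.
#'
#' @param train_cecs,test_cecs paired numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]`; 0 with attribute `degenerate` for
#'   constant input.
#' @export
cec_predictability <- function(train_cecs, test_cecs) {
  if (length(train_cecs) != length(test_cecs)) .stop_arg("length mismatch in cec_predictability()")
  if (length(train_cecs) < 3) .stop_arg("cec_predictability needs at least 3 pairs")
  if (stats::sd(train_cecs) == 0 || stats::sd(test_cecs) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(train_cecs, test_cecs)
}
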