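# Shared fixtures: all data is generated in code at test time.

ols <- function() predictor_spec("ols_linear")

# A standardized Friedman training set plus matching test set.
friedman_split <- function(n_train, n_test, m_total = 10, sigma = 1, seed = 1) {
  d <- generate_friedman(n_train + n_test, m_total, sigma, seed = seed)
  idx <- seq_len(n_train)
  list(train = regconf:::.subset_rows(d, idx),
       test = regconf:::.subset_rows(d, -idx))
}

# Exactly linear 1-feature data: any least-squares fit interpolates it.
linear_dataset <- function(n = 20, slope = 2) {
  x <- seq_len(n) / n
  conf_dataset(matrix(x, ncol = 1), slope * x)
}

# A calibration table with prescribed ncs spacing: distinct raw scores
# produce the uniform ncs grid 0, 1/n, ..., (n-1)/n.
grid_table <- function(errors, alpha = 0.2, window = 0.1, min_pool = 30) {
  calibration_table(seq_along(errors), errors, alpha = alpha,
                    window_halfwidth = window, min_pool = min_pool)
}
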