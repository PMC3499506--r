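#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`
#' and restores the previous RNG state afterwards, so that no package
#' function ever leaks or depends on global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific sub-seed from a master seed; kept within the
# 32-bit signed integer range expected by set.seed().
.subseed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483629) + 1L
}

# Squared Euclidean distance matrix between the rows of A (queries) and B
# (training rows). Negative values from cancellation are clamped to zero.
.dist2_mat <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

.dist_mat <- function(A, B) sqrt(.dist2_mat(A, B))

# Row-wise order of a distance matrix; radix sort is stable, so ties are
# broken by ascending training-row index.
.order_rows <- function(D) {
  t(apply(D, 1, order, method = "radix"))
}

# Sample variance (n-1 denominator) of each row of a matrix.
.row_vars <- function(M) {
  mu <- rowMeans(M)
  rowSums((M - mu)^2) / (ncol(M) - 1)
}

.stop_arg <- function(...) stop(..., call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
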