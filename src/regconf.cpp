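#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Indices (1-based) of the k smallest values per row of a distance
// matrix; ties broken by ascending column index (lexicographic compare
// on (value, index) pairs, matching a stable radix sort).
// [[Rcpp::export(name = ".cpp_topk_indices")]]
IntegerMatrix cpp_topk_indices(NumericMatrix D2, int k) {
  const int nq = D2.nrow(), n = D2.ncol();
  if (k > n) stop("k exceeds the number of columns");
  IntegerMatrix out(nq, k);
  std::vector<std::pair<double, int> > row(n);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < n; ++j) row[j] = std::make_pair(D2(i, j), j);
    if (k < n) std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    std::sort(row.begin(), row.begin() + k);
    for (int j = 0; j < k; ++j) out(i, j) = row[j].second + 1;
  }
  return out;
}

// Squared Euclidean distances from one query to every row of X.
// [[Rcpp::export(name = ".cpp_query_dist2")]]
NumericVector cpp_query_dist2(NumericMatrix X, NumericVector q) {
  const int n = X.nrow(), d = X.ncol();
  if (q.size() != d) stop("query length does not match feature count");
  NumericVector out(n);
  for (int j = 0; j < d; ++j) {
    const double qj = q[j];
    const double* col = &X(0, j);
    for (int i = 0; i < n; ++i) {
      const double diff = col[i] - qj;
      out[i] += diff * diff;
    }
  }
  return out;
}

// Fused single-query neighbor search: squared distances to all rows of
// X, then the indices (1-based) of the k nearest, ties by row index.
// [[Rcpp::export(name = ".cpp_query_topk")]]
IntegerVector cpp_query_topk(NumericMatrix X, NumericVector q, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (q.size() != d) stop("query length does not match feature count");
  if (k > n) stop("k exceeds the number of rows");
  std::vector<double> d2(n, 0.0);
  for (int j = 0; j < d; ++j) {
    const double qj = q[j];
    const double* col = &X(0, j);
    for (int i = 0; i < n; ++i) {
      const double diff = col[i] - qj;
      d2[i] += diff * diff;
    }
  }
  std::vector<std::pair<double, int> > row(n);
  for (int i = 0; i < n; ++i) row[i] = std::make_pair(d2[i], i);
  std::partial_sort(row.begin(), row.begin() + k, row.end());
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = row[i].second + 1;
  return out;
}

// Row-wise cumulative sums.
// [[Rcpp::export(name = ".cpp_row_cumsum")]]
NumericMatrix cpp_row_cumsum(NumericMatrix M) {
  const int nr = M.nrow(), nc = M.ncol();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nc; ++j) { acc += M(i, j); out(i, j) = acc; }
  }
  return out;
}

static double nearest_rank(std::vector<double>& buf, int m, double p) {
  int r = (int)std::ceil(p * m);
  if (r < 1) r = 1;
  std::nth_element(buf.begin(), buf.begin() + (r - 1), buf.begin() + m);
  return buf[r - 1];
}

// Error-pool interval offsets for a batch of normalized confidence
// scores. s_ncs is sorted ascending with s_err aligned; for each query
// ncs the pool is the window |ncs_i - q| <= w, expanded (nearer side
// first, left on ties) to min_pool entries when deficient, and the
// nearest-rank p_lo / p_hi quantiles of the pooled signed errors are
// returned as columns (lower, upper).
// [[Rcpp::export(name = ".cpp_interval_offsets")]]
NumericMatrix cpp_interval_offsets(NumericVector s_ncs, NumericVector s_err,
                                   NumericVector ncs_q, double w, int min_pool,
                                   double p_lo, double p_hi) {
  const int n = s_ncs.size(), nq = ncs_q.size();
  const double eps = 1e-12;
  NumericMatrix out(nq, 2);
  std::vector<double> buf(n);
  const double* s = REAL(s_ncs);
  int prev_lo = -2, prev_hi = -2;
  double prev_qlo = 0.0, prev_qhi = 0.0;
  for (int i = 0; i < nq; ++i) {
    const double q = ncs_q[i];
    int lo = (int)(std::lower_bound(s, s + n, q - w - eps) - s);
    int hi = (int)(std::upper_bound(s, s + n, q + w + eps) - s) - 1;
    if (hi < lo) { // empty window: seed from the nearest flanking entry
      int a = std::max(0, lo - 1), b = std::min(n - 1, lo);
      int j = (std::abs(s[a] - q) <= std::abs(s[b] - q)) ? a : b;
      lo = hi = j;
    }
    while (hi - lo + 1 < min_pool) {
      double left_d = (lo > 0) ? std::abs(s[lo - 1] - q) : R_PosInf;
      double right_d = (hi < n - 1) ? std::abs(s[hi + 1] - q) : R_PosInf;
      if (left_d <= right_d) --lo; else ++hi;
    }
    if (lo == prev_lo && hi == prev_hi) {
      out(i, 0) = prev_qlo; out(i, 1) = prev_qhi;
      continue;
    }
    const int m = hi - lo + 1;
    for (int j = 0; j < m; ++j) buf[j] = s_err[lo + j];
    double qhi = nearest_rank(buf, m, p_hi);
    for (int j = 0; j < m; ++j) buf[j] = s_err[lo + j];
    double qlo = nearest_rank(buf, m, p_lo);
    out(i, 0) = qlo; out(i, 1) = qhi;
    prev_lo = lo; prev_hi = hi; prev_qlo = qlo; prev_qhi = qhi;
  }
  return out;
}
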