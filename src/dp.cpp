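#include <Rcpp.h>
using namespace Rcpp;

// Longest-common-subsequence DP fill.
// S[i,j] = 0 on the borders; S[i-1,j-1]+1 on a match; max(up, left) otherwise.
// [[Rcpp::export]]
IntegerMatrix cpp_lcs_fill(IntegerVector a, IntegerVector b) {
  int m = a.size(), n = b.size();
  IntegerMatrix S(m + 1, n + 1);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (a[i - 1] == b[j - 1])
        S(i, j) = S(i - 1, j - 1) + 1;
      else
        S(i, j) = std::max(S(i - 1, j), S(i, j - 1));
    }
  }
  return S;
}

// LCS length only, with rolling rows: used when screening whole databases
// where the full matrix (needed only for traceback) would be wasted work.
// [[Rcpp::export]]
int cpp_lcs_length(IntegerVector a, IntegerVector b) {
  int m = a.size(), n = b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      if (a[i - 1] == b[j - 1])
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Residue-level scoring matrix fill: first row/column 0, then
// max of (up + g, left + g, diag + match term).  `term` holds the
// 1/(1 + d_ij^2/d0^2) match rewards, one row per template residue.
// [[Rcpp::export]]
NumericMatrix cpp_fill_m(NumericMatrix term, double g) {
  int m = term.nrow(), n = term.ncol();
  NumericMatrix M(m + 1, n + 1);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double up = M(i - 1, j) + g;
      double left = M(i, j - 1) + g;
      double diag = M(i - 1, j - 1) + term(i - 1, j - 1);
      double best = diag >= up ? diag : up;
      if (left > best) best = left;
      M(i, j) = best;
    }
  }
  return M;
}

// Global traceback of the residue-level matrix; tie-break order is
// diagonal (aligned pair) > up (template gap advance) > left.
// Returns 1-based (template, window) index pairs in ascending order.
// [[Rcpp::export]]
IntegerMatrix cpp_traceback_m(NumericMatrix M, NumericMatrix term, double g) {
  int i = M.nrow() - 1, j = M.ncol() - 1;
  std::vector<int> pi, pj;
  while (i > 0 && j > 0) {
    double v = M(i, j);
    if (v == M(i - 1, j - 1) + term(i - 1, j - 1)) {
      pi.push_back(i); pj.push_back(j);
      --i; --j;
    } else if (v == M(i - 1, j) + g) {
      --i;
    } else {
      --j;
    }
  }
  int k = pi.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(k - 1 - r, 0) = pi[r];
    out(k - 1 - r, 1) = pj[r];
  }
  return out;
}
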