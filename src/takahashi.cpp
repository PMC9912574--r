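#include <Rcpp.h>
using namespace Rcpp;

// Takahashi selected inversion.
//
// Given the simplicial Cholesky factor L (lower triangular, CSC, rows sorted
// within each column, diagonal entry first) of a permuted SPD matrix
// C[p,p] = L L', computes the entries of inv(C[p,p]) on the nonzero pattern of
// L. The recurrences, with C = L1 D L1' (L1 unit lower, d_j = L_jj^2):
//   Z_ij = -sum_{k>j} L1_kj Z_(i,k)              (i > j)
//   Z_jj = 1/d_j - sum_{k>j} L1_kj Z_(k,j)
// where Z_(a,b) = Z[max(a,b), min(a,b)] by symmetry. Both indices of every
// required entry lie in the factor's pattern (columns are closed along the
// elimination tree), so the recursion is exact, not approximate.
// [[Rcpp::export(name = ".takahashi_selinv")]]
NumericVector takahashi_selinv(IntegerVector Lp, IntegerVector Li, NumericVector Lx) {
  const int n = Lp.size() - 1;
  NumericVector Zx(Lx.size());
  // unit-lower factor and D from the LL' factor
  std::vector<double> ux(Lx.size()), dvec(n);
  for (int j = 0; j < n; ++j) {
    const double ljj = Lx[Lp[j]];
    dvec[j] = ljj * ljj;
    for (int t = Lp[j]; t < Lp[j + 1]; ++t) ux[t] = Lx[t] / ljj;
  }
  // lookup of Z[r, c], r >= c, by binary search on the rows of column c
  auto zlook = [&](int r, int c) -> double {
    int lo = Lp[c], hi = Lp[c + 1] - 1;
    while (lo <= hi) {
      const int mid = (lo + hi) / 2;
      if (Li[mid] == r) return Zx[mid];
      if (Li[mid] < r) lo = mid + 1; else hi = mid - 1;
    }
    return 0.0; // structurally absent => zero in the selected inverse
  };
  for (int j = n - 1; j >= 0; --j) {
    const int start = Lp[j], end = Lp[j + 1];
    // off-diagonals, bottom-up (order immaterial: they only read later columns)
    for (int t = end - 1; t > start; --t) {
      const int i = Li[t];
      double s = 0.0;
      for (int u = start + 1; u < end; ++u) {
        const int k = Li[u];
        s += ux[u] * (i >= k ? zlook(i, k) : zlook(k, i));
      }
      Zx[t] = -s;
    }
    double s = 0.0;
    for (int u = start + 1; u < end; ++u) s += ux[u] * Zx[u];
    Zx[start] = 1.0 / dvec[j] - s;
  }
  return Zx;
}

// Vectorised lookup of selected-inverse entries (0-based permuted indices).
// [[Rcpp::export(name = ".selinv_lookup")]]
NumericVector selinv_lookup(IntegerVector Lp, IntegerVector Li, NumericVector Zx,
                            IntegerVector rows, IntegerVector cols) {
  const int m = rows.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    int r = rows[t], c = cols[t];
    if (r < c) std::swap(r, c);
    int lo = Lp[c], hi = Lp[c + 1] - 1;
    double v = 0.0;
    while (lo <= hi) {
      const int mid = (lo + hi) / 2;
      if (Li[mid] == r) { v = Zx[mid]; break; }
      if (Li[mid] < r) lo = mid + 1; else hi = mid - 1;
    }
    out[t] = v;
  }
  return out;
}
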