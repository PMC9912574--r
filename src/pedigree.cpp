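#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo style inbreeding: F_i = a_ii - 1 with a_ii = sum_j T_ij^2 D_j,
// T the gene-flow matrix and D_j the Mendelian sampling variance coefficient.
// sire/dam are 1-based indices into the topologically ordered pedigree, 0 = unknown.
// [[Rcpp::export(name = ".ml_inbreeding")]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s == 0 && d == 0) D[i] = 1.0;
    else if (s == 0)      D[i] = 0.75 - 0.25 * F[d - 1];
    else if (d == 0)      D[i] = 0.75 - 0.25 * F[s - 1];
    else                  D[i] = 0.5 - 0.25 * (F[s - 1] + F[d - 1]);
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      const double c = L[j];
      if (c == 0.0) continue;
      aii += c * c * D[j];
      if (sire[j] > 0) L[sire[j] - 1] += 0.5 * c;
      if (dam[j] > 0)  L[dam[j] - 1]  += 0.5 * c;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Dense numerator relationship matrix by the tabular method.
// [[Rcpp::export(name = ".tabular_A")]]
NumericMatrix tabular_A(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s > 0) a += 0.5 * A(j, s - 1);
      if (d > 0) a += 0.5 * A(j, d - 1);
      A(j, i) = A(i, j) = a;
    }
    double f = 0.0;
    if (s > 0 && d > 0) f = 0.5 * A(s - 1, d - 1);
    A(i, i) = 1.0 + f;
  }
  return A;
}
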