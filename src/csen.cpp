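#include <Rcpp.h>
using namespace Rcpp;

// Cross-sample-entropy template-match counts (Richman & Moorman convention).
// Templates of length m are taken at i = 0..N-m-1 in both series so the same
// index range serves lengths m and m+1; all (N-m)^2 cross pairs are compared
// with the Chebyshev (max-abs) distance. Returns c(A, B): matches at length
// m+1 and at length m.
// [[Rcpp::export]]
NumericVector csen_counts(NumericVector x, NumericVector y, int m, double r) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n <= m + 1) stop("series length must exceed m + 1");
  const int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < nt; ++j) {
      double dmax = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - y[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double d = std::fabs(x[i + m] - y[j + m]);
      if (d > dmax) dmax = d;
      if (dmax <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
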