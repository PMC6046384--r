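#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy under the Chebyshev metric.
// Both the length-m count (B) and the length-(m+1) count (A) are taken
// over the same N - m template start points, self-matches excluded,
// following the canonical multiscale-entropy convention.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double tol) {
  const int n = x.size();
  const int nt = n - m; // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > tol) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= tol) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}
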