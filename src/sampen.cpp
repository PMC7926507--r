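#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Templates are the n - m overlapping subsequences s[i..i+m-1] with
// i = 0..n-m-1 (so the (m+1)-length extension s[i..i+m] exists for
// every template). B counts unordered pairs of distinct templates whose
// Chebyshev (max-norm) distance is <= r; A counts the pairs that still
// match when extended by one sample. Self-matches are excluded.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector s, int m, double r) {
  const int n = s.size();
  const int nt = n - m;  // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(s[i + k] - s[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(s[i + m] - s[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
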