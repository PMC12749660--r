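#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Natural visibility graph edge list (1-based, a < b).
// Points a,b are linked iff every intermediate sample lies strictly below
// the chord from a to b; equivalently the chord slope strictly exceeds the
// running maximum slope from a to any intermediate point.
// [[Rcpp::export]]
IntegerMatrix vg_edges_cpp(NumericVector x) {
  int n = x.size();
  std::vector<int> from;
  std::vector<int> to;
  from.reserve(4 * n);
  to.reserve(4 * n);
  for (int a = 0; a < n - 1; ++a) {
    double maxslope = -std::numeric_limits<double>::infinity();
    for (int b = a + 1; b < n; ++b) {
      double slope = (x[b] - x[a]) / static_cast<double>(b - a);
      if (b == a + 1 || slope > maxslope) {
        from.push_back(a + 1);
        to.push_back(b + 1);
      }
      if (slope > maxslope) maxslope = slope;
    }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t k = 0; k < from.size(); ++k) {
    out(k, 0) = from[k];
    out(k, 1) = to[k];
  }
  return out;
}

// Sample-entropy template match counts (Chebyshev distance, self-matches
// excluded): returns c(A, B) with B the m-template matches and A the
// (m+1)-template matches over the same template index range.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // templates that can be extended by one sample
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm <= r && d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
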