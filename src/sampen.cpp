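#include <Rcpp.h>
using namespace Rcpp;

// Exact O(N^2) sample-entropy template counts.
//
// Counts unordered template pairs (i < j), i, j in 1..N-m, whose Chebyshev
// distance is within tolerance r at embedding length m (b_count) and at
// length m+1 over the same index range (a_count). Restricting both counts
// to i <= N-m means every m-template considered has an (m+1)-point
// extension, so a_count / b_count is a valid conditional probability; the
// normalisation constants of the per-template averages cancel in the ratio
// and are never materialised. `strict_lt` switches the match criterion from
// d <= r (Richman–Moorman convention, default) to d < r.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r, bool strict_lt) {
  const int N = x.size();
  const int nt = N - m;  // number of (m+1)-capable templates
  if (nt < 2) stop("series too short for embedding length m");
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::abs(x[i + k] - x[j + k]);
        if (d > dm) dm = d;
      }
      bool match_m = strict_lt ? (dm < r) : (dm <= r);
      if (match_m) {
        B += 1.0;
        double d1 = std::abs(x[i + m] - x[j + m]);
        if (d1 < dm) d1 = dm;
        bool match_m1 = strict_lt ? (d1 < r) : (d1 <= r);
        if (match_m1) A += 1.0;
      }
    }
  }
  return List::create(_["a_count"] = A, _["b_count"] = B);
}
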