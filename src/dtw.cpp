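#include <Rcpp.h>
using namespace Rcpp;

// Accumulated optimal warping cost between p and r with squared local
// cost and moves {down, right, diagonal}, boundary-anchored at both ends.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector p, NumericVector r) {
  const int n = p.size(), m = r.size();
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double d = p[0] - r[j];
    prev[j] = d * d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    double d0 = p[i] - r[0];
    cur[0] = d0 * d0 + prev[0];
    for (int j = 1; j < m; ++j) {
      double d = p[i] - r[j];
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
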