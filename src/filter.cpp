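#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state zi
// (length max(len(a), len(b)) - 1). a[0] must be 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  const int n = x.size();
  const int nfilt = std::max(a.size(), b.size());
  std::vector<double> bb(b.begin(), b.end()); bb.resize(nfilt, 0.0);
  std::vector<double> aa(a.begin(), a.end()); aa.resize(nfilt, 0.0);
  std::vector<double> z(zi.begin(), zi.end()); z.resize(nfilt - 1, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nfilt > 1 ? z[0] : 0.0);
    for (int j = 1; j < nfilt - 1; ++j)
      z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
    if (nfilt > 1)
      z[nfilt - 2] = bb[nfilt - 1] * xi - aa[nfilt - 1] * yi;
    y[i] = yi;
  }
  return y;
}
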