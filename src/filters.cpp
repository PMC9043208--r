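#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// b, a must be same length, a[0] == 1. zi has length(b) - 1 states.
// [[Rcpp::export(name = ".lfilter_cpp")]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int m = b.size();
  if (a.size() != m) stop("b and a must have equal length");
  if (zi.size() != m - 1) stop("zi must have length(b) - 1 entries");
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (m > 1 ? z[0] : 0.0);
    for (int k = 0; k < m - 2; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (m > 1) z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    y[i] = yi;
  }
  return y;
}
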