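// Direct-form II transposed IIR filter with explicit initial state,
// matching the classic lfilter contract. Compiled because EMG streams run
// at 1.5 kHz and are filtered forward and backward per channel.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".lfilter_cpp")]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(na, nb);
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  double a0 = aa[0];
  for (int i = 0; i < nfilt; ++i) { bb[i] /= a0; aa[i] /= a0; }
  int n = x.size();
  std::vector<double> z(nfilt - 1, 0.0);
  for (int i = 0; i < (int)z.size() && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (nfilt > 1 ? z[0] : 0.0);
    for (int i = 0; i < nfilt - 2; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    if (nfilt > 1)
      z[nfilt - 2] = bb[nfilt - 1] * xt - aa[nfilt - 1] * yt;
    y[t] = yt;
  }
  return y;
}
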