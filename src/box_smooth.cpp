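#include <Rcpp.h>
using namespace Rcpp;

// Three-pass centred boxcar smoothing of every column of Z, in one call.
// Column j uses half width h[j] (edge windows truncated, unit DC gain);
// the cascade approximates a Gaussian of sd sqrt(h(h+1)/3).
// [[Rcpp::export]]
NumericMatrix box3_smooth(NumericMatrix Z, IntegerVector h) {
  const int n = Z.nrow(), k = Z.ncol();
  NumericMatrix out(n, k);
  std::vector<double> buf(n), cs(n + 1);
  for (int j = 0; j < k; ++j) {
    const int hj = h[j];
    for (int i = 0; i < n; ++i) buf[i] = Z(i, j);
    for (int pass = 0; pass < 3; ++pass) {
      cs[0] = 0.0;
      for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + buf[i];
      for (int i = 0; i < n; ++i) {
        int lo = i - hj; if (lo < 0) lo = 0;
        int hi = i + hj; if (hi > n - 1) hi = n - 1;
        buf[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
      }
    }
    for (int i = 0; i < n; ++i) out(i, j) = buf[i];
  }
  return out;
}
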