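#include <Rcpp.h>
using namespace Rcpp;

// Banded discrete convolution s_i = sum_{k=-K}^{K} wk[k+K] * a[i+k].
// wk holds kernel samples already multiplied by dx. Out-of-domain
// contributions are dropped (free / Dirichlet truncation: no ghost mass).
// [[Rcpp::export]]
NumericVector band_convolve_free(NumericVector a, NumericVector wk, int K) {
  int n = a.size();
  NumericVector s(n);
  for (int k = -K; k <= K; ++k) {
    double w = wk[k + K];
    int lo = std::max(0, -k), hi = std::min(n, n - k);
    for (int i = lo; i < hi; ++i) s[i] += w * a[i + k];
  }
  return s;
}

// Periodic variant: indices wrap modulo n (kernel assumed wrapped onto the
// period by the caller if its support exceeds the domain).
// [[Rcpp::export]]
NumericVector band_convolve_periodic(NumericVector a, NumericVector wk, int K) {
  int n = a.size();
  NumericVector s(n);
  for (int k = -K; k <= K; ++k) {
    double w = wk[k + K];
    for (int i = 0; i < n; ++i) {
      int j = (i + k) % n;
      if (j < 0) j += n;
      s[i] += w * a[j];
    }
  }
  return s;
}
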