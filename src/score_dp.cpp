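#include <Rcpp.h>
using namespace Rcpp;

// Exact distribution of the integer-discretized PWM score of a random
// window drawn i.i.d. from the background. `off` is the 4 x L matrix of
// per-position score offsets relative to the per-position minimum
// (negative entries mark impossible bases, i.e. -Inf log-odds). Returns
// the probability vector over scores min..max; mass of impossible windows
// is simply absent (the vector sums to the probability that every
// position draws a possible base).
// [[Rcpp::export(name = ".score_dp")]]
NumericVector score_dp(IntegerMatrix off, NumericVector bg) {
  const int L = off.ncol();
  std::vector<int> span(L);
  long width = 1;
  for (int j = 0; j < L; ++j) {
    int mx = 0;
    for (int b = 0; b < 4; ++b)
      if (off(b, j) >= 0 && off(b, j) > mx) mx = off(b, j);
    span[j] = mx;
    width += mx;
  }
  std::vector<double> d(width, 0.0), nd(width, 0.0);
  d[0] = 1.0;
  long cur = 1;
  for (int j = 0; j < L; ++j) {
    const long nl = cur + span[j];
    std::fill(nd.begin(), nd.begin() + nl, 0.0);
    for (int b = 0; b < 4; ++b) {
      const int o = off(b, j);
      if (o < 0) continue;
      const double w = bg[b];
      for (long k = 0; k < cur; ++k) nd[k + o] += w * d[k];
    }
    std::swap(d, nd);
    cur = nl;
  }
  return NumericVector(d.begin(), d.begin() + cur);
}
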