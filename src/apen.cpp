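#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy (Pincus): phi(m) - phi(m+1) with Chebyshev distance and
// self-matches included.  O(N^2 m) with symmetric pair counting; called once
// per window x channel, so it lives in compiled code.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return 0.0;
  std::vector<double> v(x.begin(), x.end());
  const double* p = v.data();
  double phi[2];
  std::vector<int> cnt;
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int nv = n - mm + 1;
    cnt.assign(nv, 1);  // self-match
    for (int i = 0; i < nv; ++i) {
      for (int j = i + 1; j < nv; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double dd = std::fabs(p[i + k] - p[j + k]);
          if (dd > d) d = dd;
        }
        if (d <= r) { ++cnt[i]; ++cnt[j]; }
      }
    }
    double acc = 0.0;
    for (int i = 0; i < nv; ++i) acc += std::log((double)cnt[i] / nv);
    phi[s] = acc / nv;
  }
  return phi[0] - phi[1];
}
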