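#include <Rcpp.h>
using namespace Rcpp;

// Recentered paired bootstrap p-value for a mean difference of zero.
// d: paired differences; resamples of the mean of the recentered
// differences are compared in absolute value against the observed mean,
// with +1 continuity correction on numerator and denominator.
// [[Rcpp::export(name = ".boot_paired_p")]]
double boot_paired_p(NumericVector d, int n_boot) {
  int n = d.size();
  double obs = mean(d);
  NumericVector dc = d - obs;
  double thr = std::fabs(obs);
  long count = 0;
  for (int b = 0; b < n_boot; ++b) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j == n) j = n - 1;
      s += dc[j];
    }
    if (std::fabs(s / n) >= thr) ++count;
  }
  return (count + 1.0) / (n_boot + 1.0);
}

// Vectorized null study: m independent tests, each drawing n standard
// normal differences and bootstrapping with n_boot resamples; returns
// the m p-values. Kept in C++ so the type-I calibration study is cheap.
// [[Rcpp::export(name = ".boot_null_study")]]
NumericVector boot_null_study(int m, int n, int n_boot) {
  NumericVector p(m);
  NumericVector d(n);
  for (int t = 0; t < m; ++t) {
    for (int i = 0; i < n; ++i) d[i] = norm_rand();
    p[t] = boot_paired_p(d, n_boot);
  }
  return p;
}
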