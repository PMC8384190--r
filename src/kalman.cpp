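#include <Rcpp.h>
using namespace Rcpp;

// Exact log marginal likelihood of a univariate linear-Gaussian state-space
// model by the Kalman filter:
//   x[i+1] = a[i] * x[i] + b[i] + w[i],  w[i] ~ N(0, q2[i])
//   y[i]   = x[i] + v[i],               v[i] ~ N(0, r2)
// The state is initialised at m0 (variance p0) taken from the first
// observed sample, whose own update is skipped to avoid using it twice.
// Missing observations (NA) contribute nothing and are bridged by the
// transition only.
// [[Rcpp::export]]
double kalman_loglik(NumericVector y, NumericVector a, NumericVector b,
                     NumericVector q2, double r2, double m0, double p0,
                     int init_idx) {
  const int n = y.size();
  if (a.size() != n - 1 || b.size() != n - 1 || q2.size() != n - 1)
    stop("transition vectors must have length n - 1");
  double m = m0, p = p0, ll = 0.0;
  const double LOG2PI = 1.8378770664093453;
  for (int i = 0; i < n; ++i) {
    if (!NumericVector::is_na(y[i]) && i != init_idx) {
      double s = p + r2;
      double e = y[i] - m;
      ll += -0.5 * (LOG2PI + std::log(s) + e * e / s);
      double k = p / s;
      m += k * e;
      p *= (1.0 - k);
    }
    if (i < n - 1) {
      m = a[i] * m + b[i];
      p = a[i] * a[i] * p + q2[i];
    }
    if (!std::isfinite(m) || !std::isfinite(p)) return R_NegInf;
  }
  return ll;
}
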