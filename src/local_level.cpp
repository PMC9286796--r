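#include <Rcpp.h>
using namespace Rcpp;

// Local-level state-space model on the (transformed) observation scale:
//   z_t     = mu_t + eps_t,   eps_t ~ N(0, s2e)   [observation]
//   mu_{t+1} = mu_t + eta_t,  eta_t ~ N(0, s2h)   [random-walk level]
// Missing observations (NA) skip the measurement update; the time index
// still advances, so the level diffuses through gaps.
//
// Gibbs sweep: (a) forward-filter backward-sample draw of the full level
// path given the variances, (b) conjugate inverse-gamma draws of s2e and
// s2h given the path. In fixed-variance mode step (b) is skipped and the
// retained paths are i.i.d. draws from the exact smoothing distribution.
// All randomness comes from R's RNG so set.seed() governs reproducibility.

static inline double rinvgamma(double shape, double rate) {
  // X ~ IG(shape, rate)  <=>  1/X ~ Gamma(shape, rate)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export]]
List ffbs_gibbs_cpp(NumericVector z, int n_iter, int burn_in,
                    double a_eps, double b_eps, double a_eta, double b_eta,
                    double m0, double C0,
                    bool fix_var, double s2e_fixed, double s2h_fixed,
                    double s2e_init, double s2h_init) {
  const int T = z.size();
  if (T < 2) stop("series must have at least 2 time points");
  const int n_keep = n_iter - burn_in;
  if (n_keep <= 0) stop("burn_in must be smaller than iterations");

  LogicalVector obs(T);
  int n_obs = 0;
  for (int t = 0; t < T; ++t) {
    obs[t] = !NumericVector::is_na(z[t]);
    if (obs[t]) ++n_obs;
  }

  NumericMatrix mu_keep(n_keep, T);
  NumericVector s2e_keep(n_keep), s2h_keep(n_keep), zf_keep(n_keep);

  std::vector<double> m(T), C(T), mu(T);
  double s2e = fix_var ? s2e_fixed : s2e_init;
  double s2h = fix_var ? s2h_fixed : s2h_init;

  for (int it = 0; it < n_iter; ++it) {
    // --- forward filter ---
    for (int t = 0; t < T; ++t) {
      double a = (t == 0) ? m0 : m[t - 1];
      double R = (t == 0) ? C0 : C[t - 1] + s2h;
      if (obs[t]) {
        double K = R / (R + s2e);
        m[t] = a + K * (z[t] - a);
        C[t] = R * (1.0 - K);
      } else {
        m[t] = a;
        C[t] = R;
      }
    }
    // --- backward sample ---
    mu[T - 1] = R::rnorm(m[T - 1], std::sqrt(C[T - 1]));
    for (int t = T - 2; t >= 0; --t) {
      double B = C[t] / (C[t] + s2h);
      double h = m[t] + B * (mu[t + 1] - m[t]);
      double H = C[t] * (1.0 - B);
      mu[t] = R::rnorm(h, std::sqrt(H));
    }
    // --- conjugate variance draws ---
    if (!fix_var) {
      double sse = 0.0;
      for (int t = 0; t < T; ++t)
        if (obs[t]) { double d = z[t] - mu[t]; sse += d * d; }
      s2e = rinvgamma(a_eps + 0.5 * n_obs, b_eps + 0.5 * sse);
      double ssh = 0.0;
      for (int t = 1; t < T; ++t) { double d = mu[t] - mu[t - 1]; ssh += d * d; }
      s2h = rinvgamma(a_eta + 0.5 * (T - 1), b_eta + 0.5 * ssh);
    }
    // --- retain + one-step-ahead predictive draw (transformed scale) ---
    if (it >= burn_in) {
      int k = it - burn_in;
      for (int t = 0; t < T; ++t) mu_keep(k, t) = mu[t];
      s2e_keep[k] = s2e;
      s2h_keep[k] = s2h;
      double mu_next = mu[T - 1] + R::rnorm(0.0, std::sqrt(s2h));
      zf_keep[k] = mu_next + R::rnorm(0.0, std::sqrt(s2e));
    }
  }

  return List::create(_["level"] = mu_keep,
                      _["sig2_obs"] = s2e_keep,
                      _["sig2_level"] = s2h_keep,
                      _["z_forecast"] = zf_keep,
                      _["n_obs"] = n_obs);
}
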