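#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the hierarchical normal model with subject-specific
// variances. Every full conditional depends on the data only through the
// per-subject sufficient statistics (n_i, sum y_ij, sum y_ij^2), so the
// sampler runs in O(I) per iteration regardless of the number of
// observations. Uses R's RNG, so set.seed() on the R side makes runs
// reproducible. Update order per sweep: mu -> tau2 -> {sigma2_i} -> {mu_i}.
//
// Full conditionals:
//   mu     ~ N( (sum mu_i / tau2) / (1/nu^2 + I/tau2), 1/(1/nu^2 + I/tau2) )
//   tau2   ~ IG( a2 + I/2,  b2 + 0.5 * sum (mu_i - mu)^2 )
//   s2_i   ~ IG( a1 + n_i/2, b1 + 0.5 * sum_j (y_ij - mu_i)^2 )
//   mu_i   ~ N( (mu/tau2 + S1_i/s2_i) / (1/tau2 + n_i/s2_i),
//               1/(1/tau2 + n_i/s2_i) )

static inline double rinvgamma(double shape, double rate) {
  // inverse gamma with density b^a / Gamma(a) x^{-a-1} exp(-b/x)
  return rate / R::rgamma(shape, 1.0);
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(NumericVector n_i, NumericVector s1, NumericVector s2,
                double nu, double a1, double b1, double a2, double b2,
                int n_iter, int burn_in, int thin,
                double mu0, double tau20,
                NumericVector mu_i0, NumericVector sigma2_i0) {
  const int I = n_i.size();
  const int kept = (n_iter - burn_in + thin - 1) / thin;
  NumericVector mu_draws(kept), tau2_draws(kept);
  NumericMatrix mu_i_draws(kept, I), sigma2_i_draws(kept, I);

  double mu = mu0, tau2 = tau20;
  std::vector<double> mu_i(mu_i0.begin(), mu_i0.end());
  std::vector<double> sigma2_i(sigma2_i0.begin(), sigma2_i0.end());
  const double inv_nu2 = 1.0 / (nu * nu);

  int row = 0;
  for (int t = 0; t < n_iter; ++t) {
    // mu
    double sum_mu_i = 0.0;
    for (int i = 0; i < I; ++i) sum_mu_i += mu_i[i];
    double prec = inv_nu2 + I / tau2;
    mu = R::rnorm((sum_mu_i / tau2) / prec, std::sqrt(1.0 / prec));

    // tau2
    double ss_mu = 0.0;
    for (int i = 0; i < I; ++i) {
      const double d = mu_i[i] - mu;
      ss_mu += d * d;
    }
    tau2 = rinvgamma(a2 + 0.5 * I, b2 + 0.5 * ss_mu);

    // sigma2_i then mu_i
    for (int i = 0; i < I; ++i) {
      const double ss = s2[i] - 2.0 * mu_i[i] * s1[i] + n_i[i] * mu_i[i] * mu_i[i];
      sigma2_i[i] = rinvgamma(a1 + 0.5 * n_i[i], b1 + 0.5 * std::max(ss, 0.0));
      const double prec_i = 1.0 / tau2 + n_i[i] / sigma2_i[i];
      const double m_i = (mu / tau2 + s1[i] / sigma2_i[i]) / prec_i;
      mu_i[i] = R::rnorm(m_i, std::sqrt(1.0 / prec_i));
    }

    if (t >= burn_in && (t - burn_in) % thin == 0) {
      mu_draws[row] = mu;
      tau2_draws[row] = tau2;
      for (int i = 0; i < I; ++i) {
        mu_i_draws(row, i) = mu_i[i];
        sigma2_i_draws(row, i) = sigma2_i[i];
      }
      ++row;
    }
  }

  return List::create(_["mu"] = mu_draws, _["tau2"] = tau2_draws,
                      _["mu_i"] = mu_i_draws, _["sigma2_i"] = sigma2_i_draws);
}
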