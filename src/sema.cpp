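#include <Rcpp.h>
using namespace Rcpp;

// Streaming (SEMA) loop: per observation, update the touched subject's
// running summaries, recompute its E-step quantities with the current
// parameter estimates, swap its contribution into the CDSS totals and rerun
// the M step from the totals. Mirrors the R reference sema_update() exactly;
// deterministic (no RNG).

// [[Rcpp::export(name = ".sema_stream_core")]]
List sema_stream_core(IntegerVector subj, NumericVector values,
                      NumericVector n_i0, NumericVector ybar0,
                      NumericVector y2bar0, NumericVector sigma20,
                      NumericVector mu_i0, NumericVector nu_i0,
                      NumericVector rho0, NumericVector T30,
                      double mu, double tau2, double T1, double T2,
                      double pool_num, double pool_den, double floor_) {
  NumericVector n_i = clone(n_i0), ybar = clone(ybar0), y2bar = clone(y2bar0),
                sigma2 = clone(sigma20), mu_i = clone(mu_i0),
                nu_i = clone(nu_i0), rho = clone(rho0), T3 = clone(T30);
  const int I = n_i.size();
  const int N = subj.size();

  for (int t = 0; t < N; ++t) {
    const int i = subj[t];
    const double y = values[t];
    const double t1_old = (n_i[i] > 0) ? mu_i[i] : 0.0;
    const double t2_old = (n_i[i] > 0) ? (nu_i[i] + mu_i[i] * mu_i[i]) : 0.0;
    // a brand-new subject has no prior contribution in T1/T2 even though its
    // slots hold placeholder values
    if (n_i[i] >= 2) {
      pool_num -= T3[i];
      pool_den -= n_i[i];
    }
    const double n = n_i[i] + 1.0;
    ybar[i] += (y - ybar[i]) / n;
    y2bar[i] += (y * y - y2bar[i]) / n;
    n_i[i] = n;

    const double r = tau2 / (tau2 + sigma2[i] / n);
    const double m = r * ybar[i] + (1.0 - r) * mu;
    const double v = tau2 * (1.0 - r);
    const double t3 = n * (y2bar[i] - 2.0 * m * ybar[i] + m * m + v);
    rho[i] = r;
    mu_i[i] = m;
    nu_i[i] = v;
    T1 += m - t1_old;
    T2 += (v + m * m) - t2_old;
    T3[i] = t3;

    mu = T1 / I;
    tau2 = T2 / I - mu * mu;
    if (tau2 < floor_) tau2 = floor_;
    if (n >= 2) {
      pool_num += t3;
      pool_den += n;
      sigma2[i] = std::max(t3 / n, floor_);
    } else {
      sigma2[i] = std::max(pool_den > 0 ? pool_num / pool_den : tau2, floor_);
    }
  }

  return List::create(_["n_i"] = n_i, _["ybar"] = ybar, _["y2bar"] = y2bar,
                      _["sigma2"] = sigma2, _["mu_i"] = mu_i,
                      _["nu_i"] = nu_i, _["rho"] = rho, _["T3"] = T3,
                      _["mu"] = mu, _["tau2"] = tau2, _["T1"] = T1,
                      _["T2"] = T2, _["pool_num"] = pool_num,
                      _["pool_den"] = pool_den);
}
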