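#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the Bayesian-alphabet marker-effect models.
//
// Model: y = mu + Z u + e, e ~ N(0, sigma2_e I).
//   Bayes A: u_j ~ N(0, sigma2_j), sigma2_j ~ scaled-inv-chi2(nu_u, S_u).
//   Bayes B: as A but u_j = 0 with prior probability pi (point mass).
//   Bayes C: shared sigma2_u ~ scaled-inv-chi2(nu_u, S_u), point mass pi.
// Residual variance: scaled-inv-chi2(nu_e, S_e).
//
// Draws use R's RNG so a set.seed() on the R side makes the whole chain
// reproducible. Variances may be held fixed (used by the ridge-limit check
// and by users who want a Bayesian ridge with known variances).

static inline double rinvchisq(double nu, double S) {
  // scaled inverse chi-square draw: nu * S / chisq_nu
  return nu * S / R::rchisq(nu);
}

// [[Rcpp::export]]
List bayes_gibbs_cpp(NumericMatrix Z, NumericVector y, std::string variant,
                     int n_iter, int burn_in, int thin,
                     double nu_u, double S_u, double nu_e, double S_e,
                     double pi0,
                     bool fix_sigma_u, double sigma2_u_fixed,
                     bool fix_sigma_e, double sigma2_e_fixed) {
  const int n = Z.nrow();
  const int m = Z.ncol();
  const bool has_mass = (variant != "A") && (pi0 > 0.0);

  std::vector<double> zz(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }

  double mu = mean(y);
  std::vector<double> u(m, 0.0);
  std::vector<int> delta(m, has_mass ? 0 : 1);
  std::vector<double> s2j(m, S_u);      // per-marker variances (Bayes A/B)
  double sigma2_u = fix_sigma_u ? sigma2_u_fixed : S_u;  // shared (Bayes C)
  double sigma2_e = fix_sigma_e ? sigma2_e_fixed : S_e;

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  std::vector<double> u_sum(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0, s2u_sum = 0.0;
  int n_kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar /= n;
    double mu_new = R::rnorm(mu + rbar, std::sqrt(sigma2_e / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= dmu;
    mu = mu_new;

    // marker effects
    for (int j = 0; j < m; ++j) {
      if (zz[j] <= 0.0) { u[j] = 0.0; delta[j] = 0; continue; }
      double sj = (variant == "C") ? sigma2_u : s2j[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * r[i];
      rhs += zz[j] * u[j];

      int dj = 1;
      if (has_mass) {
        double v0 = zz[j] * sigma2_e;
        double v1 = v0 + zz[j] * zz[j] * sj;
        double log_odds = std::log((1.0 - pi0) / pi0) +
          0.5 * (std::log(v0 / v1) + rhs * rhs * (1.0 / v0 - 1.0 / v1));
        double p1 = 1.0 / (1.0 + std::exp(-log_odds));
        dj = (R::unif_rand() < p1) ? 1 : 0;
      }
      double u_new = 0.0;
      if (dj == 1) {
        double C = zz[j] + sigma2_e / sj;
        u_new = R::rnorm(rhs / C, std::sqrt(sigma2_e / C));
      }
      double du = u[j] - u_new;
      if (du != 0.0) {
        for (int i = 0; i < n; ++i) r[i] += Z(i, j) * du;
      }
      u[j] = u_new;
      delta[j] = dj;
    }

    // effect variances
    if (variant == "A") {
      for (int j = 0; j < m; ++j)
        s2j[j] = (nu_u * S_u + u[j] * u[j]) / R::rchisq(nu_u + 1.0);
    } else if (variant == "B") {
      for (int j = 0; j < m; ++j) {
        if (delta[j] == 1)
          s2j[j] = (nu_u * S_u + u[j] * u[j]) / R::rchisq(nu_u + 1.0);
        else
          s2j[j] = rinvchisq(nu_u, S_u);   // prior draw for excluded markers
      }
    } else { // C
      if (!fix_sigma_u) {
        double ssq = 0.0; int m_in = 0;
        for (int j = 0; j < m; ++j) { ssq += u[j] * u[j]; m_in += delta[j]; }
        sigma2_u = (nu_u * S_u + ssq) / R::rchisq(nu_u + m_in);
      }
    }

    // residual variance
    if (!fix_sigma_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += r[i] * r[i];
      sigma2_e = (nu_e * S_e + sse) / R::rchisq(nu_e + n);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int j = 0; j < m; ++j) {
        u_sum[j] += u[j];
        incl_sum[j] += delta[j];
      }
      mu_sum += mu;
      s2e_sum += sigma2_e;
      s2u_sum += sigma2_u;
      ++n_kept;
    }
  }

  NumericVector u_mean(m), incl(m);
  for (int j = 0; j < m; ++j) {
    u_mean[j] = u_sum[j] / n_kept;
    incl[j] = incl_sum[j] / n_kept;
  }
  return List::create(
    _["u"] = u_mean,
    _["inclusion"] = incl,
    _["mu"] = mu_sum / n_kept,
    _["sigma2_e"] = s2e_sum / n_kept,
    _["sigma2_u"] = s2u_sum / n_kept,
    _["n_kept"] = n_kept
  );
}
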