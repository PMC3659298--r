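#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian sampler (Michael, Schucany & Haas transform), using R's RNG
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// scaled-inverse-chi-square draw: (S + q) / chisq(df)
static double rscinv(double S, double q, double df) {
  double chi = R::rchisq(df);
  if (chi < 1e-12) chi = 1e-12;
  return (S + q) / chi;
}

// Gibbs sampler for Bayesian lasso (penalty = 0) / ridge (penalty = 1)
// whole-genome regression with flat-prior fixed effects and an optional
// random subject intercept.
//
// y = W theta + X beta + Z u + e
//   e ~ N(0, varE I); u_i ~ N(0, varU)
//   lasso: beta_j ~ N(0, varE tau2_j), tau2_j ~ Exp(lambda2/2),
//          lambda2 ~ Gamma(lambda_shape, lambda_rate)   [unless fixed]
//   ridge: beta_j ~ N(0, varB), varB ~ S_B/chisq(df_B)  [unless fixed]
//   varE ~ S_E/chisq(df_E) [unless fixed], varU ~ S_U/chisq(df_U)
//
// Negative df for varE/varB or fix_lambda = true pin the corresponding
// parameter at its initial value (used by the conjugate small-scale checks).
// [[Rcpp::export(name = ".wgr_gibbs")]]
List wgr_gibbs(NumericVector y, NumericMatrix W, NumericMatrix X,
               IntegerVector subj, int n_subj, int penalty,
               double varE_df, double varE_S, double varU_df, double varU_S,
               double varB_df, double varB_S, double lambda2_init,
               double lambda_shape, double lambda_rate, bool fix_lambda,
               bool has_groups, int n_iter, int burnin, int thin,
               bool store_beta) {
  RNGScope scope;
  const int K = y.size();
  const int p = W.ncol();
  const int m = X.ncol();
  if (n_iter <= burnin) stop("n_iter must exceed burnin");

  const bool fixE = varE_df < 0.0;
  const bool fixB = varB_df < 0.0;

  std::vector<double> wss(p), xss(m);
  for (int l = 0; l < p; ++l) {
    double s = 0.0;
    for (int i = 0; i < K; ++i) s += W(i, l) * W(i, l);
    wss[l] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < K; ++i) s += X(i, j) * X(i, j);
    xss[j] = s;
  }
  std::vector<int> kcount(n_subj, 0);
  for (int i = 0; i < K; ++i) kcount[subj[i]]++;

  std::vector<double> theta(p, 0.0), beta(m, 0.0), u(n_subj, 0.0),
      tau2(m, 1.0);
  double varE = fixE ? varE_S : varE_S / std::max(varE_df - 2.0, 1.0);
  double varU = varU_S / std::max(varU_df - 2.0, 1.0);
  double varB = fixB ? varB_S : varB_S / std::max(varB_df - 2.0, 1.0);
  double lambda2 = lambda2_init;

  // residual r = y - W theta - X beta - Z u (all coefficients start at 0)
  std::vector<double> r(K);
  for (int i = 0; i < K; ++i) r[i] = y[i];

  std::vector<double> theta_sum(p, 0.0), beta_sum(m, 0.0), u_sum(n_subj, 0.0);
  int n_keep = (n_iter - burnin + thin - 1) / thin;
  NumericVector varE_chain(n_keep), varU_chain(n_keep), hyper_chain(n_keep);
  NumericMatrix beta_chain(store_beta ? n_keep : 0, store_beta ? m : 0);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, coordinate-wise, flat prior
    for (int l = 0; l < p; ++l) {
      if (wss[l] <= 0.0) continue;
      const double *wcol = &W(0, l);
      double rhs = 0.0;
      for (int i = 0; i < K; ++i) rhs += wcol[i] * r[i];
      rhs += wss[l] * theta[l];
      double newv = rhs / wss[l] + norm_rand() * std::sqrt(varE / wss[l]);
      double d = newv - theta[l];
      theta[l] = newv;
      for (int i = 0; i < K; ++i) r[i] -= d * wcol[i];
    }
    // marker effects
    for (int j = 0; j < m; ++j) {
      double prec = (penalty == 0) ? 1.0 / tau2[j] : varE / varB;
      double c = xss[j] + prec;
      if (xss[j] <= 0.0) { // zero column: draw from the prior
        double pv = (penalty == 0) ? varE * tau2[j] : varB;
        beta[j] = norm_rand() * std::sqrt(pv);
        continue; // no residual update needed for a zero column
      }
      const double *xcol = &X(0, j);
      double rhs = 0.0;
      for (int i = 0; i < K; ++i) rhs += xcol[i] * r[i];
      rhs += xss[j] * beta[j];
      double newv = rhs / c + norm_rand() * std::sqrt(varE / c);
      double d = newv - beta[j];
      beta[j] = newv;
      if (d != 0.0)
        for (int i = 0; i < K; ++i) r[i] -= d * xcol[i];
    }
    // shrinkage hierarchy
    if (penalty == 0) {
      for (int j = 0; j < m; ++j) {
        double b2 = beta[j] * beta[j];
        if (b2 < 1e-12) b2 = 1e-12;
        double mu = std::sqrt(lambda2 * varE / b2);
        double inv = rinvgauss(mu, lambda2);
        tau2[j] = 1.0 / inv;
      }
      if (!fix_lambda) {
        double sum_tau2 = 0.0;
        for (int j = 0; j < m; ++j) sum_tau2 += tau2[j];
        lambda2 = R::rgamma(lambda_shape + m, 1.0 / (lambda_rate + 0.5 * sum_tau2));
      }
    } else if (!fixB) {
      double ssb = 0.0;
      for (int j = 0; j < m; ++j) ssb += beta[j] * beta[j];
      varB = rscinv(varB_S, ssb, varB_df + m);
    }
    // subject intercepts: r holds y - Wtheta - Xbeta - Zu, so the
    // conditional mean for u_g uses rsum_g + k_g * u_g_old
    if (has_groups) {
      std::vector<double> rsum(n_subj, 0.0), du(n_subj, 0.0);
      for (int i = 0; i < K; ++i) rsum[subj[i]] += r[i];
      for (int g = 0; g < n_subj; ++g) {
        double c = kcount[g] + varE / varU;
        double mean = (rsum[g] + kcount[g] * u[g]) / c;
        double newv = mean + norm_rand() * std::sqrt(varE / c);
        du[g] = newv - u[g];
        u[g] = newv;
      }
      for (int i = 0; i < K; ++i) r[i] -= du[subj[i]];
    }
    // variance components
    if (has_groups) {
      double ssu = 0.0;
      for (int g = 0; g < n_subj; ++g) ssu += u[g] * u[g];
      varU = rscinv(varU_S, ssu, varU_df + n_subj);
    }
    double sse = 0.0;
    for (int i = 0; i < K; ++i) sse += r[i] * r[i];
    if (!fixE) {
      if (penalty == 0) {
        double ssb_tau = 0.0;
        for (int j = 0; j < m; ++j) ssb_tau += beta[j] * beta[j] / tau2[j];
        varE = rscinv(varE_S, sse + ssb_tau, varE_df + K + m);
      } else {
        varE = rscinv(varE_S, sse, varE_df + K);
      }
    }
    if (!R_finite(varE) || !R_finite(beta[0]))
      stop("wgr_gibbs: non-finite draw at iteration %d", it + 1);

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      for (int l = 0; l < p; ++l) theta_sum[l] += theta[l];
      for (int j = 0; j < m; ++j) beta_sum[j] += beta[j];
      for (int g = 0; g < n_subj; ++g) u_sum[g] += u[g];
      varE_chain[kept] = varE;
      varU_chain[kept] = has_groups ? varU : NA_REAL;
      hyper_chain[kept] = (penalty == 0) ? lambda2 : varB;
      if (store_beta)
        for (int j = 0; j < m; ++j) beta_chain(kept, j) = beta[j];
      kept++;
    }
  }

  NumericVector theta_mean(p), beta_mean(m), u_mean(n_subj);
  for (int l = 0; l < p; ++l) theta_mean[l] = theta_sum[l] / kept;
  for (int j = 0; j < m; ++j) beta_mean[j] = beta_sum[j] / kept;
  for (int g = 0; g < n_subj; ++g) u_mean[g] = u_sum[g] / kept;

  return List::create(
      _["theta_mean"] = theta_mean, _["beta_mean"] = beta_mean,
      _["u_mean"] = u_mean, _["varE_chain"] = varE_chain,
      _["varU_chain"] = varU_chain, _["hyper_chain"] = hyper_chain,
      _["beta_chain"] = beta_chain, _["n_kept"] = kept);
}
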