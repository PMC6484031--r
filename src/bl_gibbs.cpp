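#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian draw via the Michael-Schucany-Haas transformation.
// mu > 0 location, lambda > 0 shape.
static double rinvgaussian(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Gibbs sampler for the Bayesian Lasso regression
//   y = X b + W o + e,  b flat,
//   o_j | tau2_j, sig2e ~ N(0, tau2_j * sig2e),
//   tau2_j ~ Exp(rate = lambda^2 / 2),
//   sig2e ~ scaled-inv-chi2(df_e, S_e)  (sum-of-squares scale).
// X is expected to contain the intercept column.
// fix_sigma2 / fix_tau2 <= 0 mean "sample them"; positive values freeze the
// corresponding parameter (used by the conjugate-oracle tests).
// [[Rcpp::export(name = ".bl_gibbs_cpp")]]
List bl_gibbs_cpp(NumericVector y, NumericMatrix X, NumericMatrix W,
                  double lambda, double df_e, double S_e, int n_iter,
                  int burn_in, int thin, double fix_sigma2, double fix_tau2,
                  bool keep_samples) {
  int n = y.size();
  int q = X.ncol();
  int p = W.ncol();

  std::vector<double> xtx(q), wtw(p);
  for (int k = 0; k < q; ++k) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xtx[k] = s;
  }
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    wtw[j] = s;
  }

  NumericVector b(q, 0.0), o(p, 0.0), tau2(p, 1.0);
  double vy = 0, my = 0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= std::max(1, n - 1);
  double sig2e = (fix_sigma2 > 0) ? fix_sigma2 : std::max(1e-8, 0.5 * vy);
  if (fix_tau2 > 0) std::fill(tau2.begin(), tau2.end(), fix_tau2);

  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - my;
  b[0] = my; // assumes first X column is the intercept
  for (int i = 0; i < n; ++i) e[i] = y[i];
  for (int k = 0; k < q; ++k)
    for (int i = 0; i < n; ++i) e[i] -= X(i, k) * b[k];

  int n_keep = 0;
  NumericVector b_sum(q, 0.0), b_ss(q, 0.0), o_sum(p, 0.0), o_ss(p, 0.0);
  double sig2e_sum = 0, sig2e_ss = 0;
  NumericMatrix o_draws, b_draws;
  NumericVector sig2e_draws;
  int total_keep = 0;
  for (int it = 0; it < n_iter; ++it)
    if (it >= burn_in && ((it - burn_in) % thin == 0)) ++total_keep;
  if (keep_samples) {
    o_draws = NumericMatrix(total_keep, p);
    b_draws = NumericMatrix(total_keep, q);
    sig2e_draws = NumericVector(total_keep);
  }

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, scalar Gibbs with flat prior
    for (int k = 0; k < q; ++k) {
      if (xtx[k] <= 0) continue;
      double r = 0;
      for (int i = 0; i < n; ++i) r += X(i, k) * e[i];
      double mean_k = b[k] + r / xtx[k];
      double new_b = R::rnorm(mean_k, std::sqrt(sig2e / xtx[k]));
      double d = new_b - b[k];
      if (d != 0) for (int i = 0; i < n; ++i) e[i] -= X(i, k) * d;
      b[k] = new_b;
    }
    // OTU effects
    for (int j = 0; j < p; ++j) {
      double cj = wtw[j] + 1.0 / tau2[j];
      if (wtw[j] <= 0 && fix_tau2 <= 0) { o[j] = 0; continue; }
      double r = 0;
      for (int i = 0; i < n; ++i) r += W(i, j) * e[i];
      double mean_j = (r + wtw[j] * o[j]) / cj;
      double new_o = R::rnorm(mean_j, std::sqrt(sig2e / cj));
      double d = new_o - o[j];
      if (d != 0) for (int i = 0; i < n; ++i) e[i] -= W(i, j) * d;
      o[j] = new_o;
    }
    // scale-mixture variances
    if (fix_tau2 <= 0) {
      for (int j = 0; j < p; ++j) {
        double oj2 = o[j] * o[j];
        if (oj2 < 1e-14) oj2 = 1e-14;
        double mu = std::sqrt(lambda * lambda * sig2e / oj2);
        double inv = rinvgaussian(mu, lambda * lambda);
        tau2[j] = 1.0 / std::max(inv, 1e-12);
      }
    }
    // residual variance
    if (fix_sigma2 <= 0) {
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      double sso = 0;
      for (int j = 0; j < p; ++j) sso += o[j] * o[j] / tau2[j];
      double df_post = df_e + n + p;
      double S_post = S_e + sse + sso;
      sig2e = S_post / R::rchisq(df_post);
    }
    if (!std::isfinite(sig2e) || sig2e <= 0)
      stop("Bayesian Lasso sampler diverged (non-finite residual variance)");

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int k = 0; k < q; ++k) { b_sum[k] += b[k]; b_ss[k] += b[k] * b[k]; }
      for (int j = 0; j < p; ++j) { o_sum[j] += o[j]; o_ss[j] += o[j] * o[j]; }
      sig2e_sum += sig2e;
      sig2e_ss += sig2e * sig2e;
      if (keep_samples) {
        for (int j = 0; j < p; ++j) o_draws(n_keep, j) = o[j];
        for (int k = 0; k < q; ++k) b_draws(n_keep, k) = b[k];
        sig2e_draws[n_keep] = sig2e;
      }
      ++n_keep;
    }
  }
  if (n_keep == 0) stop("no post-burn-in samples kept");

  NumericVector b_mean(q), b_sd(q), o_mean(p), o_sd(p);
  for (int k = 0; k < q; ++k) {
    b_mean[k] = b_sum[k] / n_keep;
    double v = b_ss[k] / n_keep - b_mean[k] * b_mean[k];
    b_sd[k] = std::sqrt(std::max(0.0, v));
  }
  for (int j = 0; j < p; ++j) {
    o_mean[j] = o_sum[j] / n_keep;
    double v = o_ss[j] / n_keep - o_mean[j] * o_mean[j];
    o_sd[j] = std::sqrt(std::max(0.0, v));
  }
  List out = List::create(
      _["b_mean"] = b_mean, _["b_sd"] = b_sd, _["o_mean"] = o_mean,
      _["o_sd"] = o_sd, _["sigma2e_mean"] = sig2e_sum / n_keep,
      _["sigma2e_sd"] = std::sqrt(std::max(
          0.0, sig2e_ss / n_keep - (sig2e_sum / n_keep) * (sig2e_sum / n_keep))),
      _["n_kept"] = n_keep);
  if (keep_samples) {
    out["o_draws"] = o_draws;
    out["b_draws"] = b_draws;
    out["sigma2e_draws"] = sig2e_draws;
  }
  return out;
}
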