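// Gibbs samplers for whole-genome regression: Bayes A, Bayes C (with
// inclusion indicators and sampled pi), and the Bayesian Lasso
// (Park-Casella exponential-mixture representation).
//
// All samplers share the residual-update scheme: e = y - mu - X b is kept
// current, each marker's full conditional uses rhs = x_j' e computed after
// adding the marker's own contribution back.

#include <Rcpp.h>
using namespace Rcpp;

// scaled-inverse-chi-square draw: (df * scale + ss) / chisq(df + n)
static double rinvchisq(double df, double num) {
  return num / R::rchisq(df);
}

// Michael-Schucany-Haas inverse-Gaussian sampler
static double rinvgauss(double mu, double lambda) {
  double v = R::norm_rand();
  double y = v * v;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(NumericMatrix X, NumericVector y, std::string model,
               int niter, int burnin, int thin,
               double nu, double scale_b, double nu_e, double scale_e,
               double pi_a, double pi_b,
               double lasso_shape, double lasso_rate) {
  int n = X.nrow(), m = X.ncol();
  const double *Xp = X.begin();
  std::vector<double> b(m, 0.0), vb(m, scale_b > 0 ? scale_b : 0.01);
  std::vector<double> tau2(m, 1.0);
  std::vector<int> delta(m, 1);
  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    const double *xj = Xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
    if (s <= 0) stop("zero-variance marker column %d", j + 1);
  }
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double vy = var(y);
  double ve = vy * 0.5;
  double vb_common = scale_b;                 // BayesC common effect variance
  double pi = 0.5;                            // BayesC inclusion probability
  double lambda2 = 2.0 * lasso_shape / std::max(lasso_rate, 1e-8);

  int nsave = 0;
  std::vector<double> b_post(m, 0.0), incl_post(m, 0.0);
  double mu_post = 0.0, ve_post = 0.0, vb_post = 0.0, pi_post = 0.0;

  for (int it = 0; it < niter; ++it) {
    // intercept
    double se_ = 0.0;
    for (int i = 0; i < n; ++i) { e[i] += mu; se_ += e[i]; }
    mu = R::rnorm(se_ / n, std::sqrt(ve / n));
    for (int i = 0; i < n; ++i) e[i] -= mu;

    int m_in = 0;
    double ssb_in = 0.0, sum_tau2 = 0.0;

    for (int j = 0; j < m; ++j) {
      const double *xj = Xp + (size_t)j * n;
      double bj = b[j];
      double rhs = 0.0;
      if (bj != 0.0) {
        for (int i = 0; i < n; ++i) { e[i] += xj[i] * bj; rhs += xj[i] * e[i]; }
      } else {
        for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      }

      double bnew = 0.0;
      if (model == "A") {
        double C = xtx[j] + ve / vb[j];
        bnew = R::rnorm(rhs / C, std::sqrt(ve / C));
        vb[j] = rinvchisq(nu + 1.0, nu * scale_b + bnew * bnew);
      } else if (model == "C") {
        double v0 = xtx[j] * ve;
        double v1 = xtx[j] * xtx[j] * vb_common + v0;
        double logodds = std::log(pi / (1.0 - pi)) +
          0.5 * std::log(v0 / v1) + 0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double p1 = 1.0 / (1.0 + std::exp(-logodds));
        if (R::unif_rand() < p1) {
          double C = xtx[j] + ve / vb_common;
          bnew = R::rnorm(rhs / C, std::sqrt(ve / C));
          delta[j] = 1;
          ++m_in;
          ssb_in += bnew * bnew;
        } else {
          delta[j] = 0;
        }
      } else { // Lasso
        double C = xtx[j] + 1.0 / tau2[j];
        bnew = R::rnorm(rhs / C, std::sqrt(ve / C));
        double b2 = std::max(bnew * bnew, 1e-12);
        double itau = rinvgauss(std::sqrt(lambda2 * ve / b2), lambda2);
        tau2[j] = 1.0 / std::max(itau, 1e-12);
        sum_tau2 += tau2[j];
      }

      if (bnew != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * bnew;
      }
      b[j] = bnew;
    }

    if (model == "C") {
      vb_common = rinvchisq(nu + m_in, nu * scale_b + ssb_in);
      pi = R::rbeta(pi_a + m_in, pi_b + m - m_in);
    }
    if (model == "L") {
      lambda2 = R::rgamma(lasso_shape + m, 1.0 / (lasso_rate + sum_tau2 / 2.0));
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    ve = rinvchisq(nu_e + n, nu_e * scale_e + sse);
    if (!std::isfinite(ve) || ve > 1e12) {
      stop("non-convergent residual variance draw (iteration %d, ve = %g)",
           it + 1, ve);
    }

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++nsave;
      for (int j = 0; j < m; ++j) {
        b_post[j] += b[j];
        incl_post[j] += (model == "C") ? delta[j] : (b[j] != 0.0 ? 1 : 0);
      }
      mu_post += mu; ve_post += ve;
      vb_post += (model == "C") ? vb_common : 0.0;
      pi_post += pi;
    }
  }
  if (nsave == 0) stop("no posterior samples: check niter/burnin/thin");
  NumericVector bp(m), ip(m);
  for (int j = 0; j < m; ++j) {
    bp[j] = b_post[j] / nsave;
    ip[j] = incl_post[j] / nsave;
  }
  return List::create(
    _["effects"] = bp, _["inclusion"] = ip,
    _["mu"] = mu_post / nsave, _["ve"] = ve_post / nsave,
    _["vb"] = vb_post / nsave, _["pi"] = pi_post / nsave,
    _["n_samples"] = nsave
  );
}
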