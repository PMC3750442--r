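// Compiled core of the MU marker-regression model: single-site Gibbs sweep
// and GEM fixed-point sweep. The conditional-distribution algebra mirrors
// the R reference functions in R/conditionals.R; all tail masses are kept
// in log space so the three component weights never underflow to all-zero.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log(exp(x) - exp(y)) for x >= y
static inline double log_sub_exp(double x, double y) {
  return x + log1p(-std::exp(y - x));
}

// log(Phi(b) - Phi(a)) for a < b, stable in both tails
static double log_pnorm_diff(double a, double b) {
  if (a > 0.0) {
    double la = R::pnorm(a, 0.0, 1.0, 0, 1);
    double lb = R::pnorm(b, 0.0, 1.0, 0, 1);
    return log_sub_exp(la, lb);
  }
  double lb = R::pnorm(b, 0.0, 1.0, 1, 1);
  double la = R::pnorm(a, 0.0, 1.0, 1, 1);
  return log_sub_exp(lb, la);
}

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// mean of N(mu, tau^2) truncated to [lo, hi]
static double truncnorm_mean(double mu, double tau, double lo, double hi) {
  double a = (lo - mu) / tau, b = (hi - mu) / tau;
  double lZ = log_pnorm_diff(a, b);
  if (!R_FINITE(lZ)) return clamp(mu, lo, hi);
  double m = mu + tau * (std::exp(R::dnorm(a, 0.0, 1.0, 1) - lZ) -
                         std::exp(R::dnorm(b, 0.0, 1.0, 1) - lZ));
  if (!R_FINITE(m)) m = mu;
  return clamp(m, lo, hi);
}

// inverse-CDF draw from N(mu, tau^2) truncated to [lo, hi]
static double r_truncnorm(double mu, double tau, double lo, double hi) {
  const double eps = 1e-15;
  double u = unif_rand();
  u = clamp(u, eps, 1.0 - eps);
  double a = (lo - mu) / tau, b = (hi - mu) / tau;
  double x;
  if (a >= 0.0) {
    double la = R::pnorm(a, 0.0, 1.0, 0, 1);
    double lb = R::pnorm(b, 0.0, 1.0, 0, 1);
    double lq = la + log1p(-u * (-std::expm1(lb - la)));
    x = mu + tau * R::qnorm(lq, 0.0, 1.0, 0, 1);
  } else if (b <= 0.0) {
    double lbm = R::pnorm(-b, 0.0, 1.0, 0, 1);
    double lam = R::pnorm(-a, 0.0, 1.0, 0, 1);
    double lq = lbm + log1p(-u * (-std::expm1(lam - lbm)));
    x = mu - tau * R::qnorm(lq, 0.0, 1.0, 0, 1);
  } else {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0), pb = R::pnorm(b, 0.0, 1.0, 1, 0);
    double p = clamp(pa + u * (pb - pa), eps, 1.0 - eps);
    x = mu + tau * R::qnorm(p, 0.0, 1.0, 1, 0);
  }
  return clamp(x, lo, hi);
}

struct MixWork {
  double w[3];
  double lo[3];
  double hi[3];
};

// normalized component weights of the conditional truncated-normal mixture
static void mixture_weights(double mu_t, double tau, double p0, double bb,
                            double ll, MixWork &mw) {
  mw.lo[0] = -bb; mw.hi[0] = bb;
  mw.lo[1] = -ll; mw.hi[1] = -bb;
  mw.lo[2] = bb;  mw.hi[2] = ll;
  double lh_spike = std::log(p0) - std::log(2.0 * bb);
  double lh_slab = log1p(-p0) - std::log(2.0 * (ll - bb));
  double lw[3];
  lw[0] = lh_spike + log_pnorm_diff((mw.lo[0] - mu_t) / tau,
                                    (mw.hi[0] - mu_t) / tau);
  lw[1] = lh_slab + log_pnorm_diff((mw.lo[1] - mu_t) / tau,
                                   (mw.hi[1] - mu_t) / tau);
  lw[2] = lh_slab + log_pnorm_diff((mw.lo[2] - mu_t) / tau,
                                   (mw.hi[2] - mu_t) / tau);
  double mx = std::max(lw[0], std::max(lw[1], lw[2]));
  if (!R_FINITE(mx)) {
    int j = (mu_t > bb) ? 2 : ((mu_t < -bb) ? 1 : 0);
    mw.w[0] = mw.w[1] = mw.w[2] = 0.0;
    mw.w[j] = 1.0;
    return;
  }
  double tot = 0.0;
  for (int j = 0; j < 3; ++j) { mw.w[j] = std::exp(lw[j] - mx); tot += mw.w[j]; }
  for (int j = 0; j < 3; ++j) mw.w[j] /= tot;
}

// one Gibbs draw of a marker effect from its full conditional
static double beta_draw(double mu_t, double tau, double p0, double bb,
                        double ll) {
  MixWork mw;
  mixture_weights(mu_t, tau, p0, bb, ll, mw);
  double u = unif_rand(), cum = 0.0;
  int j = 2;
  for (int c = 0; c < 3; ++c) {
    cum += mw.w[c];
    if (u <= cum) { j = c; break; }
  }
  return r_truncnorm(mu_t, tau, mw.lo[j], mw.hi[j]);
}

// conditional expectation of a marker effect (GEM update)
static double beta_mean(double mu_t, double tau, double p0, double bb,
                        double ll) {
  MixWork mw;
  mixture_weights(mu_t, tau, p0, bb, ll, mw);
  double m = 0.0;
  for (int j = 0; j < 3; ++j)
    if (mw.w[j] > 0.0)
      m += mw.w[j] * truncnorm_mean(mu_t, tau, mw.lo[j], mw.hi[j]);
  return m;
}

// [[Rcpp::export]]
List gibbs_mu_cpp(const NumericMatrix X, const NumericVector y,
                  const IntegerVector fam, const int K,
                  const double p0, const double bb, const double ll,
                  const double c_alpha, const double s, const double r,
                  const double s_u, const double r_u, const bool polygenic,
                  const int n_iter, const int burn_in, const int thin,
                  const double alpha_init, const NumericVector beta_init,
                  const NumericVector u_init, const double sigma2_init,
                  const double sigma2_u_init, const bool update_alpha,
                  const bool update_sigma2, const int check_every) {
  const int N = X.nrow(), M = X.ncol();
  const double *Xp = &X[0];
  std::vector<double> xx(M);
  for (int m = 0; m < M; ++m) {
    const double *x = Xp + (size_t)m * N;
    double t = 0.0;
    for (int j = 0; j < N; ++j) t += x[j] * x[j];
    xx[m] = t;
  }
  std::vector<int> nk;
  if (polygenic) {
    nk.assign(K, 0);
    for (int j = 0; j < N; ++j) nk[fam[j] - 1]++;
  }

  double alpha = alpha_init, sigma2 = sigma2_init, sigma2_u = sigma2_u_init;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> u(polygenic ? K : 0, 0.0);
  if (polygenic)
    for (int k = 0; k < K; ++k) u[k] = u_init[k];

  // running residual e = y - alpha - X beta - Z u
  std::vector<double> e(N);
  for (int j = 0; j < N; ++j) {
    double fit = alpha;
    if (polygenic) fit += u[fam[j] - 1];
    e[j] = y[j] - fit;
  }
  for (int m = 0; m < M; ++m)
    if (beta[m] != 0.0)
      for (int j = 0; j < N; ++j) e[j] -= Xp[(size_t)m * N + j] * beta[m];

  const int T = (n_iter - burn_in) / thin;
  NumericMatrix beta_st(T, M);
  NumericVector alpha_st(T), s2_st(T), s2u_st(T);
  NumericMatrix u_st(polygenic ? T : 0, polygenic ? K : 0);
  double max_resid_dev = 0.0;
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    if (update_alpha) {
      double sum_r = alpha * N;
      for (int j = 0; j < N; ++j) sum_r += e[j];
      double v = 1.0 / (N / sigma2 + 1.0 / c_alpha);
      double newa = v * sum_r / sigma2 + std::sqrt(v) * norm_rand();
      double d = alpha - newa;
      for (int j = 0; j < N; ++j) e[j] += d;
      alpha = newa;
    }
    for (int m = 0; m < M; ++m) {
      if (xx[m] <= 0.0) continue;
      const double *x = Xp + (size_t)m * N;
      double xr = beta[m] * xx[m];
      for (int j = 0; j < N; ++j) xr += x[j] * e[j];
      double mu_t = xr / xx[m];
      double tau = std::sqrt(sigma2 / xx[m]);
      double bnew = beta_draw(mu_t, tau, p0, bb, ll);
      double d = beta[m] - bnew;
      if (d != 0.0)
        for (int j = 0; j < N; ++j) e[j] += x[j] * d;
      beta[m] = bnew;
    }
    if (polygenic) {
      std::vector<double> se(K, 0.0);
      for (int j = 0; j < N; ++j) se[fam[j] - 1] += e[j];
      std::vector<double> old_u(u);
      double ssu = 0.0;
      for (int k = 0; k < K; ++k) {
        double rsum = se[k] + nk[k] * old_u[k];
        double v = 1.0 / (nk[k] / sigma2 + 1.0 / sigma2_u);
        u[k] = v * rsum / sigma2 + std::sqrt(v) * norm_rand();
        ssu += u[k] * u[k];
      }
      for (int j = 0; j < N; ++j)
        e[j] += old_u[fam[j] - 1] - u[fam[j] - 1];
      sigma2_u = 1.0 / R::rgamma(s_u + K / 2.0, 1.0 / (r_u + 0.5 * ssu));
    }
    if (update_sigma2) {
      double sse = 0.0;
      for (int j = 0; j < N; ++j) sse += e[j] * e[j];
      sigma2 = 1.0 / R::rgamma(s + N / 2.0, 1.0 / (r + 0.5 * sse));
    }
    if (!R_FINITE(sigma2) || !R_FINITE(e[0]))
      stop("numerical failure at Gibbs iteration %d", it);
    if (check_every > 0 && it % check_every == 0) {
      // compare running residual to a fresh recomputation, then refresh
      std::vector<double> et(N);
      for (int j = 0; j < N; ++j) {
        double fit = alpha;
        if (polygenic) fit += u[fam[j] - 1];
        et[j] = y[j] - fit;
      }
      for (int m = 0; m < M; ++m)
        if (beta[m] != 0.0)
          for (int j = 0; j < N; ++j) et[j] -= Xp[(size_t)m * N + j] * beta[m];
      for (int j = 0; j < N; ++j) {
        double d = std::fabs(e[j] - et[j]);
        if (d > max_resid_dev) max_resid_dev = d;
      }
      e = et;
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < T) {
      for (int m = 0; m < M; ++m) beta_st(stored, m) = beta[m];
      alpha_st[stored] = alpha;
      s2_st[stored] = sigma2;
      s2u_st[stored] = polygenic ? sigma2_u : NA_REAL;
      if (polygenic)
        for (int k = 0; k < K; ++k) u_st(stored, k) = u[k];
      stored++;
    }
  }
  return List::create(_["beta"] = beta_st, _["alpha"] = alpha_st,
                      _["sigma2"] = s2_st, _["sigma2_u"] = s2u_st,
                      _["u"] = u_st, _["max_resid_dev"] = max_resid_dev);
}

// [[Rcpp::export]]
List gem_mu_cpp(const NumericMatrix X, const NumericVector y,
                const IntegerVector fam, const int K,
                const double p0, const double bb, const double ll,
                const double c_alpha, const double s, const double r,
                const double s_u, const double r_u, const bool polygenic,
                const double tol_total, const int max_iter,
                const double alpha_init, const NumericVector beta_init,
                const double sigma2_init, const double sigma2_u_init) {
  const int N = X.nrow(), M = X.ncol();
  const double *Xp = &X[0];
  std::vector<double> xx(M);
  for (int m = 0; m < M; ++m) {
    const double *x = Xp + (size_t)m * N;
    double t = 0.0;
    for (int j = 0; j < N; ++j) t += x[j] * x[j];
    xx[m] = t;
  }
  std::vector<int> nk;
  if (polygenic) {
    nk.assign(K, 0);
    for (int j = 0; j < N; ++j) nk[fam[j] - 1]++;
  }

  double alpha = alpha_init, sigma2 = sigma2_init, sigma2_u = sigma2_u_init;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> u(polygenic ? K : 0, 0.0);

  std::vector<double> e(N);
  for (int j = 0; j < N; ++j) e[j] = y[j] - alpha;
  for (int m = 0; m < M; ++m)
    if (beta[m] != 0.0)
      for (int j = 0; j < N; ++j) e[j] -= Xp[(size_t)m * N + j] * beta[m];

  std::vector<double> trace;
  bool converged = false;
  int it = 0;
  double dev = NA_REAL;
  while (it < max_iter) {
    ++it;
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
    dev = 0.0;
    {
      double sum_r = alpha * N;
      for (int j = 0; j < N; ++j) sum_r += e[j];
      double v = 1.0 / (N / sigma2 + 1.0 / c_alpha);
      double newa = v * sum_r / sigma2;
      dev += std::fabs(newa - alpha);
      double d = alpha - newa;
      for (int j = 0; j < N; ++j) e[j] += d;
      alpha = newa;
    }
    for (int m = 0; m < M; ++m) {
      if (xx[m] <= 0.0) continue;
      const double *x = Xp + (size_t)m * N;
      double xr = beta[m] * xx[m];
      for (int j = 0; j < N; ++j) xr += x[j] * e[j];
      double mu_t = xr / xx[m];
      double tau = std::sqrt(sigma2 / xx[m]);
      double bnew = beta_mean(mu_t, tau, p0, bb, ll);
      dev += std::fabs(bnew - beta[m]);
      double d = beta[m] - bnew;
      if (d != 0.0)
        for (int j = 0; j < N; ++j) e[j] += x[j] * d;
      beta[m] = bnew;
    }
    if (polygenic) {
      std::vector<double> se(K, 0.0);
      for (int j = 0; j < N; ++j) se[fam[j] - 1] += e[j];
      std::vector<double> old_u(u);
      double ssu = 0.0;
      for (int k = 0; k < K; ++k) {
        double rsum = se[k] + nk[k] * old_u[k];
        double v = 1.0 / (nk[k] / sigma2 + 1.0 / sigma2_u);
        u[k] = v * rsum / sigma2;
        dev += std::fabs(u[k] - old_u[k]);
        ssu += u[k] * u[k];
      }
      for (int j = 0; j < N; ++j)
        e[j] += old_u[fam[j] - 1] - u[fam[j] - 1];
      double news2u = (r_u + 0.5 * ssu) / (s_u + K / 2.0 - 1.0);
      dev += std::fabs(news2u - sigma2_u);
      sigma2_u = news2u;
    }
    {
      double sse = 0.0;
      for (int j = 0; j < N; ++j) sse += e[j] * e[j];
      double news2 = (r + 0.5 * sse) / (s + N / 2.0 - 1.0);
      dev += std::fabs(news2 - sigma2);
      sigma2 = news2;
    }
    if (!R_FINITE(dev)) stop("numerical failure at GEM iteration %d", it);
    trace.push_back(dev);
    if (dev < tol_total) { converged = true; break; }
  }
  NumericVector beta_out(beta.begin(), beta.end());
  NumericVector u_out(u.begin(), u.end());
  return List::create(_["alpha"] = alpha, _["beta"] = beta_out,
                      _["u"] = u_out, _["sigma2"] = sigma2,
                      _["sigma2_u"] = polygenic ? sigma2_u : NA_REAL,
                      _["n_iters"] = it, _["final_deviation"] = dev,
                      _["converged"] = converged,
                      _["deviation_trace"] = NumericVector(trace.begin(),
                                                           trace.end()));
}
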