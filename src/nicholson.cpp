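// Metropolis-within-Gibbs sampler for the censored-normal population
// divergence model: p_ij ~ N(pi_j, c_i pi_j (1 - pi_j)) censored to
// {0} + (0,1) + {1}, x_ij ~ Binomial(n_ij, p_ij), priors uniform on
// pi_j and c_i. Proposal scales adapt during burn-in only.

#include <Rcpp.h>
using namespace Rcpp;

// log density of the censored normal at p (atoms at 0 and 1 carry the
// tail mass of N(pi, c pi (1-pi)))
static inline double lp_censored(double p, double pi, double c) {
  double sd = std::sqrt(c * pi * (1.0 - pi));
  if (sd <= 0.0) return R_NegInf;
  if (p <= 0.0) return R::pnorm(0.0, pi, sd, 1, 1);
  if (p >= 1.0) return R::pnorm(1.0, pi, sd, 0, 1);
  return R::dnorm(p, pi, sd, 1);
}

// log density of the censoring random-walk proposal b | a with scale s
static inline double lq_censored(double b, double a, double s) {
  if (b <= 0.0) return R::pnorm(0.0, a, s, 1, 1);
  if (b >= 1.0) return R::pnorm(1.0, a, s, 0, 1);
  return R::dnorm(b, a, s, 1);
}

static inline double ll_binom(double x, double n, double p) {
  if (n <= 0.0) return 0.0;
  return R::dbinom(x, n, p, 1);
}

// [[Rcpp::export(name = ".nicholson_mcmc")]]
List nicholson_mcmc(NumericMatrix x, NumericMatrix n,
                    int burn_in, int run_length, double m,
                    double prop_p_sd, double prop_c_sd, double prop_pi_eps) {
  const int K = x.nrow(), L = x.ncol();
  const double PI_EPS = 1e-9;

  // moment initialization
  NumericVector pi(L), cpar(K);
  NumericMatrix P(K, L);
  for (int j = 0; j < L; ++j) {
    double sx = 0.0, sn = 0.0;
    for (int i = 0; i < K; ++i) { sx += x(i, j); sn += n(i, j); }
    pi[j] = (sx + 0.5) / (sn + 1.0);
    for (int i = 0; i < K; ++i)
      P(i, j) = (x(i, j) + 0.5) / (n(i, j) + 1.0);
  }
  for (int i = 0; i < K; ++i) {
    double acc = 0.0; int cnt = 0;
    for (int j = 0; j < L; ++j) {
      double d = P(i, j) - pi[j];
      double v = pi[j] * (1.0 - pi[j]);
      if (v > 0) { acc += d * d / v; ++cnt; }
    }
    double est = cnt ? acc / cnt : 0.05;
    cpar[i] = std::min(std::max(est, 0.005), 0.8);
  }

  std::vector<double> sp(K, prop_p_sd), sc(K, prop_c_sd);
  NumericMatrix c_samples(run_length, K);
  NumericVector acc_p(K), acc_c(K), pi_mean(L);
  double acc_pi = 0.0;
  std::vector<double> win_p(K, 0.0), win_c(K, 0.0);
  long n_p_post = 0, n_c_post = 0, n_pi_post = 0;
  int win = 0;
  const int total = burn_in + run_length;

  RNGScope scope;
  for (int it = 0; it < total; ++it) {
    bool post = it >= burn_in;
    // -- update p_ij, vector-sweep per population
    for (int i = 0; i < K; ++i) {
      for (int j = 0; j < L; ++j) {
        double p0 = P(i, j);
        double p1 = p0 + R::rnorm(0.0, sp[i]);
        if (p1 < 0.0) p1 = 0.0;
        if (p1 > 1.0) p1 = 1.0;
        double lr = lp_censored(p1, pi[j], cpar[i]) - lp_censored(p0, pi[j], cpar[i])
                  + ll_binom(x(i, j), n(i, j), p1) - ll_binom(x(i, j), n(i, j), p0)
                  + lq_censored(p0, p1, sp[i]) - lq_censored(p1, p0, sp[i]);
        if (std::isfinite(lr) && (lr >= 0.0 || std::log(R::runif(0.0, 1.0)) < lr)) {
          P(i, j) = p1;
          win_p[i] += 1.0;
          if (post) acc_p[i] += 1.0;
        }
      }
      if (post) n_p_post += L;
    }
    // -- update pi_j with a Dirichlet(2)-scaled (Beta) proposal, scale m
    for (int j = 0; j < L; ++j) {
      double a = m * pi[j], b = m * (1.0 - pi[j]);
      double pib = R::rbeta(a, b);
      if (pib > PI_EPS && pib < 1.0 - PI_EPS) {
        double lr = R::dbeta(pi[j], m * pib, m * (1.0 - pib), 1)
                  - R::dbeta(pib, a, b, 1);
        for (int i = 0; i < K; ++i)
          lr += lp_censored(P(i, j), pib, cpar[i]) - lp_censored(P(i, j), pi[j], cpar[i]);
        if (std::isfinite(lr) && (lr >= 0.0 || std::log(R::runif(0.0, 1.0)) < lr)) {
          pi[j] = pib;
          if (post) acc_pi += 1.0;
        }
      }
      if (post) ++n_pi_post;
    }
    // -- update c_i by log-scale random walk, uniform(0,1) prior
    for (int i = 0; i < K; ++i) {
      double c1 = cpar[i] * std::exp(R::rnorm(0.0, sc[i]));
      if (c1 > 1e-6 && c1 < 1.0) {
        double lr = std::log(c1) - std::log(cpar[i]);   // log-walk Jacobian
        for (int j = 0; j < L; ++j)
          lr += lp_censored(P(i, j), pi[j], c1) - lp_censored(P(i, j), pi[j], cpar[i]);
        if (std::isfinite(lr) && (lr >= 0.0 || std::log(R::runif(0.0, 1.0)) < lr)) {
          cpar[i] = c1;
          win_c[i] += 1.0;
          if (post) acc_c[i] += 1.0;
        }
      }
      if (post) ++n_c_post;
    }
    // -- adapt proposal scales during burn-in only (frozen afterwards)
    ++win;
    if (!post && win == 100) {
      for (int i = 0; i < K; ++i) {
        double rp = win_p[i] / (100.0 * L), rc = win_c[i] / 100.0;
        if (rp < 0.20) sp[i] *= 0.8; else if (rp > 0.50) sp[i] *= 1.25;
        if (rc < 0.20) sc[i] *= 0.8; else if (rc > 0.50) sc[i] *= 1.25;
        sp[i] = std::min(std::max(sp[i], 1e-4), 0.5);
        sc[i] = std::min(std::max(sc[i], 0.01), 2.0);
        win_p[i] = win_c[i] = 0.0;
      }
      win = 0;
    }
    if (post) {
      for (int i = 0; i < K; ++i) c_samples(it - burn_in, i) = cpar[i];
      for (int j = 0; j < L; ++j) pi_mean[j] += pi[j] / run_length;
    }
  }

  for (int i = 0; i < K; ++i) {
    acc_p[i] = n_p_post ? acc_p[i] / (double)(run_length * L) : NA_REAL;
    acc_c[i] = n_c_post ? acc_c[i] / (double)run_length : NA_REAL;
  }
  return List::create(
    _["c_samples"] = c_samples,
    _["accept_p"] = acc_p,
    _["accept_pi"] = n_pi_post ? acc_pi / (double)n_pi_post : NA_REAL,
    _["accept_c"] = acc_c,
    _["pi_mean"] = pi_mean,
    _["prop_p_sd"] = NumericVector(sp.begin(), sp.end()),
    _["prop_c_sd"] = NumericVector(sc.begin(), sc.end()));
}
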