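#include <Rcpp.h>
using namespace Rcpp;

// Numerically stable log(1 + exp(x)).
static inline double log1p_exp(double x) {
  if (x <= -37.0) return std::exp(x);
  if (x <= 18.0)  return std::log1p(std::exp(x));
  if (x <= 33.3)  return x + std::exp(-x);
  return x;
}

// Bernoulli-logit log mass: y * lp - log(1 + exp(lp)).
static inline double bern_ll(double y, double lp) {
  return y * lp - log1p_exp(lp);
}

struct StepAdapter {
  double step;
  int accepted, tried;
  StepAdapter() : step(0.5), accepted(0), tried(0) {}
  void tick(bool acc) { tried++; if (acc) accepted++; }
  // Adapt toward a 30-45% acceptance window every 50 proposals (burn-in only).
  void adapt() {
    if (tried >= 50) {
      double rate = (double)accepted / tried;
      if (rate > 0.45) step *= std::exp(0.2);
      else if (rate < 0.30) step *= std::exp(-0.2);
      step = std::min(std::max(step, 1e-3), 50.0);
      accepted = 0; tried = 0;
    }
  }
};

// MH-within-Gibbs sampler for the hierarchical logistic toxicity model
// logit p_ik = beta_k + alpha_{Z_ik} * W_i with alpha_1 = 1 fixed and
// alpha_2 sampled only when sample_alpha2 is true (flexible allocation).
// prior_type: 0 = sigma2 ~ Inv-Gamma(eta, eta) (conjugate draw),
//             1 = sigma ~ Half-Cauchy(0, tau) (MH on log sigma).
// use_w = false freezes W at 0 (correlation-free variant); fix_sigma2 >= 0
// holds sigma2 at that value.
// [[Rcpp::export(name = ".gibbs_sampler")]]
List gibbs_sampler(IntegerMatrix y, IntegerMatrix treated, IntegerMatrix ztype,
                   NumericVector mu, double sigma_beta2,
                   int prior_type, double eta, double tau,
                   bool sample_alpha2, double sigma_alpha2,
                   bool use_w, double fix_sigma2,
                   int n_samples, int burnin) {
  const int n = y.nrow(), K = y.ncol();
  // Per-dose and per-patient observation index lists.
  std::vector< std::vector<int> > by_dose(K), by_pat(n);
  std::vector<int> z2_i, z2_k;
  for (int i = 0; i < n; i++) {
    for (int k = 0; k < K; k++) {
      if (treated(i, k) == 1) {
        by_dose[k].push_back(i);
        by_pat[i].push_back(k);
        if (ztype(i, k) == 2) { z2_i.push_back(i); z2_k.push_back(k); }
      }
    }
  }

  std::vector<double> beta(K), W(n, 0.0);
  for (int k = 0; k < K; k++) beta[k] = mu[k];
  double sigma2 = (fix_sigma2 > 0) ? fix_sigma2 : 1.0;
  double alpha2 = 1.0;

  std::vector<StepAdapter> step_beta(K), step_w(n);
  StepAdapter step_a2, step_ls;

  NumericMatrix out_beta(n_samples, K), out_w(n_samples, n);
  NumericVector out_s2(n_samples), out_a2(n_samples);

  const int total = burnin + n_samples;
  for (int it = 0; it < total; it++) {
    const bool warm = it < burnin;

    // beta_k | rest
    for (int k = 0; k < K; k++) {
      double cur = beta[k];
      double prop = cur + step_beta[k].step * R::norm_rand();
      double ll = 0.0;
      for (size_t j = 0; j < by_dose[k].size(); j++) {
        int i = by_dose[k][j];
        double aw = use_w ? ((ztype(i, k) == 2 ? alpha2 : 1.0) * W[i]) : 0.0;
        ll += bern_ll(y(i, k), prop + aw) - bern_ll(y(i, k), cur + aw);
      }
      double lp = -((prop - mu[k]) * (prop - mu[k]) -
                    (cur - mu[k]) * (cur - mu[k])) / (2.0 * sigma_beta2);
      bool acc = std::log(R::unif_rand()) < ll + lp;
      if (acc) beta[k] = prop;
      step_beta[k].tick(acc);
      if (warm) step_beta[k].adapt();
    }

    if (use_w) {
      // W_i | rest
      for (int i = 0; i < n; i++) {
        double cur = W[i];
        double prop = cur + step_w[i].step * R::norm_rand();
        double ll = 0.0;
        for (size_t j = 0; j < by_pat[i].size(); j++) {
          int k = by_pat[i][j];
          double a = (ztype(i, k) == 2) ? alpha2 : 1.0;
          ll += bern_ll(y(i, k), beta[k] + a * prop) -
                bern_ll(y(i, k), beta[k] + a * cur);
        }
        double lp = -(prop * prop - cur * cur) / (2.0 * sigma2);
        bool acc = std::log(R::unif_rand()) < ll + lp;
        if (acc) W[i] = prop;
        step_w[i].tick(acc);
        if (warm) step_w[i].adapt();
      }

      // sigma2 | W
      if (!(fix_sigma2 > 0)) {
        double ss = 0.0;
        for (int i = 0; i < n; i++) ss += W[i] * W[i];
        if (prior_type == 0) {
          // conjugate: Inv-Gamma(eta + n/2, eta + ss/2)
          double shape = eta + 0.5 * n, rate = eta + 0.5 * ss;
          sigma2 = rate / R::rgamma(shape, 1.0);
        } else {
          // Half-Cauchy(0, tau) on sigma; MH on s = log sigma with Jacobian.
          double s_cur = 0.5 * std::log(sigma2);
          double s_prop = s_cur + step_ls.step * R::norm_rand();
          double sg_c = std::exp(s_cur), sg_p = std::exp(s_prop);
          double lt_c = -(n * s_cur + ss / (2.0 * sg_c * sg_c) +
                          std::log(tau * tau + sg_c * sg_c)) + s_cur;
          double lt_p = -(n * s_prop + ss / (2.0 * sg_p * sg_p) +
                          std::log(tau * tau + sg_p * sg_p)) + s_prop;
          bool acc = std::log(R::unif_rand()) < lt_p - lt_c;
          if (acc) sigma2 = sg_p * sg_p;
          step_ls.tick(acc);
          if (warm) step_ls.adapt();
        }
      }

      // alpha2 | rest (down-retreat cells only)
      if (sample_alpha2) {
        double cur = alpha2;
        double prop = cur + step_a2.step * R::norm_rand();
        double ll = 0.0;
        for (size_t j = 0; j < z2_i.size(); j++) {
          int i = z2_i[j], k = z2_k[j];
          ll += bern_ll(y(i, k), beta[k] + prop * W[i]) -
                bern_ll(y(i, k), beta[k] + cur * W[i]);
        }
        double lp = -((prop - 1.0) * (prop - 1.0) -
                      (cur - 1.0) * (cur - 1.0)) / (2.0 * sigma_alpha2);
        bool acc = std::log(R::unif_rand()) < ll + lp;
        if (acc) alpha2 = prop;
        step_a2.tick(acc);
        if (warm) step_a2.adapt();
      }
    }

    if (!warm) {
      int s = it - burnin;
      for (int k = 0; k < K; k++) out_beta(s, k) = beta[k];
      for (int i = 0; i < n; i++) out_w(s, i) = W[i];
      out_s2[s] = sigma2;
      out_a2[s] = alpha2;
    }
  }

  return List::create(_["beta"] = out_beta, _["W"] = out_w,
                      _["sigma2"] = out_s2, _["alpha2"] = out_a2);
}

// MH-within-Gibbs for the two-parameter logistic CRM with patient random
// effects: logit p_ik = b0 + b1 * d_k + W_i, b1 > 0 (sampled on log scale).
// Priors: b0 ~ N(0, v0), log b1 ~ N(0, v1), W_i ~ N(0, sigma2),
// sigma2 ~ Inv-Gamma(eta, eta).
// [[Rcpp::export(name = ".crm_sampler")]]
List crm_sampler(IntegerMatrix y, IntegerMatrix treated, NumericVector d,
                 double v0, double v1, double eta, bool use_w,
                 int n_samples, int burnin) {
  const int n = y.nrow(), K = y.ncol();
  std::vector<int> obs_i, obs_k;
  std::vector< std::vector<int> > by_pat(n);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < K; k++)
      if (treated(i, k) == 1) {
        obs_i.push_back(i); obs_k.push_back(k); by_pat[i].push_back(k);
      }

  double b0 = 0.0, lb1 = 0.0, sigma2 = 1.0;
  std::vector<double> W(n, 0.0);
  StepAdapter st0, st1;
  std::vector<StepAdapter> stw(n);

  NumericVector out_b0(n_samples), out_b1(n_samples), out_s2(n_samples);
  NumericMatrix out_w(n_samples, n);

  const int total = burnin + n_samples;
  for (int it = 0; it < total; it++) {
    const bool warm = it < burnin;
    double b1 = std::exp(lb1);

    // b0
    {
      double prop = b0 + st0.step * R::norm_rand();
      double ll = 0.0;
      for (size_t j = 0; j < obs_i.size(); j++) {
        int i = obs_i[j], k = obs_k[j];
        double base = b1 * d[k] + (use_w ? W[i] : 0.0);
        ll += bern_ll(y(i, k), prop + base) - bern_ll(y(i, k), b0 + base);
      }
      double lp = -(prop * prop - b0 * b0) / (2.0 * v0);
      bool acc = std::log(R::unif_rand()) < ll + lp;
      if (acc) b0 = prop;
      st0.tick(acc);
      if (warm) st0.adapt();
    }

    // log b1
    {
      double prop = lb1 + st1.step * R::norm_rand();
      double b1p = std::exp(prop);
      double ll = 0.0;
      for (size_t j = 0; j < obs_i.size(); j++) {
        int i = obs_i[j], k = obs_k[j];
        double wv = use_w ? W[i] : 0.0;
        ll += bern_ll(y(i, k), b0 + b1p * d[k] + wv) -
              bern_ll(y(i, k), b0 + b1 * d[k] + wv);
      }
      double lp = -(prop * prop - lb1 * lb1) / (2.0 * v1);
      bool acc = std::log(R::unif_rand()) < ll + lp;
      if (acc) { lb1 = prop; b1 = b1p; }
      st1.tick(acc);
      if (warm) st1.adapt();
    }

    if (use_w) {
      for (int i = 0; i < n; i++) {
        double cur = W[i];
        double prop = cur + stw[i].step * R::norm_rand();
        double ll = 0.0;
        for (size_t j = 0; j < by_pat[i].size(); j++) {
          int k = by_pat[i][j];
          ll += bern_ll(y(i, k), b0 + b1 * d[k] + prop) -
                bern_ll(y(i, k), b0 + b1 * d[k] + cur);
        }
        double lp = -(prop * prop - cur * cur) / (2.0 * sigma2);
        bool acc = std::log(R::unif_rand()) < ll + lp;
        if (acc) W[i] = prop;
        stw[i].tick(acc);
        if (warm) stw[i].adapt();
      }
      double ss = 0.0;
      for (int i = 0; i < n; i++) ss += W[i] * W[i];
      sigma2 = (eta + 0.5 * ss) / R::rgamma(eta + 0.5 * n, 1.0);
    }

    if (!warm) {
      int s = it - burnin;
      out_b0[s] = b0;
      out_b1[s] = std::exp(lb1);
      out_s2[s] = sigma2;
      for (int i = 0; i < n; i++) out_w(s, i) = W[i];
    }
  }

  return List::create(_["beta0"] = out_b0, _["beta1"] = out_b1,
                      _["W"] = out_w, _["sigma2"] = out_s2);
}
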