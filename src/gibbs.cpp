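// Gibbs sampler for the weighted Bayesian multi-variant liability (probit)
// regression:
//
//   y_i = mu + sum_j x_ij beta_j + e_i,  e_i ~ N(0, 1)
//   d_i = 1{y_i > 0}                      (observed)
//   beta_j ~ N(0, w_j sigma2)             (shrinkage prior, weight w_j)
//   sigma2 ~ ScaledInvChi2(nu, S2),  p(mu) proportional to 1
//
// Full conditionals (standard conjugacy / data augmentation):
//   (a) y_i | .  ~ N(mu + x_i beta, 1) truncated to (0,Inf) if d_i = 1,
//       (-Inf, 0] if d_i = 0
//   (b) mu  | .  ~ N(mean(y - X beta), 1/n)
//   (c) beta_j|. ~ N( x_j'r / c_j, 1/c_j ),  r = y - mu - X_{-j} beta_{-j},
//       c_j = x_j'x_j + 1/(w_j sigma2)
//   (d) sigma2|. ~ ScaledInvChi2( nu + p, (nu S2 + sum_j beta_j^2/w_j)/(nu+p) )
//
// Uses R's RNG (set.seed() in R gives bit-reproducible chains). Genotype
// columns are stored sparsely (rare-variant matrices are ~97% zeros).

#include <Rcpp.h>
using namespace Rcpp;

// One-sided truncated standard normal: draw u ~ N(0,1) | u > a.
// Plain rejection when the cut is not in the deep tail; Robert's (1995)
// exponential-proposal rejection otherwise (inverse-CDF is inaccurate
// beyond ~6 sigma).
static double rtruncnorm_above(double a) {
  if (a < 0.45) {
    for (;;) {
      double u = norm_rand();
      if (u > a) return u;
    }
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a - std::log(unif_rand()) / alpha;
    double d = x - alpha;
    if (std::log(unif_rand()) <= -0.5 * d * d) return x;
  }
}

// y ~ N(mean, 1) truncated to (0, Inf) if positive, else to (-Inf, 0].
static double draw_liability(double mean, bool positive) {
  if (positive) return mean + rtruncnorm_above(-mean);
  return mean - rtruncnorm_above(mean);
}

// [[Rcpp::export(name = ".gibbs_probit_cpp")]]
List gibbs_probit_cpp(IntegerMatrix X, IntegerVector d, NumericVector w,
                      double nu, double S2,
                      int n_iter, int burn_in, int thin,
                      double mu_init, NumericVector beta_init,
                      double sigma2_init,
                      bool update_mu = true, bool update_beta = true,
                      bool update_sigma2 = true,
                      bool store_chains = false) {
  const int n = X.nrow(), p = X.ncol();
  if (p < 1) stop("need at least one variant");
  if (n < 1) stop("need at least one individual");
  if (burn_in >= n_iter) stop("burn_in must be < n_iter");
  if (thin < 1) stop("thin must be >= 1");

  // sparse column representation
  std::vector<std::vector<int> > idx(p);
  std::vector<std::vector<double> > val(p);
  std::vector<double> xtx(p, 0.0);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      int x = X(i, j);
      if (x != 0) {
        idx[j].push_back(i);
        val[j].push_back((double)x);
        xtx[j] += (double)x * (double)x;
      }
    }
  }

  double mu = mu_init;
  double sigma2 = sigma2_init;
  std::vector<double> beta(p);
  for (int j = 0; j < p; ++j) beta[j] = beta_init[j];

  // eta_i = mu + x_i' beta, maintained incrementally
  std::vector<double> eta(n, mu), y(n);
  for (int j = 0; j < p; ++j)
    for (size_t k = 0; k < idx[j].size(); ++k)
      eta[idx[j][k]] += val[j][k] * beta[j];
  for (int i = 0; i < n; ++i) y[i] = draw_liability(eta[i], d[i] == 1);

  int n_ret = (n_iter - burn_in) / thin;
  std::vector<double> bsum(p, 0.0), bsumsq(p, 0.0);
  double mu_sum = 0.0;
  NumericVector sig_chain(store_chains ? n_ret : 0);
  NumericMatrix beta_chain(store_chains ? n_ret : 0, store_chains ? p : 0);
  int m = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // (a) latent liabilities
    for (int i = 0; i < n; ++i) y[i] = draw_liability(eta[i], d[i] == 1);
    // (b) intercept, flat prior
    if (update_mu) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += y[i] - (eta[i] - mu);
      double mu_new = s / n + norm_rand() / std::sqrt((double)n);
      double shift = mu_new - mu;
      for (int i = 0; i < n; ++i) eta[i] += shift;
      mu = mu_new;
    }
    // (c) effects, ascending variant index
    if (update_beta) {
      for (int j = 0; j < p; ++j) {
        double dot = 0.0;
        const std::vector<int> &ij = idx[j];
        const std::vector<double> &vj = val[j];
        for (size_t k = 0; k < ij.size(); ++k)
          dot += vj[k] * (y[ij[k]] - eta[ij[k]]);
        dot += xtx[j] * beta[j];
        double c = xtx[j] + 1.0 / (w[j] * sigma2);
        double bnew = dot / c + norm_rand() / std::sqrt(c);
        double diff = bnew - beta[j];
        for (size_t k = 0; k < ij.size(); ++k) eta[ij[k]] += vj[k] * diff;
        beta[j] = bnew;
      }
    }
    // (d) prior variance of effects
    if (update_sigma2) {
      double ssq = 0.0;
      for (int j = 0; j < p; ++j) ssq += beta[j] * beta[j] / w[j];
      sigma2 = (nu * S2 + ssq) / Rf_rchisq(nu + p);
    }
    if (!std::isfinite(sigma2) || sigma2 <= 0.0)
      stop("non-finite sampler state at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        bsum[j] += beta[j];
        bsumsq[j] += beta[j] * beta[j];
      }
      mu_sum += mu;
      if (store_chains) {
        sig_chain[m] = sigma2;
        for (int j = 0; j < p; ++j) beta_chain(m, j) = beta[j];
      }
      ++m;
    }
  }

  NumericVector post_mean(p), post_sd(p);
  for (int j = 0; j < p; ++j) {
    double mean = bsum[j] / m;
    post_mean[j] = mean;
    double ss = bsumsq[j] - m * mean * mean;
    post_sd[j] = (m > 1 && ss > 0) ? std::sqrt(ss / (m - 1)) : 0.0;
  }

  List out = List::create(
      _["post_mean"] = post_mean, _["post_sd"] = post_sd,
      _["n_retained"] = m, _["mu_mean"] = mu_sum / std::max(m, 1),
      _["state"] = List::create(_["mu"] = mu, _["beta"] = NumericVector(beta.begin(), beta.end()),
                                _["sigma2"] = sigma2,
                                _["y"] = NumericVector(y.begin(), y.end())));
  if (store_chains) {
    out["sigma2_chain"] = sig_chain;
    out["beta_chain"] = beta_chain;
  }
  return out;
}
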