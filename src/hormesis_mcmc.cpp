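// Adaptive Metropolis-within-Gibbs sampler for the binomial logit model
//   y_i ~ Binomial(n_i, p_i),  logit(p_i) = x_i' beta + u_{tank(i)}
//   u_t ~ Normal(0, sigma^2),  sigma ~ half-Normal(0, s0)
//
// Non-centered parameterization (u = sigma * z, z_t ~ N(0,1)) to avoid the
// funnel between the tank effects and their scale. Blocks: beta (joint
// random walk, Haario covariance adaptation during warmup), z (independent
// per-tank random walks, shared adapted scale; valid as a block because the
// likelihood factorises over tanks given beta), log(sigma) (scalar random
// walk over the whole-likelihood conditional). Adaptation stops at the end
// of warmup so the retained chain is a fixed-kernel Markov chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log1pexp (stable log(1 + exp(x))) comes from Rmath

static double loglik_eta(const arma::vec& y, const arma::vec& n,
                         const arma::vec& eta) {
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    ll += y[i] * eta[i] - n[i] * log1pexp(eta[i]);
  return ll;
}

// [[Rcpp::export]]
List hormesis_chain_cpp(const arma::vec& y, const arma::vec& n,
                        const arma::mat& X, const arma::ivec& tank,
                        int n_tank,
                        const arma::vec& prior_mean,
                        const arma::mat& prior_prec,
                        double sigma_prior_sd,
                        int warmup, int iter,
                        const arma::vec& beta_init, double sigma_init,
                        bool include_ranef,
                        const arma::mat& ridge_dirs,
                        const arma::mat& ridge_tankw) {
  const int N = y.n_elem, K = X.n_cols, T = n_tank;
  const int total = warmup + iter;

  arma::vec beta = beta_init;
  arma::vec z(T, arma::fill::zeros);
  double logsig = std::log(sigma_init);

  std::vector<std::vector<int>> tobs(T);
  for (int i = 0; i < N; ++i) tobs[tank[i]].push_back(i);

  arma::vec Xb = X * beta;
  arma::vec eta = Xb;
  double sig = include_ranef ? std::exp(logsig) : 0.0;
  if (include_ranef) for (int i = 0; i < N; ++i) eta[i] += sig * z[tank[i]];
  double ll = loglik_eta(y, n, eta);

  // adaptation state
  double ls_beta = std::log(0.1), ls_z = std::log(0.8), ls_sig = std::log(0.5);
  double ls_sig2 = std::log(0.5);
  const int J = ridge_dirs.n_cols;
  arma::vec ls_ridge(J, arma::fill::value(std::log(0.1)));
  arma::vec mu_run = beta;
  arma::mat cov_run = arma::eye(K, K) * 0.01;
  arma::mat prop_chol = arma::chol(cov_run, "lower");

  arma::mat beta_out(iter, K);
  arma::vec sigma_out(iter);
  arma::mat u_out(iter, T);
  arma::mat loglik_out(iter, N); // full pointwise log density
  double acc_beta = 0.0;

  arma::vec lchoose_const(N);
  for (int i = 0; i < N; ++i)
    lchoose_const[i] = R::lchoose(n[i], y[i]);

  for (int it = 0; it < total; ++it) {
    bool adapting = it < warmup;
    double gain = 1.0 / std::pow(it + 2.0, 0.6);

    // ---- beta block ----
    {
      arma::vec zp(K);
      for (int k = 0; k < K; ++k) zp[k] = R::norm_rand();
      arma::vec prop = beta + std::exp(ls_beta) * (prop_chol * zp);
      arma::vec Xb_p = X * prop;
      arma::vec eta_p = eta + (Xb_p - Xb);
      double ll_p = loglik_eta(y, n, eta_p);
      arma::vec d0 = beta - prior_mean, d1 = prop - prior_mean;
      double lpr = 0.5 * (arma::as_scalar(d0.t() * prior_prec * d0)
                          - arma::as_scalar(d1.t() * prior_prec * d1));
      bool acc = std::log(R::unif_rand()) < ll_p - ll + lpr;
      if (acc) { beta = prop; Xb = Xb_p; eta = eta_p; ll = ll_p; }
      if (adapting) {
        ls_beta += gain * ((acc ? 1.0 : 0.0) - 0.30);
        arma::vec d = beta - mu_run;
        mu_run += gain * d;
        cov_run = (1.0 - gain) * cov_run + gain * (d * d.t());
        if (it > 20 && it % 20 == 0)
          prop_chol = arma::chol(cov_run + arma::eye(K, K) * 1e-8, "lower");
      } else {
        acc_beta += acc ? 1.0 : 0.0;
      }
    }

    if (include_ranef) {
      // ---- z block (per tank, conditionally independent) ----
      double step = std::exp(ls_z);
      double acc_mean = 0.0;
      for (int t = 0; t < T; ++t) {
        double zpv = z[t] + step * R::norm_rand();
        double dll = 0.0;
        for (int idx : tobs[t]) {
          double e0 = eta[idx], e1 = e0 + sig * (zpv - z[t]);
          dll += y[idx] * (e1 - e0) - n[idx] * (log1pexp(e1) - log1pexp(e0));
        }
        double dpr = 0.5 * (z[t] * z[t] - zpv * zpv);
        if (std::log(R::unif_rand()) < dll + dpr) {
          for (int idx : tobs[t]) eta[idx] += sig * (zpv - z[t]);
          ll += dll;
          z[t] = zpv;
          acc_mean += 1.0;
        }
      }
      if (adapting) ls_z += gain * (acc_mean / T - 0.44);

      // ---- log(sigma): changes the whole linear predictor ----
      double lsp = logsig + std::exp(ls_sig) * R::norm_rand();
      double sig_p = std::exp(lsp);
      arma::vec eta_p = Xb;
      for (int i = 0; i < N; ++i) eta_p[i] += sig_p * z[tank[i]];
      double ll_p = loglik_eta(y, n, eta_p);
      // half-normal prior on sigma plus Jacobian of the log transform
      double lp0 = -0.5 * sig * sig / (sigma_prior_sd * sigma_prior_sd)
        + logsig;
      double lp1 = -0.5 * sig_p * sig_p / (sigma_prior_sd * sigma_prior_sd)
        + lsp;
      bool acc = std::log(R::unif_rand()) < ll_p - ll + lp1 - lp0;
      if (acc) { logsig = lsp; sig = sig_p; eta = eta_p; ll = ll_p; }
      if (adapting) ls_sig += gain * ((acc ? 1.0 : 0.0) - 0.44);

      // ---- sigma/z rescaling (u = sigma z held fixed) ----
      // complements the sigma move above: scale sigma while rescaling z
      // so the likelihood is untouched; Jacobian of z' = z e^{ls-ls'} is
      // e^{T (ls - ls')}
      {
        double lsp = logsig + std::exp(ls_sig2) * R::norm_rand();
        double sig_p = std::exp(lsp);
        double scale = std::exp(logsig - lsp);
        double zss = arma::dot(z, z);
        double lpr = 0.5 * zss * (1.0 - scale * scale)
          - 0.5 * (sig_p * sig_p - sig * sig) /
              (sigma_prior_sd * sigma_prior_sd)
          + (lsp - logsig) + T * (logsig - lsp);
        bool acc2 = std::log(R::unif_rand()) < lpr;
        if (acc2) { z *= scale; logsig = lsp; sig = sig_p; }
        if (adapting) ls_sig2 += gain * ((acc2 ? 1.0 : 0.0) - 0.44);
      }

      // ---- translations along the fixed-effect/random-effect ridges ----
      // every covariate is constant within a tank, so for each direction
      // d with per-tank values w the update beta += delta d,
      // z_t -= delta w_t / sigma leaves the likelihood unchanged; only
      // the priors enter the ratio. These moves traverse the subspace in
      // which systematic lack of fit trades off against the tank effects.
      {
        bool any_acc = false;
        for (int j = 0; j < J; ++j) {
          double delta = std::exp(ls_ridge[j]) * R::norm_rand();
          arma::vec bp = beta + delta * ridge_dirs.col(j);
          arma::vec d0 = beta - prior_mean, d1 = bp - prior_mean;
          double lpr = 0.5 * (arma::as_scalar(d0.t() * prior_prec * d0)
                              - arma::as_scalar(d1.t() * prior_prec * d1));
          arma::vec z1 = z - (delta / sig) * ridge_tankw.col(j);
          lpr += 0.5 * (arma::dot(z, z) - arma::dot(z1, z1));
          bool acc = std::log(R::unif_rand()) < lpr;
          if (acc) { beta = bp; z = z1; any_acc = true; }
          if (adapting) ls_ridge[j] += gain * ((acc ? 1.0 : 0.0) - 0.44);
        }
        if (any_acc) Xb = X * beta;
      }
    }

    if (!adapting) {
      int j = it - warmup;
      beta_out.row(j) = beta.t();
      sigma_out[j] = include_ranef ? sig : 0.0;
      u_out.row(j) = (sig * z).t();
      for (int i = 0; i < N; ++i) {
        double e = eta[i];
        loglik_out(j, i) = lchoose_const[i] + y[i] * e - n[i] * log1pexp(e);
      }
    }
  }

  return List::create(
    _["beta"] = beta_out, _["sigma"] = sigma_out, _["u"] = u_out,
    _["loglik"] = loglik_out, _["accept_beta"] = acc_beta / iter);
}
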