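// MCMC cores for the single-isotope mixing model and the path model.
// Both use R's RNG so that set.seed() in R makes draws reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// softmax of (z_1..z_{K-1}, 0)
static arma::vec softmax_p(const arma::vec& z) {
  arma::vec full(z.n_elem + 1);
  full.head(z.n_elem) = z;
  full(z.n_elem) = 0.0;
  full -= full.max();
  arma::vec e = arma::exp(full);
  return e / arma::accu(e);
}

// log posterior (up to a constant) for one feather sample:
// delta ~ N(p'(mu + D), p'^2 (sd^2 + sdD^2) + sigma^2), p ~ Dirichlet(1),
// sigma ~ half-Normal(0, prior_scale); parameterized by (z, log sigma)
static double mix_logpost(const arma::vec& z, double logsig, double delta,
                          const arma::vec& mu_adj, const arma::vec& var_src,
                          double prior_scale) {
  arma::vec p = softmax_p(z);
  double sig = std::exp(logsig);
  double m = arma::dot(p, mu_adj);
  double v = arma::dot(p % p, var_src) + sig * sig;
  double ll = -0.5 * std::log(2.0 * M_PI * v) - (delta - m) * (delta - m) / (2.0 * v);
  // flat Dirichlet on the simplex => logistic-normal Jacobian sum(log p)
  double lp = arma::accu(arma::log(p + 1e-300));
  lp += -sig * sig / (2.0 * prior_scale * prior_scale) + logsig; // half-normal + Jacobian
  return ll + lp;
}

// [[Rcpp::export]]
List mixing_sampler_cpp(double delta, const arma::vec& mu_adj,
                        const arma::vec& var_src, double prior_sigma_scale,
                        int chains, int iter, int burnin) {
  int K = mu_adj.n_elem;
  int d = K - 1;
  int keep_per = iter - burnin;
  arma::mat p_draws(keep_per * chains, K);
  arma::vec sig_draws(keep_per * chains);
  arma::ivec chain_id(keep_per * chains);
  double n_acc = 0.0, n_try = 0.0;

  for (int c = 0; c < chains; ++c) {
    arma::vec z(d, arma::fill::zeros);
    for (int j = 0; j < d; ++j) z(j) = R::rnorm(0.0, 1.0);
    double logsig = std::log(0.5) + R::rnorm(0.0, 0.3);
    double step = 0.6;
    double lp = mix_logpost(z, logsig, delta, mu_adj, var_src, prior_sigma_scale);
    int acc_win = 0;
    for (int it = 0; it < iter; ++it) {
      arma::vec zp = z;
      for (int j = 0; j < d; ++j) zp(j) += R::rnorm(0.0, step);
      double lsp = logsig + R::rnorm(0.0, step * 0.5);
      double lpp = mix_logpost(zp, lsp, delta, mu_adj, var_src, prior_sigma_scale);
      bool accept = std::log(R::runif(0.0, 1.0)) < lpp - lp;
      if (accept) { z = zp; logsig = lsp; lp = lpp; ++acc_win; }
      // adapt the proposal scale only during burn-in
      if (it < burnin && (it + 1) % 50 == 0) {
        double rate = acc_win / 50.0;
        step *= std::exp((rate - 0.25) * 0.5);
        if (step < 1e-3) step = 1e-3;
        if (step > 5.0) step = 5.0;
        acc_win = 0;
      }
      if (it >= burnin) {
        int row = c * keep_per + (it - burnin);
        p_draws.row(row) = softmax_p(z).t();
        sig_draws(row) = std::exp(logsig);
        chain_id(row) = c + 1;
        n_try += 1.0;
        if (accept) n_acc += 1.0;
      }
    }
  }
  return List::create(_["p"] = p_draws, _["sigma"] = sig_draws,
                      _["chain"] = chain_id, _["accept_rate"] = n_acc / n_try);
}

// Gibbs sampler for a system of independent Bayesian linear regressions
// (the recursive path model factorizes into its equations given observed
// upstream variables). beta | sigma is conjugate normal under
// beta ~ N(0, b_sd^2 I); sigma gets a Metropolis step on log sigma with a
// half-Normal(0, sigma_scale) prior.
// [[Rcpp::export]]
List sem_gibbs_cpp(const List& X_list, const List& y_list, double b_prior_sd,
                   double sigma_prior_scale, int chains, int iter, int burnin) {
  int n_eq = X_list.size();
  int keep_per = iter - burnin;
  List out(n_eq);
  arma::ivec chain_id(keep_per * chains);

  for (int e = 0; e < n_eq; ++e) {
    arma::mat X = as<arma::mat>(X_list[e]);
    arma::vec y = as<arma::vec>(y_list[e]);
    int p = X.n_cols, n = X.n_rows;
    arma::mat XtX = X.t() * X;
    arma::vec Xty = X.t() * y;
    arma::mat prior_prec = arma::eye(p, p) / (b_prior_sd * b_prior_sd);
    arma::mat draws(keep_per * chains, p + 1);

    for (int c = 0; c < chains; ++c) {
      arma::vec beta = arma::solve(XtX + prior_prec, Xty);
      for (int j = 0; j < p; ++j) beta(j) += R::rnorm(0.0, 0.1);
      arma::vec r = y - X * beta;
      double sig = std::sqrt(arma::dot(r, r) / n + 1e-12);
      double logsig = std::log(sig);
      double step = 0.3;
      int acc_win = 0;
      for (int it = 0; it < iter; ++it) {
        // beta | sigma
        double s2 = std::exp(2.0 * logsig);
        arma::mat prec = XtX / s2 + prior_prec;
        arma::mat L = arma::chol(prec, "lower");
        arma::vec mu = arma::solve(arma::trimatu(L.t()),
                                   arma::solve(arma::trimatl(L), Xty / s2));
        arma::vec zr(p);
        for (int j = 0; j < p; ++j) zr(j) = R::rnorm(0.0, 1.0);
        beta = mu + arma::solve(arma::trimatu(L.t()), zr);
        // sigma | beta (log-scale Metropolis, half-normal prior)
        r = y - X * beta;
        double rss = arma::dot(r, r);
        double lsig_p = logsig + R::rnorm(0.0, step);
        double s = std::exp(logsig), sp = std::exp(lsig_p);
        double lp_cur = -n * logsig - rss / (2.0 * s * s)
          - s * s / (2.0 * sigma_prior_scale * sigma_prior_scale) + logsig;
        double lp_prop = -n * lsig_p - rss / (2.0 * sp * sp)
          - sp * sp / (2.0 * sigma_prior_scale * sigma_prior_scale) + lsig_p;
        if (std::log(R::runif(0.0, 1.0)) < lp_prop - lp_cur) {
          logsig = lsig_p; ++acc_win;
        }
        if (it < burnin && (it + 1) % 50 == 0) {
          double rate = acc_win / 50.0;
          step *= std::exp((rate - 0.4) * 0.5);
          if (step < 1e-3) step = 1e-3;
          if (step > 3.0) step = 3.0;
          acc_win = 0;
        }
        if (it >= burnin) {
          int row = c * keep_per + (it - burnin);
          draws.submat(row, 0, row, p - 1) = beta.t();
          draws(row, p) = std::exp(logsig);
          if (e == 0) chain_id(row) = c + 1;
        }
      }
    }
    out[e] = draws;
  }
  return List::create(_["draws"] = out, _["chain"] = chain_id);
}
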