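// MCMC core for the random-effects network meta-analysis model.
//
// Two likelihood modes share one parameterization:
//   mode 0 (normal):   per-study blocks of anchor-based contrasts
//                      y_i ~ MVN(delta_i, S_i), S_i fixed (passed inverted);
//   mode 1 (binomial): per-study arms r_ik ~ Bin(n_ik, expit(mu_i + delta_ik)),
//                      delta on the anchor arm identically 0.
// Random effects: delta_i ~ MVN(X_i * theta, tau^2 * P_m) where P_m has unit
// diagonal and 0.5 off-diagonal (multi-arm consistency correlation), so
// P_m^{-1} = 2 (I - J/(m+1)).  theta holds the effect parameters (basic
// parameters d, or per-edge means, or a node-split direct effect) with
// N(0, prior_sd^2) priors; tau has a Uniform(lo, hi) prior on the SD scale
// or is fixed.  Conjugate updates are Gibbs (delta and theta in normal mode,
// theta given delta in binomial mode); the rest is adaptive random-walk
// Metropolis with proposal scales frozen at the end of burn-in.
//
// Uses R's RNG throughout so a set.seed() call in R fixes the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat pinv_m(int m) {
  arma::mat P(m, m);
  P.fill(-2.0 / (m + 1.0));
  P.diag() += 2.0;
  return P;
}

static inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static double binom_loglik(double r, double n, double eta) {
  double p = expit(eta);
  // guard against p underflow with extreme proposals
  p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
  return r * std::log(p) + (n - r) * std::log(1.0 - p);
}

static double binom_resid_dev(double r, double n, double eta) {
  double p = expit(eta);
  p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
  double dev = 0.0;
  if (r > 0) dev += r * std::log(r / (n * p));
  if (r < n) dev += (n - r) * std::log((n - r) / (n - n * p));
  return 2.0 * dev;
}

struct Adapt {
  double s;
  int acc, tries;
  Adapt() : s(0.5), acc(0), tries(0) {}
  void tally(bool a) { tries++; if (a) acc++; }
  void maybe_adapt() {
    if (tries >= 50) {
      double rate = (double)acc / tries;
      s *= (rate > 0.44) ? 1.15 : 0.87;
      s = std::min(std::max(s, 1e-4), 50.0);
      acc = 0; tries = 0;
    }
  }
};

// [[Rcpp::export(name = ".nma_chain_cpp")]]
List nma_chain_cpp(List dat, List control) {
  RNGScope scope;

  const int mode = as<int>(dat["mode"]);           // 0 normal, 1 binomial
  const int p = as<int>(dat["p"]);
  const double prior_sd = as<double>(dat["prior_sd"]);
  const double prior_prec = 1.0 / (prior_sd * prior_sd);
  const bool tau_is_fixed = as<bool>(dat["tau_is_fixed"]);
  const double tau_fixed = as<double>(dat["tau_fixed"]);
  const double tau_lo = as<double>(dat["tau_lower"]);
  const double tau_hi = as<double>(dat["tau_upper"]);

  List blocks = dat["blocks"];
  const int nb = blocks.size();

  std::vector<arma::vec> y(nb), rr(nb), nn(nb);
  std::vector<arma::mat> Sinv(nb), X(nb), Pinv(nb);
  std::vector<int> m(nb);
  for (int i = 0; i < nb; i++) {
    List b = blocks[i];
    X[i] = as<arma::mat>(b["X"]);
    m[i] = X[i].n_rows;
    Pinv[i] = pinv_m(m[i]);
    if (mode == 0) {
      y[i] = as<arma::vec>(b["y"]);
      Sinv[i] = as<arma::mat>(b["Sinv"]);
    } else {
      rr[i] = as<arma::vec>(b["r"]);   // arms: anchor first
      nn[i] = as<arma::vec>(b["n"]);
    }
  }

  const int n_burn = as<int>(control["burn_in"]);
  const int n_keep = as<int>(control["samples"]);
  const int thin = as<int>(control["thin"]);
  const int n_iter = n_burn + n_keep * thin;

  arma::vec theta = as<arma::vec>(control["theta_init"]);
  double tau = tau_is_fixed ? tau_fixed : as<double>(control["tau_init"]);
  const bool tau0 = tau_is_fixed && tau_fixed < 1e-12;

  std::vector<arma::vec> delta(nb);
  arma::vec mu(nb, arma::fill::zeros);
  if (mode == 1) mu = as<arma::vec>(control["mu_init"]);
  for (int i = 0; i < nb; i++) delta[i] = X[i] * theta;

  // adaptive proposal scales
  Adapt ad_tau;
  std::vector<Adapt> ad_mu(nb), ad_theta(p);
  std::vector<std::vector<Adapt>> ad_delta(nb);
  for (int i = 0; i < nb; i++) ad_delta[i].assign(m[i], Adapt());
  ad_tau.s = 0.2;

  arma::mat theta_out(n_keep, p);
  arma::vec tau_out(n_keep), dev_out(n_keep);
  std::vector<arma::vec> delta_sum(nb);
  for (int i = 0; i < nb; i++) delta_sum[i] = arma::zeros(m[i]);
  arma::vec mu_sum(nb, arma::fill::zeros);

  int kept = 0;
  for (int it = 0; it < n_iter; it++) {
    const bool burning = it < n_burn;
    const double tau2 = tau * tau;

    // ---- delta updates ----
    if (!tau0) {
      for (int i = 0; i < nb; i++) {
        arma::vec mean_re = X[i] * theta;
        arma::mat Q = Pinv[i] / tau2;
        if (mode == 0) {
          // conjugate MVN
          arma::mat prec = Sinv[i] + Q;
          arma::vec bvec = Sinv[i] * y[i] + Q * mean_re;
          arma::mat U = arma::chol(prec);               // upper: U'U = prec
          arma::vec meanv = arma::solve(prec, bvec);
          arma::vec z(m[i]);
          for (int j = 0; j < m[i]; j++) z(j) = R::norm_rand();
          delta[i] = meanv + arma::solve(arma::trimatu(U), z);
        } else {
          for (int j = 0; j < m[i]; j++) {
            double cur = delta[i](j);
            double prop = cur + ad_delta[i][j].s * R::norm_rand();
            arma::vec r0 = delta[i] - mean_re;
            double lp0 = -0.5 * arma::as_scalar(r0.t() * Q * r0) +
              binom_loglik(rr[i](j + 1), nn[i](j + 1), mu(i) + cur);
            arma::vec d1 = delta[i]; d1(j) = prop;
            arma::vec r1 = d1 - mean_re;
            double lp1 = -0.5 * arma::as_scalar(r1.t() * Q * r1) +
              binom_loglik(rr[i](j + 1), nn[i](j + 1), mu(i) + prop);
            bool acc = std::log(R::unif_rand()) < lp1 - lp0;
            if (acc) delta[i](j) = prop;
            ad_delta[i][j].tally(acc);
            if (burning) ad_delta[i][j].maybe_adapt();
          }
        }
      }
    } else {
      for (int i = 0; i < nb; i++) delta[i] = X[i] * theta;
    }

    // ---- mu updates (binomial) ----
    if (mode == 1) {
      for (int i = 0; i < nb; i++) {
        double cur = mu(i);
        double prop = cur + ad_mu[i].s * R::norm_rand();
        double lp0 = -0.5 * prior_prec * cur * cur +
          binom_loglik(rr[i](0), nn[i](0), cur);
        double lp1 = -0.5 * prior_prec * prop * prop +
          binom_loglik(rr[i](0), nn[i](0), prop);
        for (int j = 0; j < m[i]; j++) {
          lp0 += binom_loglik(rr[i](j + 1), nn[i](j + 1), cur + delta[i](j));
          lp1 += binom_loglik(rr[i](j + 1), nn[i](j + 1), prop + delta[i](j));
        }
        bool acc = std::log(R::unif_rand()) < lp1 - lp0;
        if (acc) mu(i) = prop;
        ad_mu[i].tally(acc);
        if (burning) ad_mu[i].maybe_adapt();
      }
    }

    // ---- theta updates ----
    if (!tau0) {
      // conjugate given delta (RE prior is normal in theta)
      for (int j = 0; j < p; j++) {
        double A = prior_prec, b = 0.0;
        for (int i = 0; i < nb; i++) {
          arma::vec xj = X[i].col(j);
          if (arma::norm(xj, 1) == 0) continue;
          arma::mat Q = Pinv[i] / tau2;
          arma::vec v = Q * (delta[i] - X[i] * theta);
          double aij = arma::as_scalar(xj.t() * Q * xj);
          A += aij;
          b += arma::as_scalar(xj.t() * v) + aij * theta(j);
        }
        theta(j) = b / A + R::norm_rand() / std::sqrt(A);
      }
    } else if (mode == 0) {
      // tau fixed at 0: theta conjugate against the likelihood directly
      for (int j = 0; j < p; j++) {
        double A = prior_prec, b = 0.0;
        for (int i = 0; i < nb; i++) {
          arma::vec xj = X[i].col(j);
          if (arma::norm(xj, 1) == 0) continue;
          arma::vec v = Sinv[i] * (y[i] - X[i] * theta);
          double aij = arma::as_scalar(xj.t() * Sinv[i] * xj);
          A += aij;
          b += arma::as_scalar(xj.t() * v) + aij * theta(j);
        }
        theta(j) = b / A + R::norm_rand() / std::sqrt(A);
      }
      for (int i = 0; i < nb; i++) delta[i] = X[i] * theta;
    } else {
      // tau fixed at 0, binomial: random-walk on theta_j
      for (int j = 0; j < p; j++) {
        double cur = theta(j);
        double prop = cur + ad_theta[j].s * R::norm_rand();
        double lp0 = -0.5 * prior_prec * cur * cur;
        double lp1 = -0.5 * prior_prec * prop * prop;
        for (int i = 0; i < nb; i++) {
          arma::vec xj = X[i].col(j);
          if (arma::norm(xj, 1) == 0) continue;
          arma::vec th1 = theta; th1(j) = prop;
          arma::vec d0 = X[i] * theta, d1 = X[i] * th1;
          for (int a = 0; a < m[i]; a++) {
            lp0 += binom_loglik(rr[i](a + 1), nn[i](a + 1), mu(i) + d0(a));
            lp1 += binom_loglik(rr[i](a + 1), nn[i](a + 1), mu(i) + d1(a));
          }
        }
        bool acc = std::log(R::unif_rand()) < lp1 - lp0;
        if (acc) theta(j) = prop;
        ad_theta[j].tally(acc);
        if (burning) ad_theta[j].maybe_adapt();
      }
      for (int i = 0; i < nb; i++) delta[i] = X[i] * theta;
    }

    // ---- tau update ----
    if (!tau_is_fixed) {
      double K = 0.0, SS = 0.0;
      for (int i = 0; i < nb; i++) {
        arma::vec r0 = delta[i] - X[i] * theta;
        SS += arma::as_scalar(r0.t() * Pinv[i] * r0);
        K += m[i];
      }
      double cur = tau;
      double prop = cur + ad_tau.s * R::norm_rand();
      bool acc = false;
      if (prop > tau_lo && prop < tau_hi) {
        double lp0 = -K * std::log(cur) - SS / (2.0 * cur * cur);
        double lp1 = -K * std::log(prop) - SS / (2.0 * prop * prop);
        acc = std::log(R::unif_rand()) < lp1 - lp0;
      }
      if (acc) tau = prop;
      ad_tau.tally(acc);
      if (burning) ad_tau.maybe_adapt();
    }

    // ---- record ----
    if (!burning && ((it - n_burn) % thin == 0) && kept < n_keep) {
      double dev = 0.0;
      for (int i = 0; i < nb; i++) {
        if (mode == 0) {
          arma::vec r0 = y[i] - delta[i];
          dev += arma::as_scalar(r0.t() * Sinv[i] * r0);
        } else {
          dev += binom_resid_dev(rr[i](0), nn[i](0), mu(i));
          for (int j = 0; j < m[i]; j++) {
            dev += binom_resid_dev(rr[i](j + 1), nn[i](j + 1),
                                   mu(i) + delta[i](j));
          }
        }
      }
      theta_out.row(kept) = theta.t();
      tau_out(kept) = tau;
      dev_out(kept) = dev;
      for (int i = 0; i < nb; i++) delta_sum[i] += delta[i];
      mu_sum += mu;
      kept++;
    }
  }

  // deviance at posterior means (for pD = Dbar - Dhat)
  double dhat = 0.0;
  for (int i = 0; i < nb; i++) {
    arma::vec dbar = delta_sum[i] / std::max(kept, 1);
    if (mode == 0) {
      arma::vec r0 = y[i] - dbar;
      dhat += arma::as_scalar(r0.t() * Sinv[i] * r0);
    } else {
      double mubar = mu_sum(i) / std::max(kept, 1);
      dhat += binom_resid_dev(rr[i](0), nn[i](0), mubar);
      for (int j = 0; j < m[i]; j++) {
        dhat += binom_resid_dev(rr[i](j + 1), nn[i](j + 1), mubar + dbar(j));
      }
    }
  }

  List dmeans(nb);
  for (int i = 0; i < nb; i++) {
    dmeans[i] = NumericVector(delta_sum[i].begin(), delta_sum[i].end());
  }
  return List::create(
    _["theta"] = theta_out,
    _["tau"] = tau_out,
    _["deviance"] = dev_out,
    _["dhat"] = dhat,
    _["delta_sum"] = dmeans,
    _["mu_mean"] = NumericVector(mu_sum.begin(), mu_sum.end()),
    _["kept"] = kept
  );
}
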