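// Metropolis-within-Gibbs sampler for the phylogenetically controlled
// Poisson mixed model with additive overdispersion:
//
//   y_i ~ Poisson(exp(eta_i)),   eta = X beta + a + e
//   a = sigma_p * L u,  u ~ N(0, I)   (non-centered; L = chol of A)
//   e_i ~ N(0, sigma2_e)
//   beta_j ~ N(0, beta_prior_var);  variances ~ inverse-gamma(shape, rate)
//
// Updates: adaptive multivariate random-walk block for beta (target ~0.23
// acceptance), univariate adaptive random walks for u_i and e_i (target
// ~0.44), conjugate inverse-gamma Gibbs draw for sigma2_e given e, and an
// ancillarity-sufficiency interweaving (centered-parameterization) draw
// for sigma2_phylo given a, after which u is rescaled so a is unchanged.
// Uses R's RNG so results are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  // X ~ Gamma(shape, rate) => 1/X ~ InvGamma(shape, rate)
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0) g = 1e-300;
  return 1.0 / g;
}

// [[Rcpp::export]]
List sampler_cpp(const arma::vec& y,
                 const arma::mat& X,
                 const arma::mat& L,
                 int n_iter, int burnin, int thin,
                 double beta_prior_var,
                 double ig_shape, double ig_rate,
                 double fix_s2p, double fix_s2e,   // < 0 means "sample"
                 bool use_likelihood,
                 const arma::vec& beta_init,
                 double s2p_init, double s2e_init) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const bool sample_s2p = fix_s2p < 0;
  const bool sample_s2e = fix_s2e < 0;
  double s2p = sample_s2p ? s2p_init : fix_s2p;
  double s2e = sample_s2e ? s2e_init : fix_s2e;
  const bool use_phylo = sample_s2p || fix_s2p > 0;
  const bool use_od    = sample_s2e || fix_s2e > 0;

  arma::vec beta = beta_init;
  arma::vec u(n, arma::fill::zeros);
  arma::vec e(n, arma::fill::zeros);
  double sp = std::sqrt(s2p);

  arma::vec eta = X * beta;            // + sp*L*u + e, both zero at init
  arma::vec exp_eta = arma::exp(eta);

  // adaptation state
  arma::vec ls_u(n, arma::fill::value(std::log(0.5)));
  arma::vec ls_e(n, arma::fill::value(std::log(0.5)));
  double ls_beta = std::log(0.1);
  arma::vec beta_mean = beta;
  arma::mat beta_cov = arma::eye(p, p) * 0.01;
  arma::mat prop_chol = arma::chol(beta_cov, "lower");

  const int n_keep = (n_iter - burnin) / thin;
  arma::mat beta_out(n_keep, p);
  arma::vec s2p_out(n_keep), s2e_out(n_keep);
  long acc_beta = 0, try_beta = 0, acc_u = 0, try_u = 0, acc_e = 0, try_e = 0;
  int keep = 0;
  bool divergent = false;
  int divergent_iter = -1;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const double gam = 1.0 / std::pow(1.0 + iter, 0.6);

    // ---- beta block update -------------------------------------------
    {
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
      arma::vec db = std::exp(ls_beta) * (prop_chol * z);
      arma::vec deta = X * db;
      double dll = 0.0;
      if (use_likelihood) {
        for (int i = 0; i < n; ++i) {
          double en = eta(i) + deta(i);
          dll += y(i) * deta(i) - (std::exp(en) - exp_eta(i));
        }
      }
      for (int j = 0; j < p; ++j) {
        double bn = beta(j) + db(j);
        dll += -0.5 * (bn * bn - beta(j) * beta(j)) / beta_prior_var;
      }
      double alpha = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
      ++try_beta;
      if (R::unif_rand() < alpha) {
        ++acc_beta;
        beta += db;
        eta += deta;
        exp_eta = arma::exp(eta);
      }
      if (iter <= burnin) {
        ls_beta += gam * (alpha - 0.23);
        // Haario-style running covariance of the beta chain
        arma::vec d = beta - beta_mean;
        beta_mean += d / std::min(iter, 1000);
        beta_cov = beta_cov * (1.0 - gam) + gam * (d * d.t());
        if (iter % 50 == 0) {
          arma::mat C = beta_cov + arma::eye(p, p) * 1e-8;
          arma::mat Ltry;
          if (arma::chol(Ltry, C, "lower")) prop_chol = Ltry;
        }
      }
    }

    // ---- phylogenetic effects (whitened u_i) -------------------------
    if (use_phylo && sp > 0) {
      for (int i = 0; i < n; ++i) {
        double du = std::exp(ls_u(i)) * R::norm_rand();
        double dll = -0.5 * ((u(i) + du) * (u(i) + du) - u(i) * u(i));
        if (use_likelihood) {
          for (int j = i; j < n; ++j) {
            double d = sp * L(j, i) * du;
            if (d != 0.0) {
              double en = eta(j) + d;
              dll += y(j) * d - (std::exp(en) - exp_eta(j));
            }
          }
        }
        double alpha = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
        ++try_u;
        if (R::unif_rand() < alpha) {
          ++acc_u;
          u(i) += du;
          for (int j = i; j < n; ++j) {
            double d = sp * L(j, i) * du;
            if (d != 0.0) {
              eta(j) += d;
              exp_eta(j) = std::exp(eta(j));
            }
          }
        }
        if (iter <= burnin) ls_u(i) += gam * (alpha - 0.44);
      }
    }

    // ---- overdispersion effects e_i ----------------------------------
    if (use_od && s2e > 0) {
      for (int i = 0; i < n; ++i) {
        double de = std::exp(ls_e(i)) * R::norm_rand();
        double en = e(i) + de;
        double dll = -0.5 * (en * en - e(i) * e(i)) / s2e;
        if (use_likelihood) {
          double etn = eta(i) + de;
          dll += y(i) * de - (std::exp(etn) - exp_eta(i));
        }
        double alpha = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
        ++try_e;
        if (R::unif_rand() < alpha) {
          ++acc_e;
          e(i) += de;
          eta(i) += de;
          exp_eta(i) = std::exp(eta(i));
        }
        if (iter <= burnin) ls_e(i) += gam * (alpha - 0.44);
      }
    }

    // ---- conjugate variance draws ------------------------------------
    if (sample_s2e) {
      s2e = rinvgamma(ig_shape + 0.5 * n,
                      ig_rate + 0.5 * arma::dot(e, e));
    }
    if (sample_s2p && sp > 0) {
      // interweave: condition on a = sp*L*u; a' A^{-1} a = s2p * u'u
      double quad = s2p * arma::dot(u, u);
      double s2p_new = rinvgamma(ig_shape + 0.5 * n, ig_rate + 0.5 * quad);
      double ratio = std::sqrt(s2p / s2p_new);
      u *= ratio;                      // a (hence eta) unchanged
      s2p = s2p_new;
      sp = std::sqrt(s2p);
    }

    if (!eta.is_finite()) {
      divergent = true;
      divergent_iter = iter;
      break;
    }

    if (iter > burnin && (iter - burnin) % thin == 0 && keep < n_keep) {
      beta_out.row(keep) = beta.t();
      s2p_out(keep) = s2p;
      s2e_out(keep) = s2e;
      ++keep;
    }
  }

  return List::create(
    _["beta"] = beta_out.rows(0, std::max(keep - 1, 0)),
    _["sigma2_phylo"] = s2p_out.head(std::max(keep, 1)),
    _["sigma2_overdisp"] = s2e_out.head(std::max(keep, 1)),
    _["n_kept"] = keep,
    _["acc_beta"] = try_beta ? (double)acc_beta / try_beta : NA_REAL,
    _["acc_u"] = try_u ? (double)acc_u / try_u : NA_REAL,
    _["acc_e"] = try_e ? (double)acc_e / try_e : NA_REAL,
    _["divergent"] = divergent,
    _["divergent_iter"] = divergent_iter);
}
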