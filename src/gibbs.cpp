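// Gibbs sampler for Bayesian (quantile) structural equation models.
//
// Model (indicators centered upstream):
//   y_i  = Lambda * omega_i + eps_i,        eps_i  ~ N(0, diag(psi))
//   omega_i = (eta_i, xi_i'),               xi_i   ~ N(0, Phi)
//   eta_i = b0 + b' d_i + gamma' xi_i + delta_i
// Mean mode:     delta_i ~ N(0, sigma)                  (sigma = variance)
// Quantile mode: delta_i ~ ALD(0, sigma, tau)           (sigma = scale), via
//   delta_i = k1 z_i + sqrt(k2 sigma z_i) w_i,  z_i ~ Exp(mean sigma),
//   k1 = (1-2tau)/(tau(1-tau)),  k2 = 2/(tau(1-tau)).
// Every indicator loads on exactly one factor; one loading per factor is
// fixed at 1 for identification.  All randomness comes from R's RNG so a
// set.seed() call upstream makes the chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PSI_FLOOR = 1e-12;
static const double Z_FLOOR = 1e-10;

// Inverse-Gaussian draw (Michael-Schucany-Haas), using R's RNG.
static double rinvgauss(double mu, double lambda) {
  double nu = ::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = Z_FLOOR; // numerical underflow guard
  double u = ::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// GIG(1/2, chi, psi) via reciprocal inverse-Gaussian.
static double rgig_half(double chi, double psi) {
  if (chi < 1e-12) chi = 1e-12;
  double u = rinvgauss(std::sqrt(psi / chi), psi);
  double z = 1.0 / u;
  return (z < Z_FLOOR) ? Z_FLOOR : z;
}

static double rinvgamma(double shape, double rate) {
  // X ~ IG(shape, rate)  <=>  1/X ~ Gamma(shape, scale = 1/rate)
  double g = ::Rf_rgamma(shape, 1.0 / rate);
  if (g < 1e-300) g = 1e-300;
  return 1.0 / g;
}

// Cholesky with a ridge retry for near-singular conditionals.
static arma::mat safe_chol(const arma::mat& A) {
  arma::mat R;
  arma::mat As = arma::symmatu(A);
  if (arma::chol(R, As)) return R;
  arma::mat Aj = As + 1e-8 * arma::eye<arma::mat>(A.n_rows, A.n_cols);
  if (arma::chol(R, Aj)) {
    Rcpp::warning("singular conditional covariance; applied 1e-8 ridge");
    return R;
  }
  Aj = As + 1e-4 * arma::eye<arma::mat>(A.n_rows, A.n_cols);
  if (!arma::chol(R, Aj))
    Rcpp::stop("conditional covariance not positive definite");
  Rcpp::warning("singular conditional covariance; applied 1e-4 ridge");
  return R;
}

static arma::vec rnorm_vec(arma::uword m) {
  arma::vec z(m);
  for (arma::uword j = 0; j < m; ++j) z(j) = ::norm_rand();
  return z;
}

// Draw from N(P^{-1} h, P^{-1}) given precision P and linear term h.
static arma::vec draw_mvn_precision(const arma::mat& P, const arma::vec& h) {
  arma::mat R = safe_chol(P); // upper: P = R'R
  arma::vec mu = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), h));
  return mu + arma::solve(arma::trimatu(R), rnorm_vec(P.n_rows));
}

// Inverse-Wishart(df, S) via Bartlett on W ~ Wishart(df, S^{-1}).
static arma::mat riwish(double df, const arma::mat& S) {
  arma::uword q = S.n_rows;
  arma::mat V = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(arma::symmatu(V), "lower");
  arma::mat A(q, q, arma::fill::zeros);
  for (arma::uword i = 0; i < q; ++i) {
    A(i, i) = std::sqrt(::Rf_rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = ::norm_rand();
  }
  arma::mat T = L * A; // W = T T'
  arma::mat Tinv = arma::inv(arma::trimatl(T));
  return arma::symmatu(Tinv.t() * Tinv);
}

// [[Rcpp::export(name = ".gibbs_sem")]]
List gibbs_sem(const arma::mat& Y,          // n x p, centered
               const arma::mat& D,          // n x r covariates (may be 0-col)
               const arma::ivec& factor_of, // length p, 1-based factor index
               const arma::ivec& fixed,     // length p, 1 = loading fixed at 1
               int q2,                      // number of exogenous factors
               bool quantile, double tau,
               List priors, List control,
               const arma::vec& fixed_psi,  // length p, NaN = estimate
               double fixed_sigma,          // NaN = estimate
               bool intercepts,             // estimate measurement intercepts?
               const arma::ivec& score_rows,// stored-row indices (1-based) to save scores
               List init                    // optional initial state (may be empty)
               ) {
  const arma::uword n = Y.n_rows, p = Y.n_cols;
  const arma::uword r = D.n_cols;
  const arma::uword q = (arma::uword)q2 + 1; // factor 1 = eta
  const arma::uword m = 1 + r + (arma::uword)q2; // structural design dim

  // priors
  const double lam0 = as<double>(priors["loading_prior_mean"]);
  const double H0 = as<double>(priors["loading_prior_variance"]);
  const double a_y = as<double>(priors["error_var_shape"]);
  const double b_y = as<double>(priors["error_var_rate"]);
  const double a_s = as<double>(priors["structural_scale_shape"]);
  const double b_s = as<double>(priors["structural_scale_rate"]);
  const double rho0 = as<double>(priors["wishart_df"]);
  const arma::mat R0 = as<arma::mat>(priors["wishart_scale"]);
  const double beta0 = as<double>(priors["coef_prior_mean"]);
  const double Hb = as<double>(priors["coef_prior_variance"]);

  const int n_iter = as<int>(control["n_iterations"]);
  const int burn = as<int>(control["burn_in"]);
  const int thin = as<int>(control["thin"]);

  const double k1 = quantile ? (1.0 - 2.0 * tau) / (tau * (1.0 - tau)) : 0.0;
  const double k2 = quantile ? 2.0 / (tau * (1.0 - tau)) : 0.0;

  // --- initial state (deterministic) ---
  arma::vec lambda(p);
  for (arma::uword k = 0; k < p; ++k) lambda(k) = 1.0;
  arma::vec psi(p, arma::fill::ones);
  for (arma::uword k = 0; k < p; ++k)
    if (std::isfinite(fixed_psi(k))) psi(k) = std::max(fixed_psi(k), PSI_FLOOR);
  double sigma = std::isfinite(fixed_sigma) ? fixed_sigma : 1.0;
  arma::rowvec mu(p, arma::fill::zeros);    // measurement intercepts (optional)
  arma::vec beta(m, arma::fill::zeros); // (b0, b_1..b_r, gamma_1..gamma_q2)
  arma::mat Phi = arma::eye<arma::mat>(q2, q2);
  arma::vec z(n, arma::fill::ones);
  // latent scores: per-factor mean of that factor's indicators
  arma::mat Omega(n, q, arma::fill::zeros);
  for (arma::uword f = 0; f < q; ++f) {
    arma::uvec idx = arma::find(factor_of == (int)(f + 1));
    if (idx.n_elem > 0 && n > 0)
      Omega.col(f) = arma::mean(Y.cols(idx), 1);
  }

  if (init.size() > 0) {
    lambda = as<arma::vec>(init["loadings"]);
    psi = as<arma::vec>(init["psi"]);
    sigma = as<double>(init["sigma"]);
    beta = as<arma::vec>(init["beta"]);
    if (q2 > 0) Phi = as<arma::mat>(init["Phi"]);
    Omega = as<arma::mat>(init["omega"]);
    z = as<arma::vec>(init["z"]);
    if (intercepts) mu = as<arma::rowvec>(init["mu"]);
  }

  const int n_keep = (n_iter - burn) / thin;
  arma::uvec free_idx = arma::find(fixed == 0);
  const arma::uword n_free = free_idx.n_elem;
  const arma::uword n_phi = (arma::uword)(q2 * (q2 + 1) / 2);
  const arma::uword n_par = n_free + m + n_phi + 1 + p + (intercepts ? p : 0);
  arma::mat draws(n_keep, n_par);
  arma::cube scores(score_rows.n_elem > 0 ? n : 0,
                    score_rows.n_elem > 0 ? q : 0, score_rows.n_elem);

  int kept = 0, score_ptr = 0;
  arma::mat Ywork;

  for (int it = 0; it < n_iter; ++it) {
    const arma::mat* Yp = &Y;
    if (intercepts && n > 0) {
      Ywork = Y;
      Ywork.each_row() -= mu;
      Yp = &Ywork;
    }
    const arma::mat& Yc = *Yp; // indicators net of measurement intercepts

    // ---- 1. latent scores omega_i ----
    if (n > 0) {
      arma::vec a(q, arma::fill::zeros);            // diag of Lambda' Psi^-1 Lambda
      arma::mat Wlam(p, q, arma::fill::zeros);      // lambda_k / psi_k at (k, f(k))
      for (arma::uword k = 0; k < p; ++k) {
        arma::uword f = (arma::uword)factor_of(k) - 1;
        a(f) += lambda(k) * lambda(k) / psi(k);
        Wlam(k, f) = lambda(k) / psi(k);
      }
      arma::mat M = Yc * Wlam;                       // n x q, Lambda' Psi^-1 y_i rows
      arma::mat Phinv;
      if (q2 > 0) Phinv = arma::inv_sympd(arma::symmatu(Phi));
      arma::vec gam = (q2 > 0) ? beta.subvec(1 + r, m - 1) : arma::vec();
      arma::vec cbase(n);
      cbase.fill(beta(0));
      if (r > 0) cbase += D * beta.subvec(1, r);

      for (arma::uword i = 0; i < n; ++i) {
        double v = quantile ? k2 * sigma * z(i) : sigma;
        if (v < PSI_FLOOR) v = PSI_FLOOR;
        double c = cbase(i) + (quantile ? k1 * z(i) : 0.0);
        arma::mat Q(q, q, arma::fill::zeros);
        arma::vec h(q, arma::fill::zeros);
        Q(0, 0) = 1.0 / v + a(0);
        h(0) = M(i, 0) + c / v;
        if (q2 > 0) {
          for (arma::uword j = 0; j < (arma::uword)q2; ++j) {
            Q(0, j + 1) = -gam(j) / v;
            Q(j + 1, 0) = Q(0, j + 1);
            h(j + 1) = M(i, j + 1) - gam(j) * c / v;
            for (arma::uword l = 0; l <= j; ++l) {
              double val = Phinv(j, l) + gam(j) * gam(l) / v;
              Q(j + 1, l + 1) = val;
              Q(l + 1, j + 1) = val;
            }
            Q(j + 1, j + 1) += a(j + 1);
          }
        }
        Omega.row(i) = draw_mvn_precision(Q, h).t();
      }
    }

    // structural design X = [1, D, xi] and eta
    arma::mat X(n, m);
    if (n > 0) {
      X.col(0).ones();
      if (r > 0) X.cols(1, r) = D;
      if (q2 > 0) X.cols(1 + r, m - 1) = Omega.cols(1, q - 1);
    }
    arma::vec eta = (n > 0) ? arma::vec(Omega.col(0)) : arma::vec();

    // ---- 2. mixing latents z_i (quantile mode) ----
    if (quantile && n > 0) {
      arma::vec delta = eta - X * beta;
      double psi_par = k1 * k1 / (k2 * sigma) + 2.0 / sigma;
      for (arma::uword i = 0; i < n; ++i) {
        double chi = delta(i) * delta(i) / (k2 * sigma);
        z(i) = rgig_half(chi, psi_par);
      }
    }

    // ---- 3./4. loadings and measurement error variances ----
    for (arma::uword k = 0; k < p; ++k) {
      arma::uword f = (arma::uword)factor_of(k) - 1;
      if (fixed(k) == 0) {
        double ww = 0.0, wy = 0.0;
        if (n > 0) {
          ww = arma::dot(Omega.col(f), Omega.col(f));
          wy = arma::dot(Omega.col(f), Yc.col(k));
        }
        double prec = ww / psi(k) + 1.0 / H0;
        double mean = (wy / psi(k) + lam0 / H0) / prec;
        lambda(k) = mean + ::norm_rand() / std::sqrt(prec);
      }
      if (!std::isfinite(fixed_psi(k))) {
        double ss = 0.0;
        if (n > 0) {
          arma::vec res = Yc.col(k) - lambda(k) * Omega.col(f);
          ss = arma::dot(res, res);
        }
        psi(k) = rinvgamma(a_y + 0.5 * (double)n, b_y + 0.5 * ss);
        if (psi(k) < PSI_FLOOR) psi(k) = PSI_FLOOR;
      }
    }

    // ---- 4b. measurement intercepts (optional) ----
    if (intercepts) {
      for (arma::uword k = 0; k < p; ++k) {
        arma::uword f = (arma::uword)factor_of(k) - 1;
        double ss = 0.0;
        if (n > 0)
          ss = arma::accu(Y.col(k) - lambda(k) * Omega.col(f));
        double prec = (double)n / psi(k) + 1.0 / Hb;
        double mean = (ss / psi(k) + beta0 / Hb) / prec;
        mu(k) = mean + ::norm_rand() / std::sqrt(prec);
      }
    }

    // ---- 5. structural coefficients ----
    {
      arma::mat P = arma::eye<arma::mat>(m, m) / Hb;
      arma::vec h(m);
      h.fill(beta0 / Hb);
      if (n > 0) {
        if (quantile) {
          arma::vec w = 1.0 / (k2 * sigma * z);
          arma::vec resp = eta - k1 * z;
          arma::mat Xw = X.each_col() % w;
          P += X.t() * Xw;
          h += Xw.t() * resp;
        } else {
          P += X.t() * X / sigma;
          h += X.t() * eta / sigma;
        }
      }
      beta = draw_mvn_precision(P, h);
    }

    // ---- 6. structural scale ----
    if (!std::isfinite(fixed_sigma)) {
      if (quantile) {
        double acc = 0.0;
        if (n > 0) {
          arma::vec delta = eta - X * beta;
          for (arma::uword i = 0; i < n; ++i) {
            double d = delta(i) - k1 * z(i);
            acc += d * d / (2.0 * k2 * z(i)) + z(i);
          }
        }
        sigma = rinvgamma(a_s + 1.5 * (double)n, b_s + acc);
      } else {
        double ss = 0.0;
        if (n > 0) {
          arma::vec delta = eta - X * beta;
          ss = arma::dot(delta, delta);
        }
        sigma = rinvgamma(a_s + 0.5 * (double)n, b_s + 0.5 * ss);
      }
    }

    // ---- 7. exogenous factor covariance ----
    if (q2 > 0) {
      arma::mat S = R0;
      if (n > 0) {
        arma::mat Xi = Omega.cols(1, q - 1);
        S += Xi.t() * Xi;
      }
      Phi = riwish(rho0 + (double)n, S);
    }

    // ---- store ----
    if (it >= burn && ((it - burn) % thin == 0)) {
      arma::uword c = 0;
      for (arma::uword j = 0; j < n_free; ++j) draws(kept, c++) = lambda(free_idx(j));
      for (arma::uword j = 0; j < m; ++j) draws(kept, c++) = beta(j);
      for (int jj = 0; jj < q2; ++jj)
        for (int ll = 0; ll <= jj; ++ll) draws(kept, c++) = Phi(jj, ll);
      draws(kept, c++) = sigma;
      for (arma::uword k = 0; k < p; ++k) draws(kept, c++) = psi(k);
      if (intercepts)
        for (arma::uword k = 0; k < p; ++k) draws(kept, c++) = mu(k);
      ++kept;
      if (score_ptr < (int)score_rows.n_elem && score_rows(score_ptr) == kept) {
        scores.slice(score_ptr) = Omega;
        ++score_ptr;
      }
    }
  }

  List state = List::create(_["loadings"] = lambda, _["psi"] = psi,
                            _["sigma"] = sigma, _["beta"] = beta,
                            _["Phi"] = Phi, _["omega"] = Omega,
                            _["z"] = z, _["mu"] = mu);
  return List::create(_["draws"] = draws,
                      _["scores"] = scores,
                      _["score_rows"] = score_rows,
                      _["state"] = state);
}
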