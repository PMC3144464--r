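// Single-site MCMC engines for the Bayesian-alphabet marker-effect models.
//
// One engine serves BayesA, BayesB and BayesDpi (Metropolis-Hastings update of
// the locus-specific variance with the marker effect integrated out), the
// other serves BayesCpi (Gibbs update of the inclusion indicator under a
// common effect variance). All randomness comes from R's RNG so that set.seed
// in R makes runs bit-reproducible.
//
// Hot-loop organisation: the engine maintains r = Z' W y_adj for all markers.
// When marker j's effect changes by delta, r -= delta * Gram column j, where
// Gram = Z' W Z is precomputed (for panels up to GRAM_MAX_K columns);
// r is refreshed from scratch periodically to cap rounding drift. This makes
// the per-iteration cost proportional to the number of markers whose state
// changes rather than to n x K.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int GRAM_MAX_K = 6000;   // Gram cache up to ~275 MB
static const int REFRESH_EVERY = 100; // full r recomputation cadence

// draw from a scaled inverse chi-square with df nu and scale s2
static inline double rscinvchisq(double nu, double s2) {
  return nu * s2 / R::rchisq(nu);
}

// log density of a scaled inverse chi-square at x > 0; lgamma(nu/2) is
// passed in precomputed
static inline double dscinvchisq_log_c(double x, double nu, double s2,
                                       double lgamma_half_nu) {
  double h = 0.5 * nu;
  return h * std::log(h * s2) - lgamma_half_nu - (h + 1.0) * std::log(x) -
         h * s2 / x;
}

// log Bayes factor of fitting marker k with effect variance s2k against not
// fitting it, with the effect integrated out analytically:
//   y_adj ~ N(0, z z' s2k + W^-1 s2e)  vs  y_adj ~ N(0, W^-1 s2e)
// r = z' W y_adj, zWz = z' W z. Rank-one Gaussian identity. Bounded above by
// r^2 / (2 s2e zWz) for every s2k > 0.
static inline double marginal_log_bf_(double r, double zWz, double s2k,
                                      double s2e) {
  if (s2k <= 0.0) return 0.0;
  double c = zWz + s2e / s2k;
  return 0.5 * (std::log(s2e) - std::log(s2k) - std::log(c)) +
         r * r / (2.0 * s2e * c);
}

// [[Rcpp::export]]
double marginal_log_bf(double r, double zWz, double s2k, double s2e) {
  return marginal_log_bf_(r, zWz, s2k, s2e);
}

// log posterior odds that delta_k = 1 in the BayesCpi Gibbs step
// [[Rcpp::export]]
double cpi_log_odds(double r, double zWz, double sigma2_a, double sigma2_e,
                    double pi) {
  if (pi <= 0.0) return R_PosInf;
  if (pi >= 1.0) return R_NegInf;
  return marginal_log_bf_(r, zWz, sigma2_a, sigma2_e) + std::log1p(-pi) -
         std::log(pi);
}

// proposal scale for the locus-variance move, a function of the state the
// move starts from: the prior scale when the SNP is out of the model, the
// current variance recentred so the proposal mean sits on it when in
static inline double mh_prop_scale(double s2_state, double nu_a,
                                   double prior_scale) {
  return (s2_state > 0.0) ? s2_state * (nu_a - 2.0) / nu_a : prior_scale;
}

// log MH acceptance ratio for moving the locus variance from s2_cur to
// s2_prop, marker effect integrated out (Godsill-type model-switch ratio).
// prior: pi * point-mass(0) + (1-pi) * scinvchisq(nu_a, prior_scale)
// proposal from state x: 0.5 * point-mass(0) +
//   0.5 * scinvchisq(nu_a, mh_prop_scale(x)); the reverse density is
// evaluated with the scale implied by the proposed state, so the kernel is
// reversible with respect to the target. For pure entry (0 -> s2) and exit
// (s2 -> 0) moves the prior and proposal densities cancel, leaving
// +/- logBF + the prior log odds.
// [[Rcpp::export]]
double mh_log_accept(double s2_cur, double s2_prop, double r, double zWz,
                     double sigma2_e, double pi, double nu_a,
                     double prior_scale) {
  double lgh = R::lgammafn(0.5 * nu_a);
  double lr = marginal_log_bf_(r, zWz, s2_prop, sigma2_e) -
              marginal_log_bf_(r, zWz, s2_cur, sigma2_e);
  if (s2_prop > 0.0) {
    if (pi >= 1.0) return R_NegInf;
    lr += std::log1p(-pi) +
          dscinvchisq_log_c(s2_prop, nu_a, prior_scale, lgh);
  } else {
    if (pi <= 0.0) return R_NegInf;
    lr += std::log(pi);
  }
  if (s2_cur > 0.0) {
    if (pi >= 1.0) return R_PosInf;
    lr -= std::log1p(-pi) +
          dscinvchisq_log_c(s2_cur, nu_a, prior_scale, lgh);
  } else {
    if (pi <= 0.0) return R_PosInf;
    lr -= std::log(pi);
  }
  // proposal terms (the 0.5 mixture weights cancel)
  lr += (s2_cur > 0.0)
            ? dscinvchisq_log_c(s2_cur, nu_a,
                                mh_prop_scale(s2_prop, nu_a, prior_scale),
                                lgh)
            : 0.0;
  lr -= (s2_prop > 0.0)
            ? dscinvchisq_log_c(s2_prop, nu_a,
                                mh_prop_scale(s2_cur, nu_a, prior_scale),
                                lgh)
            : 0.0;
  return lr;
}

// methods: 0 = BayesA, 1 = BayesB, 2 = BayesCpi, 3 = BayesDpi
// [[Rcpp::export]]
List mcmc_engine(const arma::mat& Z, const arma::vec& y, const arma::vec& w,
                 int method, List prior, List chain, List control,
                 const arma::mat& Ainv, const arma::uvec& u_map,
                 bool fit_polygenic) {
  const int n = Z.n_rows, K = Z.n_cols;
  const double nu_a = as<double>(prior["nu_a"]);
  const double S2_a = as<double>(prior["S2_a"]);
  const double nu_e = as<double>(prior["nu_e"]);
  const double S2_e = as<double>(prior["S2_e"]);
  const double nu_u = as<double>(prior["nu_u"]);
  const double S2_u = as<double>(prior["S2_u"]);
  const double dpi_shape0 = as<double>(prior["dpi_gamma_shape"]);
  const double dpi_rate0 = as<double>(prior["dpi_gamma_rate"]);
  double pi = as<double>(prior["pi0"]);

  const int n_iter = as<int>(chain["chain_length"]);
  const int burn_in = as<int>(chain["burn_in"]);
  const int mh_reps = as<int>(chain["mh_reps"]);
  const int thin = as<int>(chain["thin"]);

  const bool fix_mu = as<bool>(control["fix_mu"]);
  const bool fix_s2e = as<bool>(control["fix_sigma2_e"]);
  const bool fix_s2a = as<bool>(control["fix_sigma2_a"]);
  const bool fix_pi = as<bool>(control["fix_pi"]);
  const int check_every = as<int>(control["check_every"]);
  const bool verbose = as<bool>(control["verbose"]);

  const bool mixture_prior = (method != 2);  // locus-specific variances
  const bool pi_unknown = (method == 2 || method == 3) && !fix_pi;
  const double lgamma_half_nu = R::lgammafn(0.5 * nu_a);

  RNGScope scope;

  // state
  arma::vec a(K, arma::fill::zeros);
  arma::ivec delta(K, arma::fill::zeros);
  arma::vec s2k(K, arma::fill::zeros);   // locus variances (A/B/Dpi)
  double s2a_common = nu_a * S2_a / (nu_a - 2.0);  // Cpi common variance
  double S2_dpi = S2_a;                  // Dpi unknown scale
  double s2e = nu_e > 2.0 ? nu_e * S2_e / (nu_e - 2.0) : S2_e;
  double s2u = nu_u > 2.0 ? nu_u * S2_u / (nu_u - 2.0) : S2_u;
  const double wsum = arma::accu(w);
  double mu = arma::dot(w, y) / wsum;
  if (fix_mu) mu = as<double>(control["mu_value"]);
  if (fix_s2e) s2e = as<double>(control["sigma2_e_value"]);
  if (fix_s2a) s2a_common = as<double>(control["sigma2_a_value"]);

  if (method == 0) {  // BayesA: every marker permanently in the model
    delta.ones();
    s2k.fill(nu_a * S2_a / (nu_a - 2.0));
  }

  const int n_u = fit_polygenic ? Ainv.n_rows : 0;
  arma::vec u(std::max(n_u, 1), arma::fill::zeros);

  arma::vec y_adj = y - mu;               // y adjusted for everything fitted
  arma::mat WZ = Z.each_col() % w;        // W Z, used for r and Gram
  arma::vec zWz(K), zW1(K);
  for (int k = 0; k < K; ++k) {
    zWz[k] = arma::dot(WZ.col(k), Z.col(k));
    zW1[k] = arma::accu(WZ.col(k));
  }
  const bool use_gram = (K <= GRAM_MAX_K);
  arma::mat Gram;
  if (use_gram) Gram = WZ.t() * Z;        // Gram[k, j] = z_k' W z_j
  arma::vec r = WZ.t() * y_adj;           // r_k = z_k' W y_adj, maintained
  const double* gram_mem = use_gram ? Gram.memptr() : nullptr;

  // apply an effect change at marker j: y_adj and r stay in sync
  auto apply_change = [&](int j, double delta_a) {
    y_adj -= delta_a * Z.col(j);
    if (use_gram) {
      const double* gc = gram_mem + (size_t)j * K;
      double* rp = r.memptr();
      for (int k = 0; k < K; ++k) rp[k] -= delta_a * gc[k];
    } else {
      r -= delta_a * (WZ.t() * Z.col(j));
    }
  };
  auto refresh_r = [&]() { r = WZ.t() * y_adj; };

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  // pi, m, sigma2_e, sigma2_a_or_S2, mu, sigma2_u, sigma2_k of locus 1
  arma::mat chains(n_keep, 7);
  arma::vec a_sum(K, arma::fill::zeros);
  arma::vec freq(K, arma::fill::zeros);
  int kept = 0;
  double recon_max = 0.0;

  for (int t = 0; t < n_iter; ++t) {
    // --- overall mean ---
    if (!fix_mu) {
      double num = arma::dot(w, y_adj) + mu * wsum;
      double mu_new = R::rnorm(num / wsum, std::sqrt(s2e / wsum));
      double d = mu_new - mu;
      y_adj -= d;
      r -= d * zW1;
      mu = mu_new;
    }

    // --- marker loop ---
    int m = 0;
    if (!mixture_prior) {
      // BayesCpi Gibbs step
      const double log_odds_prior =
          (pi <= 0.0) ? R_PosInf
                      : ((pi >= 1.0) ? R_NegInf
                                     : std::log1p(-pi) - std::log(pi));
      for (int k = 0; k < K; ++k) {
        double ak = a[k];
        // r excluding marker k's own contribution
        double rk = r[k] + (ak != 0.0 ? zWz[k] * ak : 0.0);
        double lo = marginal_log_bf_(rk, zWz[k], s2a_common, s2e) +
                    log_odds_prior;
        bool in;
        if (lo == R_PosInf) in = true;
        else if (lo == R_NegInf) in = false;
        else in = (R::unif_rand() < 1.0 / (1.0 + std::exp(-lo)));
        double anew = 0.0;
        if (in) {
          double c = zWz[k] + s2e / s2a_common;
          anew = R::rnorm(rk / c, std::sqrt(s2e / c));
          delta[k] = 1;
          ++m;
        } else {
          delta[k] = 0;
        }
        if (anew != ak) {
          apply_change(k, anew - ak);
          a[k] = anew;
        }
      }
    } else {
      // BayesA / BayesB / BayesDpi Metropolis-Hastings step
      const double prior_scale = (method == 3) ? S2_dpi : S2_a;
      const double log_in_odds =
          (pi <= 0.0) ? R_PosInf
                      : ((pi >= 1.0) ? R_NegInf
                                     : std::log1p(-pi) - std::log(pi));
      for (int k = 0; k < K; ++k) {
        double ak = a[k];
        double rk = r[k] + (ak != 0.0 ? zWz[k] * ak : 0.0);
        double s2_cur = s2k[k];
        // cheap upper bound on logBF over all variances
        const double bf_bound =
            (zWz[k] > 0.0) ? rk * rk / (2.0 * s2e * zWz[k]) : 0.0;
        double logbf_cur =
            (s2_cur > 0.0) ? marginal_log_bf_(rk, zWz[k], s2_cur, s2e) : 0.0;
        for (int rep = 0; rep < mh_reps; ++rep) {
          if (R::unif_rand() < 0.5) {
            // propose removal (point mass at zero)
            if (s2_cur == 0.0) continue;  // identity move
            if (log_in_odds == R_PosInf) continue;  // pi = 0: never remove
            double lr = -logbf_cur - log_in_odds;
            if (lr >= 0.0 || std::log(R::unif_rand()) < lr) {
              s2_cur = 0.0;
              logbf_cur = 0.0;
            }
          } else if (s2_cur == 0.0) {
            // entry move; prior and proposal densities cancel
            if (log_in_odds == R_NegInf) continue;
            double loge = -R::exp_rand();  // log of the acceptance uniform
            if (bf_bound + log_in_odds < loge) continue;  // early reject
            double s2p = rscinvchisq(nu_a, prior_scale);
            double lr = marginal_log_bf_(rk, zWz[k], s2p, s2e) + log_in_odds;
            if (loge < lr) {
              s2_cur = s2p;
              logbf_cur = lr - log_in_odds;
            }
          } else {
            // variance move with the marker kept in the model
            double fwd_scale = mh_prop_scale(s2_cur, nu_a, prior_scale);
            double s2p = rscinvchisq(nu_a, fwd_scale);
            double logbf_prop = marginal_log_bf_(rk, zWz[k], s2p, s2e);
            double lr =
                logbf_prop - logbf_cur +
                dscinvchisq_log_c(s2p, nu_a, prior_scale, lgamma_half_nu) -
                dscinvchisq_log_c(s2_cur, nu_a, prior_scale, lgamma_half_nu) +
                dscinvchisq_log_c(
                    s2_cur, nu_a, mh_prop_scale(s2p, nu_a, prior_scale),
                    lgamma_half_nu) -
                dscinvchisq_log_c(s2p, nu_a, fwd_scale, lgamma_half_nu);
            if (lr >= 0.0 || std::log(R::unif_rand()) < lr) {
              s2_cur = s2p;
              logbf_cur = logbf_prop;
            }
          }
        }
        s2k[k] = s2_cur;
        double anew = 0.0;
        if (s2_cur > 0.0) {
          double c = zWz[k] + s2e / s2_cur;
          anew = R::rnorm(rk / c, std::sqrt(s2e / c));
          delta[k] = 1;
          ++m;
        } else {
          delta[k] = 0;
        }
        if (anew != ak) {
          apply_change(k, anew - ak);
          a[k] = anew;
        }
      }
    }

    // --- polygenic effects ---
    if (fit_polygenic) {
      arma::vec wy(n);
      for (int i = 0; i < n; ++i) {
        y_adj[i] += u[u_map[i]];           // unadjust records for current u
        wy[i] = w[i] * y_adj[i];
      }
      arma::mat C = Ainv / s2u;
      arma::vec rhs(n_u, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        C(u_map[i], u_map[i]) += w[i] / s2e;
        rhs[u_map[i]] += wy[i] / s2e;
      }
      arma::mat L = arma::chol(C, "lower");
      arma::vec zdraw(n_u);
      for (int j = 0; j < n_u; ++j) zdraw[j] = R::norm_rand();
      // u = C^-1 rhs + L'^-1 z  (exact draw from N(C^-1 rhs, C^-1))
      arma::vec mean_u = arma::solve(arma::trimatu(L.t()),
                                     arma::solve(arma::trimatl(L), rhs));
      arma::vec noise = arma::solve(arma::trimatu(L.t()), zdraw);
      u = mean_u + noise;
      for (int i = 0; i < n; ++i) y_adj[i] -= u[u_map[i]];
      refresh_r();
      double q = arma::as_scalar(u.t() * Ainv * u);
      s2u = rscinvchisq(nu_u + n_u, (q + nu_u * S2_u) / (nu_u + n_u));
    }

    // --- residual variance ---
    if (!fix_s2e) {
      double sse = 0.0;                    // e' W e
      for (int i = 0; i < n; ++i) sse += w[i] * y_adj[i] * y_adj[i];
      s2e = rscinvchisq(nu_e + n, (sse + nu_e * S2_e) / (nu_e + n));
    }

    // --- effect-variance hyperparameters ---
    if (method == 2 && !fix_s2a) {
      double ssa = 0.0;
      for (int k = 0; k < K; ++k) ssa += a[k] * a[k];
      s2a_common =
          rscinvchisq(nu_a + m, (ssa + nu_a * S2_a) / (nu_a + m));
    }
    if (method == 3) {
      double sinv = 0.0;
      for (int k = 0; k < K; ++k)
        if (s2k[k] > 0.0) sinv += 1.0 / s2k[k];
      double shape = 0.5 * m * nu_a + dpi_shape0;
      double rate = 0.5 * nu_a * sinv + dpi_rate0;
      S2_dpi = R::rgamma(shape, 1.0 / rate);
    }

    // --- pi ---
    if (pi_unknown) pi = R::rbeta((double)(K - m) + 1.0, (double)m + 1.0);

    // --- bookkeeping ---
    if ((t + 1) % REFRESH_EVERY == 0) refresh_r();
    if (check_every > 0 && (t + 1) % check_every == 0) {
      arma::vec recon = y_adj + mu;
      for (int k = 0; k < K; ++k)
        if (a[k] != 0.0) recon += Z.col(k) * a[k];
      if (fit_polygenic)
        for (int i = 0; i < n; ++i) recon[i] += u[u_map[i]];
      double rel = arma::norm(recon - y, "inf") /
                   std::max(1.0, arma::norm(y, "inf"));
      if (rel > recon_max) recon_max = rel;
    }
    if (verbose && (t + 1) % 1000 == 0)
      Rcpp::Rcerr << "iteration " << (t + 1) << "/" << n_iter << " m=" << m
                  << " pi=" << pi << std::endl;

    if (t >= burn_in && (t - burn_in) % thin == 0) {
      chains(kept, 0) = pi;
      chains(kept, 1) = (double)m;
      chains(kept, 2) = s2e;
      chains(kept, 3) = (method == 2) ? s2a_common
                        : (method == 3) ? S2_dpi : S2_a;
      chains(kept, 4) = mu;
      chains(kept, 5) = fit_polygenic ? s2u : NA_REAL;
      chains(kept, 6) = mixture_prior ? s2k[0] : s2a_common;
      a_sum += a;
      for (int k = 0; k < K; ++k) freq[k] += (double)delta[k];
      ++kept;
    }
    if ((t & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["snp_effect_means"] = a_sum / kept, _["model_freqs"] = freq / kept,
      _["chains"] = chains.rows(0, kept - 1), _["recon_max_rel"] = recon_max,
      _["final_mu"] = mu, _["final_pi"] = pi,
      _["final_u"] = fit_polygenic ? NumericVector(u.begin(), u.end())
                                   : NumericVector(0));
}
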