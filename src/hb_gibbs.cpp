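// Metropolis-within-Gibbs sampler for the three-level hierarchical model of
// longitudinal multiple-flow FeNO.
//
// Level 1 (maneuver):  log(FeNO_sk) ~ N( f(theta_s, flow_sk), sigma_eps^2 )
//   with f the log two-compartment mean.
// Level 2 (visit):     theta_s ~ N( beta0 + beta1 * x_s + alpha_{i(s)},
//                                   diag(sigma_v^2) ), truncated to ca >= 0.
// Level 3 (participant): alpha_i ~ MVN(0, Sigma_tau).
//
// Update scheme. Per-session theta moves by joint random-walk MH whose
// proposal covariance is the session's Gauss-Newton posterior covariance
// (likelihood curvature at the current state plus the visit-level prior
// precision), frozen at mid-warmup and scaled adaptively per session; the
// (logC_aw, logD_aw) likelihood ridge is strongly correlated, so
// componentwise walks mix far too slowly. Truncation is enforced by
// rejecting ca < 0 proposals.
//
// The hierarchy parameters use a PARTIALLY COLLAPSED scheme: conditioning on
// the participant effects alpha creates a well-known absorbing region near
// singular covariances (the conjugate inverse-Wishart chain gets trapped
// with correlations pinned at +/-1), and the participant/visit variance
// split then mixes impossibly slowly. Instead, with alpha integrated out
// analytically, (Sigma_tau, sigma_v) are updated jointly by adaptive
// random-walk MH on (Cholesky of Sigma_tau, log visit variances), and beta
// is then drawn exactly from its marginal Gaussian conditional (GLS over
// participants, covariance J (x) Sigma_tau + I (x) Sigma_v). alpha is
// refreshed from its exact conditional afterwards, which makes the collapsed
// steps a valid partially collapsed Gibbs sampler. Truncation normalising
// constants are ignored in the collapsed updates: with C_A several SDs above
// zero the factor is numerically negligible.
//
// All randomness comes from R's RNG, so set.seed() controls the chain.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double log2cm(double ca, double lcaw, double ldaw, double flow) {
  double caw = std::exp(lcaw);
  double arg = caw + (ca - caw) * std::exp(-std::exp(ldaw) / flow);
  if (arg <= 0.0 || !std::isfinite(arg)) return NA_REAL;
  return std::log(arg);
}

// session residual sum of squares of theta over its maneuvers (independent
// of sigma_eps, so it can be cached across moves and reused by the
// sigma_eps update); +Inf when the mean is invalid
static double sess_sse(const double* th, const std::vector<double>& flow,
                       const std::vector<double>& y, size_t lo, size_t hi) {
  double sse = 0.0;
  for (size_t k = lo; k < hi; ++k) {
    double m = log2cm(th[0], th[1], th[2], flow[k]);
    if (!std::isfinite(m)) return std::numeric_limits<double>::infinity();
    double r = y[k] - m;
    sse += r * r;
  }
  return sse;
}

// Gauss-Newton curvature of the session log-likelihood at theta, plus the
// diagonal visit-level prior precision: J' J / sigma_eps^2 + diag(1/sig2_v)
static arma::mat sess_curvature(const double* th,
                                const std::vector<double>& flow,
                                size_t lo, size_t hi, double sig2_eps,
                                const arma::vec& sig2_v) {
  arma::mat H = arma::diagmat(1.0 / sig2_v);
  double ca = th[0], caw = std::exp(th[1]), daw = std::exp(th[2]);
  for (size_t k = lo; k < hi; ++k) {
    double e = std::exp(-daw / flow[k]);
    double F = caw + (ca - caw) * e;
    if (F <= 0 || !std::isfinite(F)) continue;
    arma::vec J = {e / F, caw * (1.0 - e) / F,
                   -(ca - caw) * e * daw / (flow[k] * F)};
    H += J * J.t() / sig2_eps;
  }
  return H;
}

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// phi(0..5) = (log L11, log L22, log L33, L21, L31, L32): lower Cholesky of
// Sigma_tau; phi(6..8) = log visit-level variances.
static arma::mat phi_to_L(const arma::vec& phi) {
  arma::mat L(3, 3, arma::fill::zeros);
  L(0, 0) = std::exp(phi(0));
  L(1, 1) = std::exp(phi(1));
  L(2, 2) = std::exp(phi(2));
  L(1, 0) = phi(3);
  L(2, 0) = phi(4);
  L(2, 1) = phi(5);
  return L;
}

// Log of the collapsed conditional p(Sigma_tau, sigma_v^2 | theta, beta) in
// phi coordinates: inverse-Wishart + inverse-gamma priors, the marginal
// normal likelihood of the per-participant residuals with alpha integrated
// out (participant means ~ N(0, Sigma_tau + Sigma_v/n_i), within-participant
// deviations ~ N(0, Sigma_v)), and the Jacobians of the parameterisation.
static double TV_logpost(const arma::vec& phi, const arma::mat& rbar,
                         const arma::mat& wdiag, const arma::ivec& nvis,
                         double iw_df, const arma::mat& D,
                         double ig_shape, double ig_rate) {
  arma::mat L = phi_to_L(phi);
  arma::mat T = L * L.t();
  double ldT = 2.0 * (phi(0) + phi(1) + phi(2));
  arma::mat Tinv;
  if (!arma::inv_sympd(Tinv, T)) return -std::numeric_limits<double>::infinity();
  arma::vec sig2_v = arma::exp(phi.subvec(6, 8));
  // priors: IW(iw_df, D) on T; IG(a, b) on each visit variance (log scale,
  // so the +phi Jacobian folds into the exponent)
  double lp = -0.5 * (iw_df + 4.0) * ldT - 0.5 * arma::trace(D * Tinv);
  lp += 4.0 * phi(0) + 3.0 * phi(1) + 2.0 * phi(2); // dT/dphi Jacobian
  for (int c = 0; c < 3; ++c)
    lp += -ig_shape * phi(6 + c) - ig_rate / sig2_v(c);
  const int N = rbar.n_rows;
  int last_n = -1;
  arma::mat Minv;
  double ldM = 0.0, ldV = phi(6) + phi(7) + phi(8);
  for (int i = 0; i < N; ++i) {
    const int n = nvis(i);
    if (n != last_n) {
      arma::mat M = T + arma::diagmat(sig2_v / (double)n);
      arma::mat Mi;
      if (!arma::inv_sympd(Mi, M)) return -std::numeric_limits<double>::infinity();
      Minv = Mi;
      double v, sgn;
      arma::log_det(v, sgn, M);
      ldM = v;
      last_n = n;
    }
    arma::vec r = rbar.row(i).t();
    lp += -0.5 * (ldM + arma::as_scalar(r.t() * Minv * r));
    // within-participant part: (n-1) log|V| + tr(V^{-1} W_i)
    for (int c = 0; c < 3; ++c)
      lp += -0.5 * ((n - 1) * phi(6 + c) + wdiag(i, c) / sig2_v(c));
  }
  (void)ldV;
  return lp;
}

// [[Rcpp::export(name = ".hb_gibbs_chain")]]
List hb_gibbs_chain(IntegerVector session_part, NumericVector session_x,
                    IntegerVector obs_offset, NumericVector obs_flow,
                    NumericVector obs_logfeno, int n_part,
                    bool has_covariate, bool truncate_ca,
                    double prior_var_beta, double iw_df,
                    NumericMatrix iw_scale, double ig_shape, double ig_rate,
                    int n_warmup, int n_iter, int thin,
                    NumericMatrix theta_init, NumericVector phi_init) {
  const int S = session_part.size();
  const int n_obs = obs_flow.size();
  std::vector<double> flow(obs_flow.begin(), obs_flow.end());
  std::vector<double> y(obs_logfeno.begin(), obs_logfeno.end());
  std::vector<size_t> off(obs_offset.begin(), obs_offset.end()); // length S+1

  arma::mat theta(S, 3);
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < 3; ++c) theta(s, c) = theta_init(s, c);

  arma::vec beta0 = arma::vectorise(arma::mean(theta, 0));
  arma::vec beta1(3, arma::fill::zeros);
  arma::mat alpha(n_part, 3, arma::fill::zeros);
  arma::mat Sigma_tau = arma::eye(3, 3) * 0.25;
  arma::vec sig2_v = {0.09, 0.09, 0.09};
  double sig2_eps = 0.04;
  arma::mat D(iw_scale.begin(), 3, 3, false);

  // sessions per participant
  std::vector<std::vector<int> > psess(n_part);
  for (int s = 0; s < S; ++s) psess[session_part[s]].push_back(s);

  // per-session proposal: lower Cholesky factor of the Gauss-Newton
  // covariance (refreshed until mid-warmup, then frozen) times an adaptive
  // scalar step (log scale)
  arma::vec lstep(S, arma::fill::value(std::log(1.0)));
  arma::ivec acc(S, arma::fill::zeros);
  arma::ivec att(S, arma::fill::zeros);
  std::vector<arma::mat> prop_L(S, arma::eye(3, 3) * 0.05);
  const int freeze_at = n_warmup / 2;

  // state and adaptive step of the collapsed (Sigma_tau, sigma_v) update
  arma::vec phi = {std::log(0.4), std::log(0.4), std::log(0.4), 0.0, 0.0, 0.0,
                   std::log(0.09), std::log(0.09), std::log(0.09)};
  if (phi_init.size() == 9)
    for (int c = 0; c < 9; ++c) phi(c) = phi_init[c];
  {
    arma::mat L0 = phi_to_L(phi);
    Sigma_tau = L0 * L0.t();
    sig2_v = arma::exp(phi.subvec(6, 8));
  }
  double tstep = std::log(0.05);
  int t_acc = 0, t_att = 0;
  long long tv_acc_tot = 0, tv_att_tot = 0;
  // adaptive (Haario-style) proposal covariance for the collapsed update:
  // empirical covariance of phi accumulated over warmup, refreshed
  // periodically, frozen afterwards
  arma::vec tv_sum(9, arma::fill::zeros);
  arma::mat tv_ss(9, 9, arma::fill::zeros);
  int tv_n = 0;
  arma::mat tv_L = arma::eye(9, 9);
  bool tv_have_cov = false;
  // Many cheap collapsed steps per sweep: the sufficient statistics are
  // computed once, each step costs O(n_part) with 3x3 solves, and the
  // (Sigma_tau, sigma_v) conditional can be bimodal in weakly identified
  // designs (a truthlike mode and a near-singular one), so frequent
  // transitions are needed for the chains to mix across modes. One step in
  // ten triples the proposal scale to encourage mode jumps.
  const int n_tv_steps = 30;

  // adaptive scales of the per-component level-shift moves, plus a joint
  // 3-dim shift whose covariance is learnt from the warmup beta0 draws
  arma::vec shift_lstep(3, arma::fill::value(std::log(0.02)));
  arma::ivec shift_acc(3, arma::fill::zeros);
  arma::ivec shift_att(3, arma::fill::zeros);
  arma::vec b0_sum(3, arma::fill::zeros);
  arma::mat b0_ss(3, 3, arma::fill::zeros);
  int b0_n = 0;
  arma::mat jshift_L = arma::eye(3, 3) * 0.02;
  bool jshift_have = false;
  double jshift_lstep = std::log(1.0);
  int jshift_acc = 0, jshift_att = 0;
  // slope-shift move: beta1 and theta_.c += delta_c * x_s jointly, same
  // residual-invariance idea applied to the covariate slopes
  arma::vec b1_sum(3, arma::fill::zeros);
  arma::mat b1_ss(3, 3, arma::fill::zeros);
  int b1_n = 0;
  arma::mat sshift_L = arma::eye(3, 3) * 0.02;
  bool sshift_have = false;
  double sshift_lstep = std::log(1.0);
  int sshift_acc = 0, sshift_att = 0;

  const int n_keep = n_iter / thin;
  const int P = 17; // beta0(3) beta1(3) tau(3) rho(3) sigma_v(3) sigma_eps theta_accept
  arma::mat draws(n_keep, P);
  arma::mat theta_sum(S, 3, arma::fill::zeros);
  double ca_min = std::numeric_limits<double>::infinity();
  int kept = 0;
  long long tot_acc = 0, tot_att = 0;

  const int p_beta = has_covariate ? 6 : 3;

  // cached residual sum of squares per session at the current theta
  arma::vec cur_sse(S);
  for (int s = 0; s < S; ++s) {
    double th[3] = {theta(s, 0), theta(s, 1), theta(s, 2)};
    cur_sse(s) = sess_sse(th, flow, y, off[s], off[s + 1]);
  }
  arma::vec prop_sse(S);

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    const bool warm = it < n_warmup;
    const double inv2s2 = 0.5 / sig2_eps;

    // --- theta: joint random-walk MH with Gauss-Newton proposal -----------
    const bool refresh = it <= freeze_at;
    for (int s = 0; s < S; ++s) {
      const int i = session_part[s];
      double m[3], cur[3], prop[3];
      for (int c = 0; c < 3; ++c) {
        m[c] = beta0(c) + (has_covariate ? beta1(c) * session_x[s] : 0.0) +
               alpha(i, c);
        cur[c] = theta(s, c);
      }
      if (refresh) {
        arma::mat H = sess_curvature(cur, flow, off[s], off[s + 1],
                                     sig2_eps, sig2_v);
        arma::mat Cov;
        if (arma::inv_sympd(Cov, H)) {
          arma::mat L;
          if (arma::chol(L, Cov, "lower")) prop_L[s] = L;
        }
      }
      att(s)++;
      const arma::mat& L = prop_L[s];
      double sc = std::exp(lstep(s));
      arma::vec z = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
      arma::vec step = L * z;
      for (int c = 0; c < 3; ++c) prop[c] = cur[c] + sc * step(c);
      bool reject = truncate_ca && prop[0] < 0.0;
      if (!reject) {
        double sse_p = sess_sse(prop, flow, y, off[s], off[s + 1]);
        double dpri = 0.0;
        for (int c = 0; c < 3; ++c)
          dpri -= 0.5 * ((prop[c] - m[c]) * (prop[c] - m[c]) -
                         (cur[c] - m[c]) * (cur[c] - m[c])) / sig2_v(c);
        double lr = (cur_sse(s) - sse_p) * inv2s2 + dpri;
        if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
          for (int c = 0; c < 3; ++c) theta(s, c) = prop[c];
          cur_sse(s) = sse_p;
          acc(s)++;
        }
      }
    }
    if (warm && (it + 1) % 25 == 0) {
      double delta = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
      for (int s = 0; s < S; ++s) {
        double rate = att(s) ? (double)acc(s) / att(s) : 0.0;
        lstep(s) += (rate > 0.30 ? delta : -delta);
        acc(s) = 0; att(s) = 0;
      }
    }
    if (!warm) {
      for (int s = 0; s < S; ++s) { tot_acc += acc(s); tot_att += att(s); }
      acc.zeros(); att.zeros();
    }

    // --- level-shift move: beta0_c and every theta_.c jointly -------------
    // Translating the population intercept together with all session
    // parameters leaves every hierarchy residual unchanged, so only the
    // observation likelihood (and the flat beta0 prior, negligibly) moves.
    // This cuts through the strong cross-level coupling that makes the
    // intercepts mix slowly via per-session updates alone.
    // once the joint move is available, rotate through the per-component
    // shifts (one per sweep) to save likelihood passes
    for (int c = jshift_have ? it % 3 : 0;
         c < (jshift_have ? it % 3 + 1 : 3); ++c) {
      double dlt = std::exp(shift_lstep(c)) * R::norm_rand();
      bool reject = truncate_ca && c == 0 && (theta.col(0).min() + dlt) < 0.0;
      shift_att(c)++;
      if (!reject) {
        double dll = 0.0;
        for (int s = 0; s < S && std::isfinite(dll); ++s) {
          double prp3[3] = {theta(s, 0), theta(s, 1), theta(s, 2)};
          prp3[c] += dlt;
          prop_sse(s) = sess_sse(prp3, flow, y, off[s], off[s + 1]);
          dll += (cur_sse(s) - prop_sse(s)) * inv2s2;
        }
        double b_new = beta0(c) + dlt;
        dll += -0.5 * (b_new * b_new - beta0(c) * beta0(c)) / prior_var_beta;
        if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
          theta.col(c) += dlt;
          beta0(c) = b_new;
          cur_sse = prop_sse;
          shift_acc(c)++;
        }
      }
      if (warm && (it + 1) % 50 == 0) {
        double delta = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
        double rate = shift_att(c) ? (double)shift_acc(c) / shift_att(c) : 0.0;
        shift_lstep(c) += (rate > 0.35 ? delta : -delta);
        shift_acc(c) = 0; shift_att(c) = 0;
      }
    }
    // joint shift along the empirical beta0 covariance (all components of
    // beta0 and theta translated together), for the correlated intercept
    // ridge that axis-aligned shifts traverse slowly
    if (jshift_have) {
      arma::vec z = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
      arma::vec dlt = std::exp(jshift_lstep) * (jshift_L * z);
      bool reject = truncate_ca && (theta.col(0).min() + dlt(0)) < 0.0;
      jshift_att++;
      if (!reject) {
        double dll = 0.0;
        for (int s = 0; s < S && std::isfinite(dll); ++s) {
          double prp3[3];
          for (int c = 0; c < 3; ++c) prp3[c] = theta(s, c) + dlt(c);
          prop_sse(s) = sess_sse(prp3, flow, y, off[s], off[s + 1]);
          dll += (cur_sse(s) - prop_sse(s)) * inv2s2;
        }
        for (int c = 0; c < 3; ++c) {
          double b_new = beta0(c) + dlt(c);
          dll += -0.5 * (b_new * b_new - beta0(c) * beta0(c)) / prior_var_beta;
        }
        if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
          for (int c = 0; c < 3; ++c) theta.col(c) += dlt(c);
          beta0 += dlt;
          cur_sse = prop_sse;
          jshift_acc++;
        }
      }
    }
    // slope shift: beta1_c += delta_c, theta_sc += delta_c * x_s
    if (has_covariate && sshift_have) {
      arma::vec z = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
      arma::vec dlt = std::exp(sshift_lstep) * (sshift_L * z);
      sshift_att++;
      double dll = 0.0;
      for (int s = 0; s < S && std::isfinite(dll); ++s) {
        double prp3[3];
        for (int c = 0; c < 3; ++c) prp3[c] = theta(s, c) + dlt(c) * session_x[s];
        if (truncate_ca && prp3[0] < 0.0) { dll = -INFINITY; break; }
        prop_sse(s) = sess_sse(prp3, flow, y, off[s], off[s + 1]);
        dll += (cur_sse(s) - prop_sse(s)) * inv2s2;
      }
      if (std::isfinite(dll)) {
        for (int c = 0; c < 3; ++c) {
          double b_new = beta1(c) + dlt(c);
          dll += -0.5 * (b_new * b_new - beta1(c) * beta1(c)) / prior_var_beta;
        }
        if (std::log(R::unif_rand()) < dll) {
          for (int s = 0; s < S; ++s)
            for (int c = 0; c < 3; ++c) theta(s, c) += dlt(c) * session_x[s];
          beta1 += dlt;
          cur_sse = prop_sse;
          sshift_acc++;
        }
      }
    }
    if (warm) {
      b0_sum += beta0;
      b0_ss += beta0 * beta0.t();
      b0_n++;
      if (has_covariate) {
        b1_sum += beta1;
        b1_ss += beta1 * beta1.t();
        b1_n++;
      }
      if (b0_n >= 200 && (it + 1) % 100 == 0) {
        arma::vec mu = b0_sum / b0_n;
        arma::mat C = b0_ss / b0_n - mu * mu.t() + arma::eye(3, 3) * 1e-8;
        arma::mat L;
        if (arma::chol(L, C, "lower")) { jshift_L = L; jshift_have = true; }
        if (has_covariate) {
          arma::vec mu1 = b1_sum / b1_n;
          arma::mat C1 = b1_ss / b1_n - mu1 * mu1.t() + arma::eye(3, 3) * 1e-8;
          if (arma::chol(L, C1, "lower")) { sshift_L = L; sshift_have = true; }
        }
      }
      if (jshift_have && (it + 1) % 50 == 0) {
        double delta = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
        double rate = jshift_att ? (double)jshift_acc / jshift_att : 0.0;
        jshift_lstep += (rate > 0.30 ? delta : -delta);
        jshift_acc = 0; jshift_att = 0;
      }
      if (sshift_have && (it + 1) % 50 == 0) {
        double delta = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
        double rate = sshift_att ? (double)sshift_acc / sshift_att : 0.0;
        sshift_lstep += (rate > 0.30 ? delta : -delta);
        sshift_acc = 0; sshift_att = 0;
      }
    }

    // --- (Sigma_tau, sigma_v^2): collapsed adaptive MH --------------------
    {
      arma::mat rbar(n_part, 3, arma::fill::zeros);
      arma::mat wdiag(n_part, 3, arma::fill::zeros);
      arma::ivec nvis(n_part);
      for (int i = 0; i < n_part; ++i) {
        const std::vector<int>& ss = psess[i];
        nvis(i) = (int)ss.size();
        for (int s : ss)
          for (int c = 0; c < 3; ++c)
            rbar(i, c) += theta(s, c) - beta0(c) -
              (has_covariate ? beta1(c) * session_x[s] : 0.0);
        rbar.row(i) /= (double)ss.size();
        for (int s : ss)
          for (int c = 0; c < 3; ++c) {
            double dev = theta(s, c) - beta0(c) -
              (has_covariate ? beta1(c) * session_x[s] : 0.0) - rbar(i, c);
            wdiag(i, c) += dev * dev;
          }
      }
      double lp_cur = TV_logpost(phi, rbar, wdiag, nvis, iw_df, D,
                                 ig_shape, ig_rate);
      for (int k = 0; k < n_tv_steps; ++k) {
        arma::vec z(9);
        for (int c = 0; c < 9; ++c) z(c) = R::norm_rand();
        double sc = std::exp(tstep) * (k % 10 == 9 ? 3.0 : 1.0);
        arma::vec prop = phi + sc * (tv_have_cov ? tv_L * z : z);
        double lp_prop = TV_logpost(prop, rbar, wdiag, nvis, iw_df, D,
                                    ig_shape, ig_rate);
        t_att++;
        if (std::isfinite(lp_prop) &&
            std::log(R::unif_rand()) < lp_prop - lp_cur) {
          phi = prop;
          lp_cur = lp_prop;
          t_acc++;
          if (!warm) tv_acc_tot++;
        }
        if (!warm) tv_att_tot++;
      }
      if (warm) {
        tv_sum += phi;
        tv_ss += phi * phi.t();
        tv_n++;
        if ((it + 1) % 25 == 0) {
          double delta = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
          tstep += ((double)t_acc / t_att > 0.25 ? delta : -delta);
          t_acc = 0; t_att = 0;
        }
        if (tv_n >= 200 && (it + 1) % 100 == 0) {
          arma::vec mu = tv_sum / tv_n;
          arma::mat C = tv_ss / tv_n - mu * mu.t() +
            arma::eye(9, 9) * 1e-6;
          arma::mat L;
          if (arma::chol(L, C, "lower")) {
            tv_L = L;
            if (!tv_have_cov) { tv_have_cov = true; tstep = std::log(0.8); }
          }
        }
      }
      arma::mat Lt = phi_to_L(phi);
      Sigma_tau = Lt * Lt.t();
      sig2_v = arma::exp(phi.subvec(6, 8));
    }

    // --- beta: exact marginal Gaussian draw (alpha collapsed, GLS) --------
    {
      arma::mat Lam = arma::eye(p_beta, p_beta) / prior_var_beta;
      arma::vec rhs(p_beta, arma::fill::zeros);
      int last_n = -1;
      arma::mat Oinv;
      for (int i = 0; i < n_part; ++i) {
        const std::vector<int>& ss = psess[i];
        const int n = (int)ss.size();
        if (n != last_n) {
          arma::mat Om(3 * n, 3 * n, arma::fill::zeros);
          for (int j = 0; j < n; ++j)
            for (int j2 = 0; j2 < n; ++j2)
              for (int c = 0; c < 3; ++c)
                for (int c2 = 0; c2 < 3; ++c2) {
                  double v = Sigma_tau(c, c2);
                  if (j == j2 && c == c2) v += sig2_v(c);
                  Om(3 * j + c, 3 * j2 + c2) = v;
                }
          Oinv = arma::inv_sympd(Om);
          last_n = n;
        }
        arma::mat A(3 * n, p_beta, arma::fill::zeros);
        arma::vec yv(3 * n);
        for (int j = 0; j < n; ++j) {
          int s = ss[j];
          for (int c = 0; c < 3; ++c) {
            A(3 * j + c, c) = 1.0;
            if (has_covariate) A(3 * j + c, 3 + c) = session_x[s];
            yv(3 * j + c) = theta(s, c);
          }
        }
        arma::mat AtO = A.t() * Oinv;
        Lam += AtO * A;
        rhs += AtO * yv;
      }
      arma::mat Cov = arma::inv_sympd(Lam);
      arma::vec mu = Cov * rhs;
      arma::mat Lc = arma::chol(Cov, "lower");
      arma::vec z(p_beta);
      for (int c = 0; c < p_beta; ++c) z(c) = R::norm_rand();
      arma::vec b = mu + Lc * z;
      for (int c = 0; c < 3; ++c) beta0(c) = b(c);
      if (has_covariate)
        for (int c = 0; c < 3; ++c) beta1(c) = b(3 + c);
    }

    // --- alpha_i | theta, beta, Sigma_tau, sigma_v: conjugate MVN ---------
    arma::mat Tinv = arma::inv_sympd(Sigma_tau);
    arma::mat Vinv = arma::diagmat(1.0 / sig2_v);
    for (int i = 0; i < n_part; ++i) {
      const std::vector<int>& ss = psess[i];
      arma::vec rsum(3, arma::fill::zeros);
      for (int s : ss)
        for (int c = 0; c < 3; ++c)
          rsum(c) += (theta(s, c) - beta0(c) -
                      (has_covariate ? beta1(c) * session_x[s] : 0.0)) / sig2_v(c);
      arma::mat Prec = Tinv + (double)ss.size() * Vinv;
      arma::mat Cov = arma::inv_sympd(Prec);
      arma::vec mu = Cov * rsum;
      arma::mat L = arma::chol(Cov, "lower");
      arma::vec z(3);
      for (int c = 0; c < 3; ++c) z(c) = R::norm_rand();
      arma::vec a = mu + L * z;
      for (int c = 0; c < 3; ++c) alpha(i, c) = a(c);
    }

    // --- sigma_eps^2 | theta: inverse-gamma --------------------------------
    sig2_eps = rinvgamma(ig_shape + 0.5 * n_obs,
                         ig_rate + 0.5 * arma::accu(cur_sse));

    // --- store --------------------------------------------------------------
    if (!warm && ((it - n_warmup + 1) % thin == 0)) {
      int j = 0;
      for (int c = 0; c < 3; ++c) draws(kept, j++) = beta0(c);
      for (int c = 0; c < 3; ++c) draws(kept, j++) = beta1(c);
      arma::vec tsd = arma::sqrt(Sigma_tau.diag());
      for (int c = 0; c < 3; ++c) draws(kept, j++) = tsd(c);
      draws(kept, j++) = Sigma_tau(0, 1) / (tsd(0) * tsd(1));
      draws(kept, j++) = Sigma_tau(0, 2) / (tsd(0) * tsd(2));
      draws(kept, j++) = Sigma_tau(1, 2) / (tsd(1) * tsd(2));
      for (int c = 0; c < 3; ++c) draws(kept, j++) = std::sqrt(sig2_v(c));
      draws(kept, j++) = std::sqrt(sig2_eps);
      draws(kept, j++) = 0.0; // filled below
      theta_sum += theta;
      double cmin = theta.col(0).min();
      if (cmin < ca_min) ca_min = cmin;
      kept++;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  double arate = tot_att ? (double)tot_acc / tot_att : NA_REAL;
  for (int r = 0; r < kept; ++r) draws(r, P - 1) = arate;

  return List::create(_["draws"] = wrap(draws),
                      _["theta_mean"] = wrap(theta_sum / std::max(kept, 1)),
                      _["theta_ca_min"] = ca_min,
                      _["accept_rate"] = arate,
                      _["tv_accept_rate"] =
                        tv_att_tot ? (double)tv_acc_tot / tv_att_tot : NA_REAL);
}
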