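// Metropolis-within-Gibbs sampler for the mixed-effects location-scale model
// with Dirac spike-and-slab model comparison.
//
// Model variants (variant code):
//   0 plain      eta0i = eta0 + tau_sigma * lam_i
//   1 pick_group eta0i = eta0 + delta * tau_sigma * lam_i
//   2 membership eta0i = eta0 + tau_sigma * delta_i * lam_i
// with lam_i = z_mu[i]*rho + z_sigma[i]*sqrt(1-rho^2) and rho = tanh(z_f).
//
// The outcome likelihood is y_ij ~ N(beta0 + tau_mu*z_mu[i], exp(eta0i)),
// where exp(eta0i) is a VARIANCE, so the per-person log-likelihood only
// needs (J_i, sum y, sum y^2).
//
// Indicators use their exact Bernoulli full conditionals (Kuo-Mallick).
// While an indicator is zero, the parameters it gates have full
// conditionals equal to their priors and are refreshed by direct draws,
// which lets the chain re-enter the slab.
//
// Random-walk proposals adapt toward 0.44 acceptance in batches of 50
// during iterations <= adapt_until only, so the retained chain is a
// fixed-kernel Markov chain.  All randomness comes from R's RNG.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;
static const double ETA_CLAMP = 30.0;

struct PriorPars {
  double pi_incl;
  double b0_loc, b0_scale;
  double e0_loc, e0_scale;
  double tmu_df, tmu_scale;
  double tsig_df, tsig_scale;
  double zf_loc, zf_scale;
};

static inline double clamp_eta(double v) {
  if (v > ETA_CLAMP) return ETA_CLAMP;
  if (v < -ETA_CLAMP) return -ETA_CLAMP;
  return v;
}

// log N(y_i. | mean m, variance exp(v)) summed over person i's trials
static inline double pll(int Ji, double sy, double ssy, double m, double v) {
  v = clamp_eta(v);
  return -0.5 * Ji * (LOG2PI + v)
         - 0.5 * std::exp(-v) * (ssy - 2.0 * m * sy + Ji * m * m);
}

// half-Student-t log density (x >= 0), scale s, df nu
static inline double ldhalf_t(double x, double nu, double s) {
  if (x < 0.0) return R_NegInf;
  return M_LN2 + R::dt(x / s, nu, 1) - std::log(s);
}

static inline double rhalf_t(double nu, double s) {
  return std::fabs(R::rt(nu)) * s;
}

class Sampler {
public:
  IntegerVector J;
  NumericVector sy, ssy;
  int n, variant;
  PriorPars pr;
  double lw; // likelihood weight (0 = prior only)

  // state
  double b0, e0, tmu, tsig, zf, rho, sq1m;
  NumericVector zmu, zsig;
  IntegerVector delta; // length 1 (variant 0/1) or n (variant 2)

  // adaptation
  double ls_e0, ls_tmu, ls_tsig, ls_zf;
  NumericVector ls_zmu, ls_zsig;
  int acc_e0, acc_tmu, acc_tsig, acc_zf, try_e0, try_tmu, try_tsig, try_zf;
  IntegerVector acc_zmu, try_zmu, acc_zsig, try_zsig;
  // post-burn-in totals
  double tot_acc_e0, tot_try_e0, tot_acc_tmu, tot_try_tmu,
         tot_acc_tsig, tot_try_tsig, tot_acc_zf, tot_try_zf,
         tot_acc_z, tot_try_z;

  Sampler(IntegerVector J_, NumericVector sy_, NumericVector ssy_,
          int variant_, List prior, List init, double lw_)
    : J(J_), sy(sy_), ssy(ssy_), n(J_.size()), variant(variant_), lw(lw_) {
    pr.pi_incl   = as<double>(prior["pi"]);
    pr.b0_loc    = as<double>(prior["beta0_loc"]);
    pr.b0_scale  = as<double>(prior["beta0_scale"]);
    pr.e0_loc    = as<double>(prior["eta0_loc"]);
    pr.e0_scale  = as<double>(prior["eta0_scale"]);
    pr.tmu_df    = as<double>(prior["tau_mu_df"]);
    pr.tmu_scale = as<double>(prior["tau_mu_scale"]);
    pr.tsig_df   = as<double>(prior["tau_sigma_df"]);
    pr.tsig_scale= as<double>(prior["tau_sigma_scale"]);
    pr.zf_loc    = as<double>(prior["rho_fisher_loc"]);
    pr.zf_scale  = as<double>(prior["rho_fisher_scale"]);

    b0   = as<double>(init["beta0"]);
    e0   = as<double>(init["eta0"]);
    tmu  = as<double>(init["tau_mu"]);
    tsig = as<double>(init["tau_sigma"]);
    zf   = as<double>(init["z_f"]);
    zmu  = clone(as<NumericVector>(init["z_mu"]));
    zsig = clone(as<NumericVector>(init["z_sigma"]));
    delta = clone(as<IntegerVector>(init["delta"]));
    set_rho();

    ls_e0 = ls_tmu = ls_tsig = ls_zf = std::log(0.2);
    ls_zmu = NumericVector(n, std::log(0.2));
    ls_zsig = NumericVector(n, std::log(0.2));
    acc_e0 = acc_tmu = acc_tsig = acc_zf = 0;
    try_e0 = try_tmu = try_tsig = try_zf = 0;
    acc_zmu = IntegerVector(n); try_zmu = IntegerVector(n);
    acc_zsig = IntegerVector(n); try_zsig = IntegerVector(n);
    tot_acc_e0 = tot_try_e0 = tot_acc_tmu = tot_try_tmu = 0;
    tot_acc_tsig = tot_try_tsig = tot_acc_zf = tot_try_zf = 0;
    tot_acc_z = tot_try_z = 0;
  }

  void set_rho() { rho = std::tanh(zf); sq1m = std::sqrt(1.0 - rho * rho); }

  bool scale_active(int i) const {
    if (variant == 0) return true;
    if (variant == 1) return delta[0] == 1;
    return delta[i] == 1;
  }
  bool scale_active_any() const {
    if (variant == 0) return true;
    if (variant == 1) return delta[0] == 1;
    for (int i = 0; i < n; ++i) if (delta[i] == 1) return true;
    return false;
  }

  double eta_i(int i) const {
    if (!scale_active(i)) return e0;
    return e0 + tsig * (zmu[i] * rho + zsig[i] * sq1m);
  }
  // eta for person i with explicit parts (used in proposals)
  double eta_i_with(int i, double e0_, double tsig_, double rho_,
                    double sq1m_, double zmu_i, double zsig_i) const {
    if (!scale_active(i)) return e0_;
    return e0_ + tsig_ * (zmu_i * rho_ + zsig_i * sq1m_);
  }

  double total_ll() const {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      s += pll(J[i], sy[i], ssy[i], b0 + tmu * zmu[i], eta_i(i));
    return s;
  }

  void update_zmu(int i) {
    try_zmu[i]++; tot_try_z += 1.0;
    double cur = zmu[i];
    double prop = cur + std::exp(ls_zmu[i]) * norm_rand();
    double m_cur = b0 + tmu * cur, m_prop = b0 + tmu * prop;
    double v_cur = eta_i(i);
    double v_prop = eta_i_with(i, e0, tsig, rho, sq1m, prop, zsig[i]);
    double lr = lw * (pll(J[i], sy[i], ssy[i], m_prop, v_prop)
                      - pll(J[i], sy[i], ssy[i], m_cur, v_cur))
                + R::dnorm(prop, 0.0, 1.0, 1) - R::dnorm(cur, 0.0, 1.0, 1);
    if (std::log(unif_rand()) < lr) {
      zmu[i] = prop; acc_zmu[i]++; tot_acc_z += 1.0;
    }
  }

  void update_zsig(int i) {
    if (!scale_active(i)) { zsig[i] = norm_rand(); return; } // prior refresh
    try_zsig[i]++; tot_try_z += 1.0;
    double cur = zsig[i];
    double prop = cur + std::exp(ls_zsig[i]) * norm_rand();
    double m = b0 + tmu * zmu[i];
    double v_cur = eta_i(i);
    double v_prop = eta_i_with(i, e0, tsig, rho, sq1m, zmu[i], prop);
    double lr = lw * (pll(J[i], sy[i], ssy[i], m, v_prop)
                      - pll(J[i], sy[i], ssy[i], m, v_cur))
                + R::dnorm(prop, 0.0, 1.0, 1) - R::dnorm(cur, 0.0, 1.0, 1);
    if (std::log(unif_rand()) < lr) {
      zsig[i] = prop; acc_zsig[i]++; tot_acc_z += 1.0;
    }
  }

  void update_b0() { // exact conjugate normal draw
    double prec = 1.0 / (pr.b0_scale * pr.b0_scale);
    double num = pr.b0_loc * prec;
    for (int i = 0; i < n; ++i) {
      double w = lw * std::exp(-clamp_eta(eta_i(i)));
      prec += w * J[i];
      num += w * (sy[i] - J[i] * tmu * zmu[i]);
    }
    b0 = num / prec + norm_rand() / std::sqrt(prec);
  }

  void update_e0() {
    try_e0++; tot_try_e0 += 1.0;
    double prop = e0 + std::exp(ls_e0) * norm_rand();
    double ll_cur = total_ll();
    double e0_keep = e0; e0 = prop;
    double ll_prop = total_ll();
    double lr = lw * (ll_prop - ll_cur)
                + R::dnorm(prop, pr.e0_loc, pr.e0_scale, 1)
                - R::dnorm(e0_keep, pr.e0_loc, pr.e0_scale, 1);
    if (std::log(unif_rand()) < lr) { acc_e0++; tot_acc_e0 += 1.0; }
    else e0 = e0_keep;
  }

  void update_tmu() {
    try_tmu++; tot_try_tmu += 1.0;
    double prop = tmu + std::exp(ls_tmu) * norm_rand();
    if (prop < 0.0) return; // prior density 0
    double ll_cur = total_ll();
    double keep = tmu; tmu = prop;
    double ll_prop = total_ll();
    double lr = lw * (ll_prop - ll_cur)
                + ldhalf_t(prop, pr.tmu_df, pr.tmu_scale)
                - ldhalf_t(keep, pr.tmu_df, pr.tmu_scale);
    if (std::log(unif_rand()) < lr) { acc_tmu++; tot_acc_tmu += 1.0; }
    else tmu = keep;
  }

  void update_tsig() {
    if (!scale_active_any()) { tsig = rhalf_t(pr.tsig_df, pr.tsig_scale); return; }
    try_tsig++; tot_try_tsig += 1.0;
    double prop = tsig + std::exp(ls_tsig) * norm_rand();
    if (prop < 0.0) return;
    double ll_cur = total_ll();
    double keep = tsig; tsig = prop;
    double ll_prop = total_ll();
    double lr = lw * (ll_prop - ll_cur)
                + ldhalf_t(prop, pr.tsig_df, pr.tsig_scale)
                - ldhalf_t(keep, pr.tsig_df, pr.tsig_scale);
    if (std::log(unif_rand()) < lr) { acc_tsig++; tot_acc_tsig += 1.0; }
    else tsig = keep;
  }

  void update_zf() {
    if (!scale_active_any()) {
      zf = pr.zf_loc + pr.zf_scale * norm_rand(); set_rho(); return;
    }
    try_zf++; tot_try_zf += 1.0;
    double prop = zf + std::exp(ls_zf) * norm_rand();
    double ll_cur = total_ll();
    double keep_zf = zf, keep_rho = rho, keep_sq = sq1m;
    zf = prop; set_rho();
    double ll_prop = total_ll();
    double lr = lw * (ll_prop - ll_cur)
                + R::dnorm(prop, pr.zf_loc, pr.zf_scale, 1)
                - R::dnorm(keep_zf, pr.zf_loc, pr.zf_scale, 1);
    if (std::log(unif_rand()) < lr) { acc_zf++; tot_acc_zf += 1.0; }
    else { zf = keep_zf; rho = keep_rho; sq1m = keep_sq; }
  }

  void update_delta() {
    double lodds0 = std::log(pr.pi_incl) - std::log1p(-pr.pi_incl);
    if (variant == 1) {
      double ll1 = 0.0, ll0 = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = b0 + tmu * zmu[i];
        double lam = zmu[i] * rho + zsig[i] * sq1m;
        ll1 += pll(J[i], sy[i], ssy[i], m, e0 + tsig * lam);
        ll0 += pll(J[i], sy[i], ssy[i], m, e0);
      }
      double logit = lodds0 + lw * (ll1 - ll0);
      double p1 = 1.0 / (1.0 + std::exp(-logit));
      delta[0] = (unif_rand() < p1) ? 1 : 0;
    } else if (variant == 2) {
      for (int i = 0; i < n; ++i) {
        double m = b0 + tmu * zmu[i];
        double lam = zmu[i] * rho + zsig[i] * sq1m;
        double l1 = pll(J[i], sy[i], ssy[i], m, e0 + tsig * lam);
        double l0 = pll(J[i], sy[i], ssy[i], m, e0);
        double logit = lodds0 + lw * (l1 - l0);
        double p1 = 1.0 / (1.0 + std::exp(-logit));
        delta[i] = (unif_rand() < p1) ? 1 : 0;
      }
    }
  }

  void adapt(int batch_no) {
    double step = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
    adapt_one(ls_e0, acc_e0, try_e0, step);
    adapt_one(ls_tmu, acc_tmu, try_tmu, step);
    adapt_one(ls_tsig, acc_tsig, try_tsig, step);
    adapt_one(ls_zf, acc_zf, try_zf, step);
    for (int i = 0; i < n; ++i) {
      adapt_one_i(ls_zmu, acc_zmu, try_zmu, i, step);
      adapt_one_i(ls_zsig, acc_zsig, try_zsig, i, step);
    }
  }
  static void adapt_one(double &ls, int &acc, int &tries, double step) {
    if (tries > 0) {
      ls += ((double)acc / tries > 0.44) ? step : -step;
      acc = 0; tries = 0;
    }
  }
  static void adapt_one_i(NumericVector &ls, IntegerVector &acc,
                          IntegerVector &tries, int i, double step) {
    if (tries[i] > 0) {
      ls[i] += ((double)acc[i] / tries[i] > 0.44) ? step : -step;
      acc[i] = 0; tries[i] = 0;
    }
  }
};

// [[Rcpp::export(name = ".melsm_mcmc")]]
List melsm_mcmc(IntegerVector J, NumericVector sumy, NumericVector ssy,
                int variant, List prior, List init, LogicalVector update,
                int n_iter, int burn_in, int thin, int adapt_until,
                double lik_weight) {
  RNGScope scope;
  Sampler s(J, sumy, ssy, variant, prior, init, lik_weight);
  int n = s.n;
  // update flags: beta0, eta0, tau_mu, tau_sigma, z_f, z_mu, z_sigma, delta
  bool u_b0 = update[0], u_e0 = update[1], u_tmu = update[2],
       u_tsig = update[3], u_zf = update[4], u_zmu = update[5],
       u_zsig = update[6], u_delta = update[7];

  int n_delta = (variant == 2) ? n : 1;
  int n_par = 5 + 2 * n + n_delta;
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, n_par);
  int row = 0, batch = 0;

  for (int t = 1; t <= n_iter; ++t) {
    if (u_zmu) for (int i = 0; i < n; ++i) s.update_zmu(i);
    if (u_zsig) for (int i = 0; i < n; ++i) s.update_zsig(i);
    if (u_b0) s.update_b0();
    if (u_e0) s.update_e0();
    if (u_tmu) s.update_tmu();
    if (u_tsig) s.update_tsig();
    if (u_zf) s.update_zf();
    if (u_delta) s.update_delta();

    if (t <= adapt_until && t % 50 == 0) s.adapt(++batch);

    if (t > burn_in && (t - burn_in) % thin == 0) {
      out(row, 0) = s.b0; out(row, 1) = s.e0; out(row, 2) = s.tmu;
      out(row, 3) = s.tsig; out(row, 4) = s.rho;
      for (int i = 0; i < n; ++i) {
        out(row, 5 + i) = s.zmu[i];
        out(row, 5 + n + i) = s.zsig[i];
      }
      for (int k = 0; k < n_delta; ++k) out(row, 5 + 2 * n + k) = s.delta[k];
      ++row;
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc = NumericVector::create(
    _["eta0"] = s.tot_try_e0 > 0 ? s.tot_acc_e0 / s.tot_try_e0 : NA_REAL,
    _["tau_mu"] = s.tot_try_tmu > 0 ? s.tot_acc_tmu / s.tot_try_tmu : NA_REAL,
    _["tau_sigma"] = s.tot_try_tsig > 0 ? s.tot_acc_tsig / s.tot_try_tsig : NA_REAL,
    _["z_f"] = s.tot_try_zf > 0 ? s.tot_acc_zf / s.tot_try_zf : NA_REAL,
    _["z"] = s.tot_try_z > 0 ? s.tot_acc_z / s.tot_try_z : NA_REAL);

  return List::create(_["draws"] = out, _["accept"] = acc);
}
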