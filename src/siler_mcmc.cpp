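#include <Rcpp.h>
using namespace Rcpp;

// Siler hazard: mu(x) = exp(a0 - a1 x) + c + exp(b0 + b1 x)
// Closed-form cumulative hazard U(x); both guarded against overflow so that
// a proposal wandering into an absurd region yields -Inf log-likelihood
// (reject) rather than NaN propagation.

static inline double siler_U(double a0, double a1, double c, double b0,
                             double b1, double x) {
  return std::exp(a0) / a1 * (1.0 - std::exp(-a1 * x)) + c * x +
         std::exp(b0) / b1 * (std::exp(b1 * x) - 1.0);
}

static inline double siler_logmu(double a0, double a1, double c, double b0,
                                 double b1, double x) {
  return std::log(std::exp(a0 - a1 * x) + c + std::exp(b0 + b1 * x));
}

// log-likelihood of one record under left truncation + right censoring,
// with a proportional-hazards multiplier eg = exp(gamma_z):
//   death:    log mu(x) + log eg - eg * (U(x) - U(xt))
//   censored:                    - eg * (U(x) - U(xt))
static inline double record_ll(double a0, double a1, double c, double b0,
                               double b1, double x, double xt, int death,
                               double eg) {
  double dU = siler_U(a0, a1, c, b0, b1, x) - siler_U(a0, a1, c, b0, b1, xt);
  double ll = -eg * dU;
  if (death)
    ll += siler_logmu(a0, a1, c, b0, b1, x) + std::log(eg);
  return ll;
}

// Cohort log-likelihood: the compiled route checked against the pure-R
// cohort_loglik() in the tests, and the workhorse of the mode finder.
// [[Rcpp::export]]
double cpp_cohort_loglik(NumericVector theta, NumericVector x,
                         NumericVector xt, IntegerVector death,
                         NumericVector eg) {
  const double a0 = theta[0], a1 = theta[1], c = theta[2], b0 = theta[3],
               b1 = theta[4];
  double tot = 0.0;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    double ll = record_ll(a0, a1, c, b0, b1, x[i], xt[i], death[i], eg[i]);
    if (!std::isfinite(ll)) return R_NegInf;
    tot += ll;
  }
  return tot;
}

// z -> theta: z = (a0, log a1, log c, b0, log b1)
static inline void z_to_theta(const double *z, double *th) {
  th[0] = z[0];
  th[1] = std::exp(z[1]);
  th[2] = std::exp(z[2]);
  th[3] = z[3];
  th[4] = std::exp(z[4]);
}

static double fill_ll(const double *z, const NumericVector &entry_t,
                      const NumericVector &depart_t,
                      const NumericVector &birth, const IntegerVector &death,
                      const std::vector<double> &eg_level,
                      const IntegerVector &level, std::vector<double> &buf) {
  double th[5];
  z_to_theta(z, th);
  const int n = depart_t.size();
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double x = depart_t[i] - birth[i];
    double xt = entry_t[i] - birth[i];
    if (xt < 0.0) xt = 0.0;
    double ll = record_ll(th[0], th[1], th[2], th[3], th[4], x, xt, death[i],
                          eg_level[level[i]]);
    if (!std::isfinite(ll)) return R_NegInf;
    buf[i] = ll;
    tot += ll;
  }
  return tot;
}

// Metropolis-Hastings sampler for one chain.
//
// Mortality parameters are sampled on the unconstrained scale
// z = (a0, log a1, log c, b0, log b1) -- positivity is automatic and the
// prior picks up the log-scale Jacobian. Each iteration performs (i) one
// Gaussian random-walk update per coordinate of z (and per gamma
// coefficient), (ii) optionally one joint random-walk proposal
// z' = z + s_joint * L eps with L a Cholesky factor supplied from the
// curvature of the log-posterior at its mode, which handles the strong
// a0-a1 and b0-b1 ridges, and (iii) an independence-proposal update of
// each latent birth time, uniform on its interval (prior and proposal
// cancel). Per-coordinate scales and the joint scale factor adapt during
// burn-in toward `target_acc`, then freeze. Uses R's RNG so chains are
// reproducible from set.seed() on the R side.
// [[Rcpp::export]]
List cpp_siler_mh(NumericVector entry_t, NumericVector depart_t,
                  NumericVector birth0, IntegerVector death,
                  IntegerVector level, int n_levels,
                  IntegerVector unknown_idx, NumericVector bmin,
                  NumericVector bmax, NumericVector z0,
                  NumericVector gamma0, NumericVector prior_mean,
                  NumericVector prior_sd, double gamma_prior_sd, int n_iter,
                  int burn_in, int thin, NumericVector prop_sd0,
                  NumericMatrix joint_L, bool use_joint, int adapt_interval,
                  double target_acc) {
  const int n = depart_t.size();
  const int n_gamma = n_levels - 1;  // may be 0
  const int n_par = 5 + n_gamma;
  const int n_unk = unknown_idx.size();
  const int n_ret = (n_iter - burn_in) / thin;

  std::vector<double> z(5), gam(std::max(n_gamma, 0));
  for (int j = 0; j < 5; ++j) z[j] = z0[j];
  for (int j = 0; j < n_gamma; ++j) gam[j] = gamma0[j];
  NumericVector birth = clone(birth0);

  std::vector<double> eg_level(n_levels, 1.0);
  for (int zl = 1; zl < n_levels; ++zl) eg_level[zl] = std::exp(gam[zl - 1]);

  // log prior in z space: Normal on a0, b0; half-Normal kernels on the
  // positive parameters plus the Jacobian z of the log transform.
  auto log_prior = [&](const std::vector<double> &zz,
                       const std::vector<double> &g) {
    double lp = 0.0;
    const int pos_idx[3] = {1, 2, 4};
    for (int k = 0; k < 3; ++k) {
      int j = pos_idx[k];
      double t = std::exp(zz[j]);
      double s = prior_sd[j];
      lp += -0.5 * t * t / (s * s) + zz[j];
    }
    for (int k = 0; k < 2; ++k) {
      int j = k == 0 ? 0 : 3;
      double s = prior_sd[j];
      double d = zz[j] - prior_mean[j];
      lp += -0.5 * d * d / (s * s);
    }
    for (int j = 0; j < n_gamma; ++j)
      lp += -0.5 * g[j] * g[j] / (gamma_prior_sd * gamma_prior_sd);
    return lp;
  };

  std::vector<double> buf(n), buf_prop(n);
  double cur_ll = fill_ll(z.data(), entry_t, depart_t, birth, death,
                          eg_level, level, buf);
  if (!std::isfinite(cur_ll))
    stop("initial parameter values give non-finite log-likelihood");
  double cur_lp = log_prior(z, gam);

  std::vector<double> prop_sd(n_par);
  for (int j = 0; j < n_par; ++j) prop_sd[j] = prop_sd0[j];
  double joint_scale = 1.0;
  std::vector<int> acc_win(n_par, 0), acc_tot(n_par, 0);
  int joint_acc_win = 0, joint_acc_tot = 0;
  long birth_acc = 0, birth_prop = 0;

  NumericMatrix draws(n_ret, n_par);
  NumericMatrix birth_draws(n_unk > 0 ? n_ret : 0, n_unk);
  int ret = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- per-coordinate z and gamma updates ---
    for (int j = 0; j < n_par; ++j) {
      std::vector<double> z_p(z), gam_p(gam);
      if (j < 5)
        z_p[j] = z[j] + R::rnorm(0.0, prop_sd[j]);
      else
        gam_p[j - 5] = gam[j - 5] + R::rnorm(0.0, prop_sd[j]);
      double lp_p = log_prior(z_p, gam_p);
      std::vector<double> eg_p(eg_level);
      if (j >= 5)
        for (int zl = 1; zl < n_levels; ++zl)
          eg_p[zl] = std::exp(gam_p[zl - 1]);
      double ll_p = fill_ll(z_p.data(), entry_t, depart_t, birth, death,
                            eg_p, level, buf_prop);
      double lr = (ll_p + lp_p) - (cur_ll + cur_lp);
      if (std::isfinite(ll_p) && std::log(R::runif(0.0, 1.0)) < lr) {
        z = z_p;
        gam = gam_p;
        eg_level = eg_p;
        cur_ll = ll_p;
        cur_lp = lp_p;
        buf.swap(buf_prop);
        ++acc_win[j];
        ++acc_tot[j];
      }
    }

    // --- joint update along the curvature of the posterior ---
    if (use_joint) {
      double eps[5];
      for (int j = 0; j < 5; ++j) eps[j] = R::rnorm(0.0, 1.0);
      std::vector<double> z_p(z);
      for (int j = 0; j < 5; ++j) {
        double step = 0.0;
        for (int k = 0; k <= j; ++k) step += joint_L(j, k) * eps[k];
        z_p[j] += joint_scale * step;
      }
      double lp_p = log_prior(z_p, gam);
      double ll_p = fill_ll(z_p.data(), entry_t, depart_t, birth, death,
                            eg_level, level, buf_prop);
      double lr = (ll_p + lp_p) - (cur_ll + cur_lp);
      if (std::isfinite(ll_p) && std::log(R::runif(0.0, 1.0)) < lr) {
        z = z_p;
        cur_ll = ll_p;
        cur_lp = lp_p;
        buf.swap(buf_prop);
        ++joint_acc_win;
        ++joint_acc_tot;
      }
    }

    // --- latent birth-time updates ---
    double th[5];
    z_to_theta(z.data(), th);
    for (int k = 0; k < n_unk; ++k) {
      int i = unknown_idx[k];
      double b_new = R::runif(bmin[i], bmax[i]);
      double x = depart_t[i] - b_new;
      double xt = entry_t[i] - b_new;
      if (xt < 0.0) xt = 0.0;
      double ll_new = record_ll(th[0], th[1], th[2], th[3], th[4], x, xt,
                                death[i], eg_level[level[i]]);
      ++birth_prop;
      if (std::isfinite(ll_new) &&
          std::log(R::runif(0.0, 1.0)) < ll_new - buf[i]) {
        cur_ll += ll_new - buf[i];
        buf[i] = ll_new;
        birth[i] = b_new;
        ++birth_acc;
      }
    }

    // --- proposal adaptation during burn-in ---
    if (it < burn_in && (it + 1) % adapt_interval == 0) {
      for (int j = 0; j < n_par; ++j) {
        double rate = (double)acc_win[j] / adapt_interval;
        prop_sd[j] *= std::exp(1.2 * (rate - target_acc));
        if (prop_sd[j] < 1e-6) prop_sd[j] = 1e-6;
        if (prop_sd[j] > 10.0) prop_sd[j] = 10.0;
        acc_win[j] = 0;
      }
      if (use_joint) {
        double rate = (double)joint_acc_win / adapt_interval;
        joint_scale *= std::exp(1.2 * (rate - target_acc));
        if (joint_scale < 1e-4) joint_scale = 1e-4;
        if (joint_scale > 50.0) joint_scale = 50.0;
        joint_acc_win = 0;
      }
    }
    if (it == burn_in - 1) {
      for (int j = 0; j < n_par; ++j) {
        if (acc_tot[j] == 0)
          stop("all proposals rejected for parameter %d during burn-in; "
               "rescale proposal_sd or check the data", j + 1);
        acc_tot[j] = 0;  // report post-burn-in acceptance
      }
      joint_acc_tot = 0;
    }

    // --- retain ---
    if (it >= burn_in && (it - burn_in) % thin == thin - 1 && ret < n_ret) {
      double tho[5];
      z_to_theta(z.data(), tho);
      for (int j = 0; j < 5; ++j) draws(ret, j) = tho[j];
      for (int j = 0; j < n_gamma; ++j) draws(ret, 5 + j) = gam[j];
      for (int k = 0; k < n_unk; ++k)
        birth_draws(ret, k) = birth[unknown_idx[k]];
      ++ret;
    }
  }

  NumericVector acc(n_par);
  int post = n_iter - burn_in;
  for (int j = 0; j < n_par; ++j) acc[j] = (double)acc_tot[j] / post;

  return List::create(
      _["draws"] = draws, _["birth_draws"] = birth_draws,
      _["acceptance"] = acc,
      _["joint_acceptance"] =
          use_joint ? (double)joint_acc_tot / post : NA_REAL,
      _["birth_acceptance"] =
          birth_prop > 0 ? (double)birth_acc / birth_prop : NA_REAL,
      _["prop_sd"] = NumericVector(prop_sd.begin(), prop_sd.end()),
      _["joint_scale"] = joint_scale, _["loglik_final"] = cur_ll);
}
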