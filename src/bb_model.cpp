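#include <Rcpp.h>
using namespace Rcpp;

// Beta-binomial model core.
//
// Counts are small integers, so every lgamma/digamma/trigamma difference in
// the beta-binomial likelihood reduces to a short sum of logs/reciprocals
// via the recurrence psi(x+k) - psi(x) = sum 1/(x+j). Observations within a
// feature are pooled into tail-count histograms once per call, making each
// likelihood/gradient/Hessian sweep O(max n) per feature instead of
// O(cells) special-function calls.
//
// Two parameter spaces are used:
//  * centered per-feature (z_j = logit mu_j, t_j = logit gamma_j) for the
//    Laplace-marginal fit (globals estimated with latents integrated out);
//  * non-centered joint (zeta, eta, globals) for the MCMC sampler.

static const double CLAMP_LO = 1e-6;
static const double CLAMP_HI = 1.0 - 1e-6;

static inline double clamp01(double x) {
  if (x < CLAMP_LO) return CLAMP_LO;
  if (x > CLAMP_HI) return CLAMP_HI;
  return x;
}

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// full beta-binomial log pmf (lgamma form, used by the exported functions);
// gamma is clamped far looser than in the inference paths so the gamma -> 0
// binomial limit is numerically faithful
static inline double bb_logpmf_one(double y, double n, double mu, double g) {
  mu = clamp01(mu);
  if (g < 1e-10) g = 1e-10;
  if (g > CLAMP_HI) g = CLAMP_HI;
  double lam = (1.0 - g) / g;
  double a = mu * lam, b = (1.0 - mu) * lam;
  return R::lchoose(n, y) + R::lgammafn(y + a) + R::lgammafn(n - y + b) -
         R::lgammafn(n + a + b) - R::lgammafn(a) - R::lgammafn(b) +
         R::lgammafn(a + b);
}

// [[Rcpp::export]]
NumericVector cpp_bb_logpmf(NumericVector y, NumericVector n,
                            NumericVector mu, NumericVector gamma) {
  R_xlen_t m = y.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = bb_logpmf_one(y[i], n[i], mu[i], gamma[i]);
  return out;
}

// [[Rcpp::export]]
double cpp_bb_loglik_sum(NumericVector y, NumericVector n,
                         double mu, double gamma) {
  double s = 0.0;
  for (R_xlen_t i = 0; i < y.size(); ++i)
    s += bb_logpmf_one(y[i], n[i], mu, gamma);
  return s;
}

struct ModelData {
  const NumericMatrix &X;
  const NumericVector &centers;
  double h;
  const NumericVector &hyper; // w_mu_mean, w_mu_sd, w_g_mean, w_g_sd, s_mu_scale, s_g_scale
  int J, P, L, G;
  // pooled tail counts per feature: cy[k] = #obs with y >= k+1, etc.
  std::vector<double> cy, cny, cn;
  std::vector<int> oy, ony, on; // offsets, length J+1
  ModelData(const NumericVector &yv, const NumericVector &nv,
            const IntegerVector &fptr, const NumericMatrix &X_,
            const NumericVector &centers_, double h_,
            const NumericVector &hyper_)
    : X(X_), centers(centers_), h(h_), hyper(hyper_) {
    J = fptr.size() - 1;
    P = X.ncol();
    L = centers.size() + 1;
    G = P + L + 2;
    oy.resize(J + 1);
    ony.resize(J + 1);
    on.resize(J + 1);
    oy[0] = ony[0] = on[0] = 0;
    for (int j = 0; j < J; ++j) {
      int my = 0, mny = 0, mn = 0;
      for (int i = fptr[j]; i < fptr[j + 1]; ++i) {
        int y = (int)yv[i], n = (int)nv[i];
        if (y > my) my = y;
        if (n - y > mny) mny = n - y;
        if (n > mn) mn = n;
      }
      oy[j + 1] = oy[j] + my;
      ony[j + 1] = ony[j] + mny;
      on[j + 1] = on[j] + mn;
    }
    cy.assign(oy[J], 0.0);
    cny.assign(ony[J], 0.0);
    cn.assign(on[J], 0.0);
    for (int j = 0; j < J; ++j) {
      for (int i = fptr[j]; i < fptr[j + 1]; ++i) {
        int y = (int)yv[i], n = (int)nv[i];
        for (int k = 0; k < y; ++k) cy[oy[j] + k] += 1.0;
        for (int k = 0; k < n - y; ++k) cny[ony[j] + k] += 1.0;
        for (int k = 0; k < n; ++k) cn[on[j] + k] += 1.0;
      }
    }
  }
  // feature log likelihood at (a, b), up to the binomial-coefficient const
  double lik(int j, double a, double b) const {
    double s = 0.0;
    for (int k = oy[j]; k < oy[j + 1]; ++k)
      s += cy[k] * std::log(a + (k - oy[j]));
    for (int k = ony[j]; k < ony[j + 1]; ++k)
      s += cny[k] * std::log(b + (k - ony[j]));
    for (int k = on[j]; k < on[j + 1]; ++k)
      s -= cn[k] * std::log(a + b + (k - on[j]));
    return s;
  }
  // first derivatives wrt (a, b)
  void lik_AB(int j, double a, double b, double &A, double &B) const {
    A = 0.0;
    B = 0.0;
    double C = 0.0;
    for (int k = oy[j]; k < oy[j + 1]; ++k) A += cy[k] / (a + (k - oy[j]));
    for (int k = ony[j]; k < ony[j + 1]; ++k)
      B += cny[k] / (b + (k - ony[j]));
    for (int k = on[j]; k < on[j + 1]; ++k) C += cn[k] / (a + b + (k - on[j]));
    A -= C;
    B -= C;
  }
  // first and second derivatives wrt (a, b)
  void lik_AB2(int j, double a, double b, double &A, double &B, double &Laa,
               double &Lbb, double &Lab) const {
    A = B = Laa = Lbb = Lab = 0.0;
    double C = 0.0, C2 = 0.0;
    for (int k = oy[j]; k < oy[j + 1]; ++k) {
      double r = 1.0 / (a + (k - oy[j]));
      A += cy[k] * r;
      Laa -= cy[k] * r * r;
    }
    for (int k = ony[j]; k < ony[j + 1]; ++k) {
      double r = 1.0 / (b + (k - ony[j]));
      B += cny[k] * r;
      Lbb -= cny[k] * r * r;
    }
    for (int k = on[j]; k < on[j + 1]; ++k) {
      double r = 1.0 / (a + b + (k - on[j]));
      C += cn[k] * r;
      C2 += cn[k] * r * r;
    }
    A -= C;
    B -= C;
    Laa += C2;
    Lbb += C2;
    Lab = C2;
  }
};

static double wg_trend(double mu, const double *wg, const ModelData &md) {
  double u = wg[0];
  double h2 = 2.0 * md.h * md.h;
  for (int l = 0; l < md.L - 1; ++l) {
    double d = mu - md.centers[l];
    u += wg[l + 1] * std::exp(-d * d / h2);
  }
  return u;
}

// ---------------------------------------------------------------------------
// Laplace-marginal machinery (centered per-feature space)

struct Globals {
  const double *wmu, *wg;
  double s_mu, s_g, ls_mu, ls_g;
};

static Globals unpack_globals(const double *gpar, const ModelData &md) {
  Globals g;
  g.wmu = gpar;
  g.wg = gpar + md.P;
  g.ls_mu = gpar[md.P + md.L];
  g.ls_g = gpar[md.P + md.L + 1];
  g.s_mu = std::exp(g.ls_mu);
  g.s_g = std::exp(g.ls_g);
  return g;
}

static double feat_centered_lp(int j, double z, double t, double m_j,
                               const Globals &g, const ModelData &md) {
  double mu = clamp01(invlogit(z));
  double gam = clamp01(invlogit(t));
  double lam = (1.0 - gam) / gam;
  double lp = md.lik(j, mu * lam, (1.0 - mu) * lam);
  double f = wg_trend(mu, g.wg, md);
  double dz = (z - m_j) / g.s_mu, dt = (t - f) / g.s_g;
  lp += -0.5 * dz * dz - g.ls_mu - 0.5 * dt * dt - g.ls_g;
  return lp;
}

// analytic gradient and Hessian of lp_j(z, t | g) in a single sweep
static void feat_grad_hess(int j, double z, double t, double m_j,
                           const Globals &g, const ModelData &md,
                           double &gz, double &gt, double &hzz, double &hzt,
                           double &htt) {
  double mu = clamp01(invlogit(z));
  double gam = clamp01(invlogit(t));
  double lam = (1.0 - gam) / gam;
  double a = mu * lam, b = (1.0 - mu) * lam;
  double A, B, Laa, Lbb, Lab;
  md.lik_AB2(j, a, b, A, B, Laa, Lbb, Lab);
  double g2 = gam * gam, g3 = g2 * gam;
  double a_g = -mu / g2, b_g = -(1.0 - mu) / g2;
  double l_mu = lam * (A - B);
  double l_g = A * a_g + B * b_g;
  double l_mumu = lam * lam * (Laa - 2.0 * Lab + Lbb);
  double l_mug = lam * (Laa * a_g + Lab * b_g - Lab * a_g - Lbb * b_g) +
                 (B - A) / g2;
  double l_gg = a_g * a_g * Laa + 2.0 * a_g * b_g * Lab + b_g * b_g * Lbb +
                A * 2.0 * mu / g3 + B * 2.0 * (1.0 - mu) / g3;
  double dmudz = mu * (1.0 - mu);
  double d2mudz2 = dmudz * (1.0 - 2.0 * mu);
  double dgdt = gam * (1.0 - gam);
  double d2gdt2 = dgdt * (1.0 - 2.0 * gam);
  double F = g.wg[0], Fp = 0.0, Fpp = 0.0;
  double hh = md.h * md.h;
  for (int l = 0; l < md.L - 1; ++l) {
    double d = mu - md.centers[l];
    double gl = std::exp(-d * d / (2.0 * hh));
    F += g.wg[l + 1] * gl;
    Fp += g.wg[l + 1] * gl * (-d / hh);
    Fpp += g.wg[l + 1] * gl * ((d * d) / (hh * hh) - 1.0 / hh);
  }
  double F_z = Fp * dmudz;
  double F_zz = Fpp * dmudz * dmudz + Fp * d2mudz2;
  double smu2 = g.s_mu * g.s_mu, sg2 = g.s_g * g.s_g;
  double tres = (t - F) / sg2;
  gz = l_mu * dmudz - (z - m_j) / smu2 + tres * F_z;
  gt = l_g * dgdt - tres;
  double lzz = l_mumu * dmudz * dmudz + l_mu * d2mudz2 - 1.0 / smu2 +
               ((t - F) * F_zz - F_z * F_z) / sg2;
  double lzt = l_mug * dmudz * dgdt + F_z / sg2;
  double ltt = l_gg * dgdt * dgdt + l_g * d2gdt2 - 1.0 / sg2;
  hzz = -lzz;
  hzt = -lzt;
  htt = -ltt;
}

// damped Newton to the conditional mode of (z_j, t_j); returns the negative
// Hessian at the mode through hzz/hzt/htt
static void feat_inner_newton(int j, double &z, double &t, double m_j,
                              const Globals &g, const ModelData &md,
                              double &hzz, double &hzt, double &htt,
                              int max_iter = 30, double tol = 1e-6) {
  double gz, gt;
  for (int it = 0; it < max_iter; ++it) {
    feat_grad_hess(j, z, t, m_j, g, md, gz, gt, hzz, hzt, htt);
    if (std::fabs(gz) < tol && std::fabs(gt) < tol) return;
    // make the (negative) Hessian positive definite if needed
    double det = hzz * htt - hzt * hzt;
    if (hzz <= 0 || det <= 0) {
      double ridge = 1e-3 + std::max(0.0, -std::min(hzz, htt));
      hzz += ridge;
      htt += ridge;
      det = hzz * htt - hzt * hzt;
    }
    double dz = (htt * gz - hzt * gt) / det;
    double dt = (-hzt * gz + hzz * gt) / det;
    double cap = 4.0; // keep logit steps sane
    double mx = std::max(std::fabs(dz), std::fabs(dt));
    if (mx > cap) {
      dz *= cap / mx;
      dt *= cap / mx;
    }
    double lp0 = feat_centered_lp(j, z, t, m_j, g, md);
    double step = 1.0;
    for (int hlv = 0; hlv < 8; ++hlv) {
      double zn = z + step * dz, tn = t + step * dt;
      if (feat_centered_lp(j, zn, tn, m_j, g, md) >= lp0 - 1e-12) {
        z = zn;
        t = tn;
        break;
      }
      step *= 0.5;
      if (hlv == 7) return; // no improving step: accept current point
    }
  }
}

static double global_log_prior(const double *gpar, const ModelData &md) {
  const double wmm = md.hyper[0], wms = md.hyper[1], wgm = md.hyper[2],
               wgs = md.hyper[3], sma = md.hyper[4], sga = md.hyper[5];
  const int P = md.P, L = md.L;
  double lp = 0.0;
  for (int p = 0; p < P; ++p) {
    double d = (gpar[p] - wmm) / wms;
    lp -= 0.5 * d * d;
  }
  for (int l = 0; l < L; ++l) {
    double d = (gpar[P + l] - wgm) / wgs;
    lp -= 0.5 * d * d;
  }
  double s_mu = std::exp(gpar[P + L]), s_g = std::exp(gpar[P + L + 1]);
  lp += -0.5 * (s_mu / sma) * (s_mu / sma) + gpar[P + L];
  lp += -0.5 * (s_g / sga) * (s_g / sga) + gpar[P + L + 1];
  return lp;
}

// negative Laplace-marginal log posterior of the globals; `warm` (J x 2,
// modified in place) carries the inner modes across calls for warm starts
// [[Rcpp::export]]
double cpp_marginal_nlp(NumericVector gpar, NumericVector yv,
                        NumericVector nv, IntegerVector fptr, NumericMatrix X,
                        NumericVector centers, double h, NumericVector hyper,
                        NumericMatrix warm) {
  ModelData md(yv, nv, fptr, X, centers, h, hyper);
  Globals g = unpack_globals(REAL(gpar), md);
  double lp = global_log_prior(REAL(gpar), md);
  for (int j = 0; j < md.J; ++j) {
    double m_j = 0.0;
    for (int p = 0; p < md.P; ++p) m_j += md.X(j, p) * g.wmu[p];
    double z = warm(j, 0), t = warm(j, 1);
    double hzz, hzt, htt;
    feat_inner_newton(j, z, t, m_j, g, md, hzz, hzt, htt);
    warm(j, 0) = z;
    warm(j, 1) = t;
    double det = hzz * htt - hzt * hzt;
    if (det <= 0 || hzz <= 0) det = 1e-6; // degenerate mode: flat fallback
    lp += feat_centered_lp(j, z, t, m_j, g, md) - 0.5 * std::log(det);
  }
  return -lp;
}

// per-feature conditional modes, covariances and marginal contributions
// [[Rcpp::export]]
NumericMatrix cpp_feature_laplace(NumericVector gpar, NumericVector yv,
                                  NumericVector nv, IntegerVector fptr,
                                  NumericMatrix X, NumericVector centers,
                                  double h, NumericVector hyper,
                                  NumericMatrix warm) {
  ModelData md(yv, nv, fptr, X, centers, h, hyper);
  Globals g = unpack_globals(REAL(gpar), md);
  // columns: z, t, var_z, cov_zt, var_t, laplace_contribution
  NumericMatrix out(md.J, 6);
  for (int j = 0; j < md.J; ++j) {
    double m_j = 0.0;
    for (int p = 0; p < md.P; ++p) m_j += md.X(j, p) * g.wmu[p];
    double z = warm(j, 0), t = warm(j, 1);
    double hzz, hzt, htt;
    feat_inner_newton(j, z, t, m_j, g, md, hzz, hzt, htt);
    warm(j, 0) = z;
    warm(j, 1) = t;
    double det = hzz * htt - hzt * hzt;
    out(j, 0) = z;
    out(j, 1) = t;
    if (det <= 0 || hzz <= 0) {
      // degenerate curvature: fall back to prior-scale uncertainty
      out(j, 2) = g.s_mu * g.s_mu;
      out(j, 3) = 0.0;
      out(j, 4) = g.s_g * g.s_g;
      out(j, 5) = feat_centered_lp(j, z, t, m_j, g, md) -
                  0.5 * std::log(1e-6);
      continue;
    }
    out(j, 2) = htt / det;
    out(j, 3) = -hzt / det;
    out(j, 4) = hzz / det;
    out(j, 5) = feat_centered_lp(j, z, t, m_j, g, md) - 0.5 * std::log(det);
  }
  return out;
}

// ---------------------------------------------------------------------------
// non-centered joint machinery (MCMC)

// feature likelihood at natural (z, e) where gamma = invlogit(f(mu) + e)
static double feat_loglik_nc(int j, double z, double e, const double *wg,
                             const ModelData &md) {
  double mu = clamp01(invlogit(z));
  double u = wg_trend(mu, wg, md);
  double g = clamp01(invlogit(u + e));
  double lam = (1.0 - g) / g;
  return md.lik(j, mu * lam, (1.0 - mu) * lam);
}

// joint non-centered log posterior
static double joint_lp(const double *par, const ModelData &md) {
  const int J = md.J, P = md.P, L = md.L;
  const double *wmu = par + 2 * J;
  const double *wg = par + 2 * J + P;
  double s_mu = std::exp(par[2 * J + P + L]);
  double s_g = std::exp(par[2 * J + P + L + 1]);
  double lp = global_log_prior(par + 2 * J, md);
  for (int j = 0; j < J; ++j) {
    double zeta = par[j], eta = par[J + j];
    double m = 0.0;
    for (int p = 0; p < P; ++p) m += md.X(j, p) * wmu[p];
    lp += feat_loglik_nc(j, m + s_mu * zeta, s_g * eta, wg, md);
    lp += -0.5 * zeta * zeta - 0.5 * eta * eta;
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_joint_nlp(NumericVector par, NumericVector yv, NumericVector nv,
                     IntegerVector fptr, NumericMatrix X,
                     NumericVector centers, double h, NumericVector hyper) {
  ModelData md(yv, nv, fptr, X, centers, h, hyper);
  return -joint_lp(REAL(par), md);
}

// likelihood gradient on the natural scale (z, e)
static void feat_natural_grad(int j, double z, double e, const double *wg,
                              const ModelData &md, double &gz, double &ge) {
  double mu = clamp01(invlogit(z));
  double h2 = 2.0 * md.h * md.h;
  double u = wg[0], fpmu = 0.0;
  for (int l = 0; l < md.L - 1; ++l) {
    double d = mu - md.centers[l];
    double gl = std::exp(-d * d / h2);
    u += wg[l + 1] * gl;
    fpmu += wg[l + 1] * gl * (md.centers[l] - mu) / (md.h * md.h);
  }
  double g = clamp01(invlogit(u + e));
  double lam = (1.0 - g) / g;
  double a = mu * lam, b = (1.0 - mu) * lam;
  double A, B;
  md.lik_AB(j, a, b, A, B);
  double Smu = lam * (A - B);
  double Sg = -(A * mu + B * (1.0 - mu)) / (g * g);
  double dgdu = g * (1.0 - g);
  double dmudz = mu * (1.0 - mu);
  gz = (Smu + Sg * dgdu * fpmu) * dmudz;
  ge = Sg * dgdu;
}

// full gradient of +logp in the non-centered space; out length 2J + G
static void joint_grad(const double *par, const ModelData &md, double *out) {
  const int J = md.J, P = md.P, L = md.L;
  const int G0 = 2 * J;
  const double *wmu = par + G0;
  const double *wg = par + G0 + P;
  double ls_mu = par[G0 + P + L], ls_g = par[G0 + P + L + 1];
  double s_mu = std::exp(ls_mu), s_g = std::exp(ls_g);
  const double wmm = md.hyper[0], wms = md.hyper[1], wgm = md.hyper[2],
               wgs = md.hyper[3], sma = md.hyper[4], sga = md.hyper[5];
  for (int k = 0; k < G0 + md.G; ++k) out[k] = 0.0;
  std::vector<double> gl(L - 1);
  double h2 = 2.0 * md.h * md.h;
  for (int j = 0; j < J; ++j) {
    double zeta = par[j], eta = par[J + j];
    double m = 0.0;
    for (int p = 0; p < P; ++p) m += md.X(j, p) * wmu[p];
    double z = m + s_mu * zeta, e = s_g * eta;
    double gz, ge;
    feat_natural_grad(j, z, e, wg, md, gz, ge);
    double mu = clamp01(invlogit(z));
    for (int l = 0; l < L - 1; ++l) {
      double d = mu - md.centers[l];
      gl[l] = std::exp(-d * d / h2);
    }
    out[G0 + P] += ge;
    for (int l = 0; l < L - 1; ++l) out[G0 + P + 1 + l] += ge * gl[l];
    out[j] = gz * s_mu - zeta;
    out[J + j] = ge * s_g - eta;
    for (int p = 0; p < P; ++p) out[G0 + p] += gz * md.X(j, p);
    out[G0 + P + L] += gz * s_mu * zeta;
    out[G0 + P + L + 1] += ge * s_g * eta;
  }
  for (int p = 0; p < P; ++p) out[G0 + p] -= (wmu[p] - wmm) / (wms * wms);
  for (int l = 0; l < L; ++l) out[G0 + P + l] -= (wg[l] - wgm) / (wgs * wgs);
  out[G0 + P + L] += -(s_mu * s_mu) / (sma * sma) + 1.0;
  out[G0 + P + L + 1] += -(s_g * s_g) / (sga * sga) + 1.0;
}

// [[Rcpp::export]]
NumericVector cpp_joint_grad(NumericVector par, NumericVector yv,
                             NumericVector nv, IntegerVector fptr,
                             NumericMatrix X, NumericVector centers, double h,
                             NumericVector hyper) {
  ModelData md(yv, nv, fptr, X, centers, h, hyper);
  NumericVector out(par.size());
  joint_grad(REAL(par), md, REAL(out));
  for (R_xlen_t k = 0; k < out.size(); ++k) out[k] = -out[k];
  return out;
}

// gradient contribution of feature j (likelihood + its zeta/eta priors) to
// [zeta_j, eta_j, w_mu (P), w_gamma (L), ls_mu, ls_g]; out length 2 + G
static void feat_grad_contrib(int j, const double *par, const ModelData &md,
                              double *out) {
  const int J = md.J, P = md.P, L = md.L;
  const double *wmu = par + 2 * J;
  const double *wg = par + 2 * J + P;
  double s_mu = std::exp(par[2 * J + P + L]);
  double s_g = std::exp(par[2 * J + P + L + 1]);
  double zeta = par[j], eta = par[J + j];
  double m = 0.0;
  for (int p = 0; p < P; ++p) m += md.X(j, p) * wmu[p];
  double z = m + s_mu * zeta, e = s_g * eta;
  double gz, ge;
  feat_natural_grad(j, z, e, wg, md, gz, ge);
  double mu = clamp01(invlogit(z));
  double h2 = 2.0 * md.h * md.h;
  out[0] = gz * s_mu - zeta;
  out[1] = ge * s_g - eta;
  for (int p = 0; p < P; ++p) out[2 + p] = gz * md.X(j, p);
  out[2 + P] = ge;
  for (int l = 0; l < L - 1; ++l) {
    double d = mu - md.centers[l];
    out[2 + P + 1 + l] = ge * std::exp(-d * d / h2);
  }
  out[2 + P + L] = gz * s_mu * zeta;
  out[2 + P + L + 1] = ge * s_g * eta;
}

// Hessian of the negative joint log posterior, exploiting arrow sparsity
// [[Rcpp::export]]
NumericMatrix cpp_joint_hessian(NumericVector par, NumericVector yv,
                                NumericVector nv, IntegerVector fptr,
                                NumericMatrix X, NumericVector centers,
                                double h, NumericVector hyper) {
  ModelData md(yv, nv, fptr, X, centers, h, hyper);
  const int J = md.J, G = md.G;
  const int dim = 2 * J + G;
  NumericMatrix H(dim, dim);
  std::vector<double> p(REAL(par), REAL(par) + dim);
  std::vector<double> gp(2 + G), gm(2 + G);
  const double base_step = 1e-4;
  for (int j = 0; j < J; ++j) {
    int idx[2] = {j, J + j};
    for (int v = 0; v < 2; ++v) {
      int k = idx[v];
      double step = base_step * std::max(1.0, std::fabs(p[k]));
      double save = p[k];
      p[k] = save + step;
      feat_grad_contrib(j, p.data(), md, gp.data());
      p[k] = save - step;
      feat_grad_contrib(j, p.data(), md, gm.data());
      p[k] = save;
      double inv = 1.0 / (2.0 * step);
      H(idx[0], k) = -(gp[0] - gm[0]) * inv;
      H(idx[1], k) = -(gp[1] - gm[1]) * inv;
      for (int g = 0; g < G; ++g)
        H(2 * J + g, k) = -(gp[2 + g] - gm[2 + g]) * inv;
    }
  }
  std::vector<double> fp(dim), fm(dim);
  for (int g = 0; g < G; ++g) {
    int k = 2 * J + g;
    double step = base_step * std::max(1.0, std::fabs(p[k]));
    double save = p[k];
    p[k] = save + step;
    joint_grad(p.data(), md, fp.data());
    p[k] = save - step;
    joint_grad(p.data(), md, fm.data());
    p[k] = save;
    double inv = 1.0 / (2.0 * step);
    for (int r = 0; r < dim; ++r) H(r, k) = -(fp[r] - fm[r]) * inv;
  }
  for (int r = 0; r < dim; ++r)
    for (int c = r + 1; c < dim; ++c) {
      double v = 0.5 * (H(r, c) + H(c, r));
      H(r, c) = v;
      H(c, r) = v;
    }
  return H;
}

// Metropolis-within-Gibbs in the non-centered space: feature blocks
// (zeta_j, eta_j) then a joint global block. feat_chol: J x 3 lower-Cholesky
// entries (l11, l21, l22); glob_chol: G x G lower Cholesky.
// [[Rcpp::export]]
List cpp_mwg(NumericVector par0, NumericVector yv, NumericVector nv,
             IntegerVector fptr, NumericMatrix X, NumericVector centers,
             double h, NumericVector hyper, NumericMatrix feat_chol,
             NumericMatrix glob_chol, double feat_scale, double glob_scale,
             int n_warmup, int n_keep, int thin) {
  ModelData md(yv, nv, fptr, X, centers, h, hyper);
  const int J = md.J, P = md.P, L = md.L, G = md.G;
  const int dim = par0.size();
  std::vector<double> par(REAL(par0), REAL(par0) + dim);
  NumericMatrix draws(n_keep, dim);
  int n_iter = n_warmup + n_keep * thin;
  double acc_feat = 0.0, acc_glob = 0.0;
  long n_feat_prop = 0;
  int kept = 0;
  std::vector<double> prop(dim);
  for (int it = 0; it < n_iter; ++it) {
    const double *wg = par.data() + 2 * J + P;
    double s_mu = std::exp(par[2 * J + P + L]);
    double s_g = std::exp(par[2 * J + P + L + 1]);
    for (int j = 0; j < J; ++j) {
      double m_j = 0.0;
      for (int p = 0; p < P; ++p) m_j += X(j, p) * par[2 * J + p];
      double zeta = par[j], eta = par[J + j];
      double u1 = R::norm_rand(), u2 = R::norm_rand();
      double zp = zeta + feat_scale * feat_chol(j, 0) * u1;
      double ep = eta + feat_scale * (feat_chol(j, 1) * u1 + feat_chol(j, 2) * u2);
      double d = feat_loglik_nc(j, m_j + s_mu * zp, s_g * ep, wg, md)
               - 0.5 * zp * zp - 0.5 * ep * ep
               - feat_loglik_nc(j, m_j + s_mu * zeta, s_g * eta, wg, md)
               + 0.5 * zeta * zeta + 0.5 * eta * eta;
      ++n_feat_prop;
      if (std::log(R::unif_rand()) < d) {
        par[j] = zp;
        par[J + j] = ep;
        acc_feat += 1.0;
      }
    }
    double cur_lp = joint_lp(par.data(), md);
    for (int k = 0; k < dim; ++k) prop[k] = par[k];
    std::vector<double> zdr(G);
    for (int g = 0; g < G; ++g) zdr[g] = R::norm_rand();
    for (int g = 0; g < G; ++g) {
      double step = 0.0;
      for (int q = 0; q <= g; ++q) step += glob_chol(g, q) * zdr[q];
      prop[2 * J + g] += glob_scale * step;
    }
    double prop_lp = joint_lp(prop.data(), md);
    if (std::log(R::unif_rand()) < prop_lp - cur_lp) {
      for (int g = 0; g < G; ++g) par[2 * J + g] = prop[2 * J + g];
      acc_glob += 1.0;
    }
    if (it >= n_warmup && ((it - n_warmup) % thin == 0) && kept < n_keep) {
      for (int k = 0; k < dim; ++k) draws(kept, k) = par[k];
      ++kept;
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept_feature"] = acc_feat / (double)n_feat_prop,
                      _["accept_global"] = acc_glob / (double)n_iter);
}
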