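// Core numerical engine: one-compartment oral superposition, indirect-
// response turnover integration, and per-subject Laplace (FOCE-type)
// marginal-likelihood contributions for the three sequential stages.
//
// Inner (conditional-mode) problems are solved by Newton iterations with
// analytic residual sensitivities and the Gauss-Newton/Fisher metric; the
// Laplace log-determinant uses the exact Hessian of the conditional -2 log-
// likelihood, obtained by central differences at the mode.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// Structural models
// ---------------------------------------------------------------------------

// Plasma concentration (mg/L == ug/mL) at time t from superposed oral
// doses; optionally the sensitivity d f / d ke.  dose_t sorted ascending;
// dose_amt is absorbed S-warfarin in mg; cl mL/h, vd L, ka 1/h.
static double cp_at(double t, const double* dose_t, const double* dose_amt,
                    int nd, double ke, double vd, double ka,
                    double* dfdke = 0) {
  double c = 0.0, s = 0.0;
  for (int k = 0; k < nd; ++k) {
    double del = t - dose_t[k];
    if (del < 0.0) break;
    double e1 = std::exp(-ke * del), e2 = std::exp(-ka * del);
    double dk = ka - ke;
    if (std::fabs(dk) > 1e-8) {
      double base = dose_amt[k] * ka / vd;
      c += base * (e1 - e2) / dk;
      if (dfdke) s += base * ((e1 - e2) / (dk * dk) - del * e1 / dk);
    } else {
      c += dose_amt[k] * ka * del * e2 / vd;
      if (dfdke) s += -dose_amt[k] * ka * del * del * e2 / (2.0 * vd);
    }
  }
  if (dfdke) *dfdke = s;
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_cp_profile(NumericVector times, NumericVector dose_t,
                             NumericVector dose_amt, double cl, double vd,
                             double ka) {
  double ke = (cl / 1000.0) / vd;
  int n = times.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j)
    out[j] = cp_at(times[j], dose_t.begin(), dose_amt.begin(),
                   dose_t.size(), ke, vd, ka);
  return out;
}

// Turnover pool: dNPT/dt = Kin (1 - Imax Cp/(IC50+Cp)) - Kout NPT with
// Kin = Kout NPT0, NPT(0) = NPT0.  Exact integrating-factor solution of
// the linear ODE with piecewise-linear inhibition input on a uniform
// grid (step h).  Optionally propagates the sensitivities of NPT to
// log IC50 (s1) and log Kout (s2).
static void npt_grid(const double* cp, int n, double h, double npt0,
                     double ic50, double kout, double imax, double* out,
                     double* s1 = 0, double* s2 = 0) {
  out[0] = npt0;
  if (s1) { s1[0] = 0.0; s2[0] = 0.0; }
  if (n < 2) return;
  const double kin = kout * npt0;
  const double e = std::exp(-kout * h);
  const double c1 = (1.0 - e) / kout;
  const double c2 = (1.0 - e * (1.0 + kout * h)) / (kout * kout * h);
  // d/dkout of the step constants (used for the log-Kout sensitivity)
  const double de = -h * e;
  const double dc1 = h * e / kout - c1 / kout;
  const double dc2 = h * e / kout - 2.0 * c2 / kout;
  double D = ic50 + cp[0];
  double A = 1.0 - imax * cp[0] / D;
  double dA = imax * cp[0] * ic50 / (D * D);   // dA/d(log ic50)
  for (int k = 0; k + 1 < n; ++k) {
    double Dn = ic50 + cp[k + 1];
    double B = 1.0 - imax * cp[k + 1] / Dn;
    double dB = imax * cp[k + 1] * ic50 / (Dn * Dn);
    double src = B * c1 + (A - B) * c2;
    out[k + 1] = out[k] * e + kin * src;
    if (s1) {
      s1[k + 1] = s1[k] * e + kin * (dB * c1 + (dA - dB) * c2);
      s2[k + 1] = s2[k] * e + kout *
        (de * out[k] + npt0 * src + kin * (B * dc1 + (A - B) * dc2));
    }
    A = B; dA = dB;
  }
}

// [[Rcpp::export]]
NumericVector cpp_npt_grid(NumericVector cp, double h, double npt0,
                           double ic50, double kout, double imax) {
  int n = cp.size();
  NumericVector out(n);
  npt_grid(cp.begin(), n, h, npt0, ic50, kout, imax, out.begin());
  return out;
}

// Full second-order sensitivity pass: N plus first (S1, S2) and second
// (S11, S12, S22) derivatives with respect to (log IC50, log Kout).  All
// sensitivity recurrences are linear, so the propagation is exact.
static void npt_grid2(const double* cp, int n, double h, double npt0,
                      double ic50, double kout, double imax,
                      double* N, double* S1, double* S2,
                      double* S11, double* S12, double* S22) {
  N[0] = npt0;
  S1[0] = S2[0] = S11[0] = S12[0] = S22[0] = 0.0;
  if (n < 2) return;
  const double kin = kout * npt0;            // d/d(log kout) = itself
  const double e = std::exp(-kout * h);
  const double c1 = (1.0 - e) / kout;
  const double c2 = (1.0 - e * (1.0 + kout * h)) / (kout * kout * h);
  // derivatives with respect to log kout
  const double d2e = -kout * h * e;
  const double d22e = kout * h * e * (kout * h - 1.0);
  const double d2c1 = h * e - c1;
  const double d22c1 = -kout * h * h * e - h * e + c1;
  const double d2c2 = h * e - 2.0 * c2;
  const double d22c2 = -kout * h * h * e - 2.0 * h * e + 4.0 * c2;
  double D = ic50 + cp[0];
  double A = 1.0 - imax * cp[0] / D;
  double dA = imax * cp[0] * ic50 / (D * D);
  double ddA = dA * (1.0 - 2.0 * ic50 / D);
  for (int k = 0; k + 1 < n; ++k) {
    double Dn = ic50 + cp[k + 1];
    double B = 1.0 - imax * cp[k + 1] / Dn;
    double dB = imax * cp[k + 1] * ic50 / (Dn * Dn);
    double ddB = dB * (1.0 - 2.0 * ic50 / Dn);
    double src = B * c1 + (A - B) * c2;
    double s1src = dB * c1 + (dA - dB) * c2;
    double s11src = ddB * c1 + (ddA - ddB) * c2;
    double s2src = B * d2c1 + (A - B) * d2c2;
    double s12src = dB * d2c1 + (dA - dB) * d2c2;
    double s22src = B * d22c1 + (A - B) * d22c2;
    N[k + 1] = N[k] * e + kin * src;
    S1[k + 1] = S1[k] * e + kin * s1src;
    S2[k + 1] = d2e * N[k] + S2[k] * e + kin * (src + s2src);
    S11[k + 1] = S11[k] * e + kin * s11src;
    S12[k + 1] = d2e * S1[k] + S12[k] * e + kin * (s1src + s12src);
    S22[k + 1] = d22e * N[k] + 2.0 * d2e * S2[k] + S22[k] * e +
                 kin * (src + 2.0 * s2src + s22src);
    A = B; dA = dB; ddA = ddB;
  }
}

// ---------------------------------------------------------------------------
// Per-subject inner problem
// ---------------------------------------------------------------------------
// q(eta) = -2 log{ p(y | eta) p(eta) } with all 2*pi constants kept.
// Evaluators provide q, its analytic gradient, and the Gauss-Newton /
// Fisher approximation M of the Hessian of q (both over the active
// random-effect dimensions only).

struct Evaluator {
  virtual double eval(const double* eta, double* grad, double* gn) = 0;
  virtual ~Evaluator() {}
};

static void true_hess(Evaluator& ev, const double* eta, int d, double f0,
                      double* H);

// Newton minimisation in d dims (d <= 2) with the GN metric and
// backtracking; eta updated in place; returns q at the mode.
// Levenberg-damped Newton on the Gauss-Newton/Fisher metric.  The metric
// can understate the true curvature on moderate-residual subjects, so a
// rejected step raises the damping instead of terminating; convergence is
// declared on a vanishing expected decrease at (near-)zero damping.
static double newton_gn(Evaluator& ev, double* eta, int d,
                        int maxit = 300) {
  double g[2], M[3]; // M = [m11, m12, m22]
  double f0 = ev.eval(eta, g, M);
  double lambda = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double step[2] = {0.0, 0.0};
    if (d == 1) {
      double m = M[0] + lambda;
      if (m < 1e-12) m = 1e-12;
      step[0] = g[0] / m;
    } else {
      double a = M[0] + lambda, b = M[1], c = M[2] + lambda;
      double det = a * c - b * b;
      if (det < 1e-12 || a < 1e-12) { a += 1.0; c += 1.0; det = a * c - b * b; }
      step[0] = (c * g[0] - b * g[1]) / det;
      step[1] = (a * g[1] - b * g[0]) / det;
    }
    double ed = g[0] * step[0] + (d == 2 ? g[1] * step[1] : 0.0);
    if (ed < 1e-11 * (1.0 + std::fabs(f0)) && lambda < 1e-6) break;
    // cap the step to keep exp() sane
    double smax = std::fabs(step[0]);
    if (d == 2) smax = std::max(smax, std::fabs(step[1]));
    if (smax > 2.0) { step[0] *= 2.0 / smax; if (d == 2) step[1] *= 2.0 / smax; }
    double t = 1.0;
    bool ok = false;
    double en[2], f1 = f0;
    for (int ls = 0; ls < 12; ++ls) {
      for (int k = 0; k < d; ++k) en[k] = eta[k] - t * step[k];
      f1 = ev.eval(en, 0, 0);
      if (R_finite(f1) && f1 < f0) { ok = true; break; }
      t *= 0.5;
    }
    if (ok) {
      for (int k = 0; k < d; ++k) eta[k] = en[k];
      f0 = ev.eval(eta, g, M);
      if (t == 1.0) {
        lambda /= 4.0;
        if (lambda < 1e-10) lambda = 0.0;
      } else {
        // partial step: the metric understates curvature, raise damping
        lambda = (lambda == 0.0) ? 0.5 * (M[0] + (d == 2 ? M[2] : M[0]))
                                 : lambda * 4.0;
      }
    } else {
      if (lambda > 1e8) break;          // no representable progress left
      lambda = (lambda == 0.0) ? std::max(1.0, M[0]) : lambda * 10.0;
    }
  }
  return f0;
}

// Terminal polish with the exact (finite-difference) Hessian: quadratic
// convergence to the conditional mode, removing any residual drift the
// damped GN phase leaves behind.
static double newton_polish(Evaluator& ev, double* eta, int d, double f0) {
  double g[2], M[3], H[4];
  for (int it = 0; it < 4; ++it) {
    ev.eval(eta, g, M);
    // skip when the GN metric already certifies a converged mode
    double edgn;
    if (d == 1) {
      edgn = g[0] * g[0] / std::max(M[0], 1e-12);
    } else {
      double det = std::max(M[0] * M[2] - M[1] * M[1], 1e-12);
      edgn = (M[2] * g[0] * g[0] - 2.0 * M[1] * g[0] * g[1] +
              M[0] * g[1] * g[1]) / det;
    }
    if (edgn < 1e-13 * (1.0 + std::fabs(f0))) break;
    true_hess(ev, eta, d, f0, H);
    double step[2] = {0.0, 0.0};
    if (d == 1) {
      double h11 = H[0] > 1e-10 ? H[0] : (M[0] > 1e-10 ? 2.0 * M[0] : 1e-10);
      step[0] = g[0] / h11;
    } else {
      double a = H[0], b = H[1], c = H[3];
      double det = a * c - b * b;
      if (det < 1e-12 || a < 1e-12) { a = 2.0 * M[0]; b = 2.0 * M[1];
        c = 2.0 * M[2]; det = a * c - b * b;
        if (det < 1e-12) break; }
      step[0] = (c * g[0] - b * g[1]) / det;
      step[1] = (a * g[1] - b * g[0]) / det;
    }
    double ed = g[0] * step[0] + (d == 2 ? g[1] * step[1] : 0.0);
    if (!R_finite(ed) || ed < 0.0) break;
    if (ed < 1e-13 * (1.0 + std::fabs(f0))) break;
    double t = 1.0, en[2], f1 = f0;
    bool ok = false;
    for (int ls = 0; ls < 20; ++ls) {
      for (int k = 0; k < d; ++k) en[k] = eta[k] - t * step[k];
      f1 = ev.eval(en, 0, 0);
      if (R_finite(f1) && f1 <= f0) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) break;
    bool same = true;
    for (int k = 0; k < d; ++k) {
      if (en[k] != eta[k]) same = false;
      eta[k] = en[k];
    }
    f0 = f1;
    if (same) break;
  }
  return f0;
}

// Exact Hessian of q at eta by central differences of plain evaluations.
static void true_hess(Evaluator& ev, const double* eta, int d, double f0,
                      double* H) {
  // step balances truncation against round-off noise in the outer
  // objective (the log-determinant must vary smoothly with parameters)
  double hs[2];
  for (int k = 0; k < d; ++k) hs[k] = 1e-3 * (1.0 + std::fabs(eta[k]));
  double e[2], fp[2];
  for (int k = 0; k < d; ++k) {
    for (int j = 0; j < d; ++j) e[j] = eta[j];
    e[k] = eta[k] + hs[k]; fp[k] = ev.eval(e, 0, 0);
    e[k] = eta[k] - hs[k]; double fm = ev.eval(e, 0, 0);
    H[k * d + k] = (fp[k] - 2.0 * f0 + fm) / (hs[k] * hs[k]);
  }
  if (d == 2) {
    // cross term from the (+,+) corner, reusing the axis points
    double epp[2] = {eta[0] + hs[0], eta[1] + hs[1]};
    double hx = (ev.eval(epp, 0, 0) - fp[0] - fp[1] + f0) /
                (hs[0] * hs[1]);
    H[1] = hx; H[2] = hx;
  }
}

// One-dimensional conditional mode by bracketed secant iteration on the
// analytic gradient (regula falsi with secant proposals): superlinear and
// free of metric-quality issues.
static double solve_1d(Evaluator& ev, double* eta) {
  double g[1], M[1];
  double a = eta[0];
  double f = ev.eval(&a, g, M);
  double ga = g[0];
  if (std::fabs(ga) < 1e-11 * (1.0 + std::fabs(f))) return f;
  double dir = ga > 0.0 ? -1.0 : 1.0;
  double step = std::fabs(ga) / std::max(M[0], 1e-8);
  if (step > 1.0) step = 1.0;
  if (step < 1e-3) step = 1e-3;
  double b = a, gb = ga;
  bool bracketed = false;
  for (int k = 0; k < 60; ++k) {
    double xn = b + dir * step;
    ev.eval(&xn, g, M);
    if ((g[0] > 0.0) != (ga > 0.0)) {
      a = b; ga = gb; b = xn; gb = g[0];
      bracketed = true;
      break;
    }
    a = b; ga = gb; b = xn; gb = g[0];
    step *= 1.7;
  }
  if (!bracketed) {       // pathological surface: keep the better endpoint
    eta[0] = std::fabs(ga) < std::fabs(gb) ? a : b;
    return ev.eval(eta, 0, 0);
  }
  double xm = b;
  for (int k = 0; k < 100; ++k) {
    double denom = gb - ga;
    xm = (std::fabs(denom) > 1e-300) ? b - gb * (b - a) / denom
                                     : 0.5 * (a + b);
    double lo = std::min(a, b), hi = std::max(a, b);
    if (!(xm > lo && xm < hi)) xm = 0.5 * (a + b);
    ev.eval(&xm, g, M);
    if (std::fabs(g[0]) < 1e-10 || (hi - lo) < 1e-11) break;
    if ((g[0] > 0.0) == (gb > 0.0)) { b = xm; gb = g[0]; }
    else { a = xm; ga = g[0]; }
  }
  eta[0] = xm;
  return ev.eval(eta, 0, 0);
}

// Laplace contribution: q(mode) - d log(2 pi) + log det(0.5 * Hq(mode)).
// For d == 0 (no active random effect) this is the plain -2 log-likelihood.
static double laplace_subject(Evaluator& ev, double* eta, int d) {
  if (d == 0) {
    double z[2] = {0.0, 0.0};
    return ev.eval(z, 0, 0);
  }
  double f0;
  if (d == 1) {
    f0 = solve_1d(ev, eta);
    double H[1];
    true_hess(ev, eta, 1, f0, H);
    double h11 = 0.5 * H[0];
    if (h11 < 1e-12) h11 = 1e-12;
    return f0 - LOG2PI + std::log(h11);
  }
  f0 = newton_gn(ev, eta, d);
  f0 = newton_polish(ev, eta, d, f0);
  double H[4];
  true_hess(ev, eta, d, f0, H);
  double logdet;
  if (d == 1) {
    double h11 = 0.5 * H[0];
    if (h11 < 1e-12) h11 = 1e-12;
    logdet = std::log(h11);
  } else {
    double a = 0.5 * H[0], b = 0.5 * H[1], c = 0.5 * H[3];
    double det = a * c - b * b;
    if (det < 1e-20) det = 1e-20;
    logdet = std::log(det);
  }
  return f0 - d * LOG2PI + logdet;
}

// ---------------------------------------------------------------------------
// Stage 1: PK (Cp(S), additive error, one random effect on CL)
// ---------------------------------------------------------------------------
// Flattened layout: subject i owns doses [dptr[i], dptr[i+1]) and
// observations [optr[i], optr[i+1]) (0-based offsets, length n+1).

struct PkEval : Evaluator {
  const double *dt, *da, *ot, *oy;
  int nd, no;
  double tv, vd, ka, om2, sg2;
  bool has_eta;
  double eval(const double* eta, double* grad, double* gn) {
    double e0 = has_eta ? eta[0] : 0.0;
    double ke = (tv * std::exp(e0) / 1000.0) / vd;
    double q = 0.0, g = 0.0, m = 0.0;
    for (int j = 0; j < no; ++j) {
      double dfdke, f = cp_at(ot[j], dt, da, nd, ke, vd, ka,
                              grad ? &dfdke : 0);
      double r = oy[j] - f;
      q += LOG2PI + std::log(sg2) + r * r / sg2;
      if (grad) {
        double fp = dfdke * ke;  // d f / d eta
        g += -2.0 * r * fp / sg2;
        m += 2.0 * fp * fp / sg2;
      }
    }
    if (has_eta) {
      q += LOG2PI + std::log(om2) + e0 * e0 / om2;
      if (grad) { g += 2.0 * e0 / om2; m += 2.0 / om2; }
    }
    if (grad) { grad[0] = g; gn[0] = 0.5 * m; }
    return q;
  }
};

// [[Rcpp::export]]
List cpp_pk_laplace(NumericVector dose_t, NumericVector dose_amt,
                    IntegerVector dptr, NumericVector obs_t,
                    NumericVector obs_y, IntegerVector optr,
                    NumericVector cl_typ, double vd, double ka,
                    double omega_sd, double sigma,
                    NumericVector eta_start, bool want_pred) {
  int n = cl_typ.size();
  if (sigma <= 0.0) stop("sigma must be positive");
  NumericVector eta_hat = clone(eta_start);
  bool has_eta = omega_sd > 1e-12;
  double total = 0.0;
  NumericVector pred_pop, pred_ind, pred_grad;
  if (want_pred) {
    pred_pop = NumericVector(obs_t.size());
    pred_ind = NumericVector(obs_t.size());
    pred_grad = NumericVector(obs_t.size());
  }
  PkEval ev;
  ev.vd = vd; ev.ka = ka; ev.om2 = omega_sd * omega_sd;
  ev.sg2 = sigma * sigma; ev.has_eta = has_eta;
  for (int i = 0; i < n; ++i) {
    ev.dt = dose_t.begin() + dptr[i];
    ev.da = dose_amt.begin() + dptr[i];
    ev.nd = dptr[i + 1] - dptr[i];
    ev.ot = obs_t.begin() + optr[i];
    ev.oy = obs_y.begin() + optr[i];
    ev.no = optr[i + 1] - optr[i];
    ev.tv = cl_typ[i];
    if (ev.no == 0) { eta_hat[i] = 0.0; continue; }  // no data: marginal = 1
    double e[2] = {has_eta ? eta_hat[i] : 0.0, 0.0};
    total += laplace_subject(ev, e, has_eta ? 1 : 0);
    eta_hat[i] = e[0];
    if (want_pred) {
      double ke0 = (ev.tv / 1000.0) / vd;
      double kei = (ev.tv * std::exp(e[0]) / 1000.0) / vd;
      for (int j = 0; j < ev.no; ++j) {
        double dfdke;
        pred_pop[optr[i] + j] = cp_at(ev.ot[j], ev.dt, ev.da, ev.nd, ke0,
                                      vd, ka, &dfdke);
        pred_grad[optr[i] + j] = dfdke * ke0;   // d f / d eta at eta = 0
        pred_ind[optr[i] + j] = cp_at(ev.ot[j], ev.dt, ev.da, ev.nd, kei,
                                      vd, ka);
      }
    }
  }
  List out = List::create(_["ofv"] = total, _["eta"] = eta_hat);
  if (want_pred) {
    out["pred_pop"] = pred_pop; out["pred_ind"] = pred_ind;
    out["pred_grad"] = pred_grad;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stage 2: NPT (indirect response, additive error, random effects on
// IC50 and Kout).  Each subject's Cp(S) is supplied on a uniform grid
// (step h, from t = 0); observations map to grid cells by local lower
// index + interpolation fraction, precomputed in R.
// ---------------------------------------------------------------------------

struct NptEval : Evaluator {
  const double *cp, *ofr, *oy;
  const int* oi;
  int ng, no;
  double h, npt0, t1, t2, imax, om1, om2, sg2;
  bool h1, h2;
  std::vector<double>* buf;  // 6 * max grid length

  // exact value, gradient and Hessian over the full (eta1, eta2) pair
  double eval2(const double* eta, double* g, double* H) {
    double ic50 = t1 * std::exp(eta[0]), kout = t2 * std::exp(eta[1]);
    double* N = buf->data();
    double* S1 = N + ng; double* S2 = S1 + ng;
    double* S11 = S2 + ng; double* S12 = S11 + ng; double* S22 = S12 + ng;
    npt_grid2(cp, ng, h, npt0, ic50, kout, imax, N, S1, S2, S11, S12,
              S22);
    double q = 0.0;
    g[0] = g[1] = 0.0;
    double h11 = 0.0, h12 = 0.0, h22 = 0.0;
    for (int j = 0; j < no; ++j) {
      int a = oi[j];
      double w = ofr[j];
      double f = N[a] + w * (N[a + 1] - N[a]);
      double f1 = S1[a] + w * (S1[a + 1] - S1[a]);
      double f2 = S2[a] + w * (S2[a + 1] - S2[a]);
      double f11 = S11[a] + w * (S11[a + 1] - S11[a]);
      double f12 = S12[a] + w * (S12[a + 1] - S12[a]);
      double f22 = S22[a] + w * (S22[a + 1] - S22[a]);
      double r = oy[j] - f;
      q += LOG2PI + std::log(sg2) + r * r / sg2;
      g[0] += -2.0 * r * f1 / sg2;
      g[1] += -2.0 * r * f2 / sg2;
      h11 += 2.0 * (f1 * f1 - r * f11) / sg2;
      h12 += 2.0 * (f1 * f2 - r * f12) / sg2;
      h22 += 2.0 * (f2 * f2 - r * f22) / sg2;
    }
    q += LOG2PI + std::log(om1) + eta[0] * eta[0] / om1;
    q += LOG2PI + std::log(om2) + eta[1] * eta[1] / om2;
    g[0] += 2.0 * eta[0] / om1;
    g[1] += 2.0 * eta[1] / om2;
    h11 += 2.0 / om1;
    h22 += 2.0 / om2;
    H[0] = h11; H[1] = h12; H[2] = h22;
    return q;
  }
  double eval(const double* eta, double* grad, double* gn) {
    double e1 = 0.0, e2 = 0.0;
    int k = 0;
    if (h1) e1 = eta[k++];
    if (h2) e2 = eta[k++];
    double ic50 = t1 * std::exp(e1), kout = t2 * std::exp(e2);
    double* N = buf->data();
    double* S1 = N + ng;
    double* S2 = S1 + ng;
    npt_grid(cp, ng, h, npt0, ic50, kout, imax, N,
             grad ? S1 : 0, grad ? S2 : 0);
    double q = 0.0, g1 = 0.0, g2 = 0.0, m11 = 0.0, m12 = 0.0, m22 = 0.0;
    for (int j = 0; j < no; ++j) {
      int a = oi[j];
      double w = ofr[j];
      double f = N[a] + w * (N[a + 1] - N[a]);
      double r = oy[j] - f;
      q += LOG2PI + std::log(sg2) + r * r / sg2;
      if (grad) {
        double d1 = S1[a] + w * (S1[a + 1] - S1[a]);
        double d2 = S2[a] + w * (S2[a + 1] - S2[a]);
        g1 += -2.0 * r * d1 / sg2;
        g2 += -2.0 * r * d2 / sg2;
        m11 += 2.0 * d1 * d1 / sg2;
        m12 += 2.0 * d1 * d2 / sg2;
        m22 += 2.0 * d2 * d2 / sg2;
      }
    }
    if (h1) {
      q += LOG2PI + std::log(om1) + e1 * e1 / om1;
      if (grad) { g1 += 2.0 * e1 / om1; m11 += 2.0 / om1; }
    }
    if (h2) {
      q += LOG2PI + std::log(om2) + e2 * e2 / om2;
      if (grad) { g2 += 2.0 * e2 / om2; m22 += 2.0 / om2; }
    }
    if (grad) {
      int d = 0;
      double gg[2], mm[3];
      if (h1) { gg[d] = g1; ++d; }
      if (h2) { gg[d] = g2; ++d; }
      if (d == 1) {
        mm[0] = 0.5 * (h1 ? m11 : m22);
      } else {
        mm[0] = 0.5 * m11; mm[1] = 0.5 * m12; mm[2] = 0.5 * m22;
      }
      for (int t = 0; t < d; ++t) grad[t] = gg[t];
      for (int t = 0; t < 3; ++t) gn[t] = mm[t];
    }
    return q;
  }
};

// Damped Newton with the exact analytic Hessian for the 2-D NPT inner
// problem; returns the Laplace contribution directly (the final Hessian
// feeds the log-determinant, no finite differences involved).
static double npt_laplace_2d(NptEval& ev, double* eta) {
  double g[2], H[3];
  double f0 = ev.eval2(eta, g, H);
  double lambda = 0.0;
  for (int it = 0; it < 100; ++it) {
    double a = H[0] + lambda, b = H[1], c = H[2] + lambda;
    double det = a * c - b * b;
    if (det < 1e-12 || a < 1e-12) {
      lambda = (lambda == 0.0) ? 1.0 + std::fabs(H[0]) + std::fabs(H[2])
                               : lambda * 10.0;
      if (lambda > 1e10) break;
      continue;
    }
    double step[2] = {(c * g[0] - b * g[1]) / det,
                      (a * g[1] - b * g[0]) / det};
    double ed = g[0] * step[0] + g[1] * step[1];
    if (ed < 1e-12 * (1.0 + std::fabs(f0)) && lambda < 1e-6 && ed >= 0.0)
      break;
    if (ed < 0.0) {  // damped matrix not PD enough
      lambda = (lambda == 0.0) ? 1.0 : lambda * 10.0;
      if (lambda > 1e10) break;
      continue;
    }
    double smax = std::max(std::fabs(step[0]), std::fabs(step[1]));
    if (smax > 2.0) { step[0] *= 2.0 / smax; step[1] *= 2.0 / smax; }
    double t = 1.0, en[2], f1 = f0;
    bool ok = false;
    for (int ls = 0; ls < 25; ++ls) {
      en[0] = eta[0] - t * step[0];
      en[1] = eta[1] - t * step[1];
      f1 = ev.eval(en, 0, 0);     // cheap value-only pass
      if (R_finite(f1) && f1 < f0) { ok = true; break; }
      t *= 0.5;
    }
    if (ok) {
      eta[0] = en[0]; eta[1] = en[1];
      f0 = ev.eval2(eta, g, H);
      lambda = (t == 1.0) ? lambda / 4.0 : lambda * 2.0;
      if (lambda < 1e-10) lambda = 0.0;
    } else {
      if (lambda > 1e10) break;
      lambda = (lambda == 0.0) ? 1.0 + std::fabs(H[0]) : lambda * 10.0;
    }
  }
  double a = 0.5 * H[0], b = 0.5 * H[1], c = 0.5 * H[2];
  double det = a * c - b * b;
  if (det < 1e-20) det = 1e-20;
  return f0 - 2.0 * LOG2PI + std::log(det);
}

// [[Rcpp::export]]
List cpp_npt_laplace(NumericVector cp_grid, IntegerVector gptr, double h,
                     IntegerVector obs_idx, NumericVector obs_frac,
                     NumericVector obs_y, IntegerVector optr,
                     NumericVector npt0, NumericVector ic50_typ,
                     NumericVector kout_typ, double imax,
                     double omega_ic50, double omega_kout, double sigma,
                     NumericMatrix eta_start, bool want_pred) {
  int n = ic50_typ.size();
  if (sigma <= 0.0) stop("sigma must be positive");
  NumericMatrix eta_hat = clone(eta_start);
  bool h1 = omega_ic50 > 1e-12, h2 = omega_kout > 1e-12;
  double total = 0.0;
  NumericVector pred_pop, pred_ind;
  NumericMatrix pred_grad;
  if (want_pred) {
    pred_pop = NumericVector(obs_y.size());
    pred_ind = NumericVector(obs_y.size());
    pred_grad = NumericMatrix(obs_y.size(), 2);
  }
  int maxg = 0;
  for (int i = 0; i < n; ++i) maxg = std::max(maxg, gptr[i + 1] - gptr[i]);
  std::vector<double> buf(6 * maxg);
  NptEval ev;
  ev.h = h; ev.imax = imax; ev.sg2 = sigma * sigma;
  ev.om1 = omega_ic50 * omega_ic50; ev.om2 = omega_kout * omega_kout;
  ev.h1 = h1; ev.h2 = h2; ev.buf = &buf;
  for (int i = 0; i < n; ++i) {
    ev.cp = cp_grid.begin() + gptr[i];
    ev.ng = gptr[i + 1] - gptr[i];
    ev.oi = obs_idx.begin() + optr[i];
    ev.ofr = obs_frac.begin() + optr[i];
    ev.oy = obs_y.begin() + optr[i];
    ev.no = optr[i + 1] - optr[i];
    ev.npt0 = npt0[i]; ev.t1 = ic50_typ[i]; ev.t2 = kout_typ[i];
    if (ev.no == 0) { eta_hat(i, 0) = 0.0; eta_hat(i, 1) = 0.0; continue; }
    int d = (h1 ? 1 : 0) + (h2 ? 1 : 0);
    if (d == 2) {
      // exact analytic Hessian path
      double e[2] = {eta_hat(i, 0), eta_hat(i, 1)};
      total += npt_laplace_2d(ev, e);
      eta_hat(i, 0) = e[0]; eta_hat(i, 1) = e[1];
    } else {
      double e[2] = {0.0, 0.0};
      { int k = 0; if (h1) e[k++] = eta_hat(i, 0);
        if (h2) e[k++] = eta_hat(i, 1); }
      total += laplace_subject(ev, e, d);
      { int k = 0;
        eta_hat(i, 0) = (h1 && d) ? e[k++] : 0.0;
        eta_hat(i, 1) = (h2 && d) ? e[k++] : 0.0; }
    }
    if (want_pred) {
      double* N = buf.data();
      double* S1 = N + ev.ng; double* S2 = S1 + ev.ng;
      npt_grid(ev.cp, ev.ng, h, ev.npt0, ev.t1, ev.t2, imax, N, S1, S2);
      for (int j = 0; j < ev.no; ++j) {
        int a = ev.oi[j];
        double w = ev.ofr[j];
        pred_pop[optr[i] + j] = N[a] + w * (N[a + 1] - N[a]);
        pred_grad(optr[i] + j, 0) = S1[a] + w * (S1[a + 1] - S1[a]);
        pred_grad(optr[i] + j, 1) = S2[a] + w * (S2[a + 1] - S2[a]);
      }
      npt_grid(ev.cp, ev.ng, h, ev.npt0, ev.t1 * std::exp(eta_hat(i, 0)),
               ev.t2 * std::exp(eta_hat(i, 1)), imax, N);
      for (int j = 0; j < ev.no; ++j) {
        int a = ev.oi[j];
        pred_ind[optr[i] + j] = N[a] + ev.ofr[j] * (N[a + 1] - N[a]);
      }
    }
  }
  List out = List::create(_["ofv"] = total, _["eta"] = eta_hat);
  if (want_pred) {
    out["pred_pop"] = pred_pop; out["pred_ind"] = pred_ind;
    out["pred_grad"] = pred_grad;
  }
  return out;
}

// Gradient/metric probe for one subject's NPT inner problem (testing aid:
// the analytic sensitivities must agree with finite differences).
// [[Rcpp::export]]
List cpp_npt_inner_probe(NumericVector cp, double h, IntegerVector obs_idx,
                         NumericVector obs_frac, NumericVector obs_y,
                         double npt0, double ic50_typ, double kout_typ,
                         double imax, double omega_ic50, double omega_kout,
                         double sigma, NumericVector eta) {
  std::vector<double> buf(6 * cp.size());
  NptEval ev;
  ev.cp = cp.begin(); ev.ng = cp.size();
  ev.oi = obs_idx.begin(); ev.ofr = obs_frac.begin();
  ev.oy = obs_y.begin(); ev.no = obs_y.size();
  ev.h = h; ev.npt0 = npt0; ev.t1 = ic50_typ; ev.t2 = kout_typ;
  ev.imax = imax; ev.sg2 = sigma * sigma;
  ev.om1 = omega_ic50 * omega_ic50; ev.om2 = omega_kout * omega_kout;
  ev.h1 = omega_ic50 > 1e-12; ev.h2 = omega_kout > 1e-12;
  ev.buf = &buf;
  double g[2] = {0, 0}, M[3] = {0, 0, 0};
  double q = ev.eval(eta.begin(), g, M);
  double g2[2] = {0, 0}, H[3] = {0, 0, 0};
  double q2 = ev.eval2(eta.begin(), g2, H);
  return List::create(_["q"] = q, _["q2"] = q2,
                      _["grad"] = NumericVector(g, g + 2),
                      _["grad2"] = NumericVector(g2, g2 + 2),
                      _["gn"] = NumericVector(M, M + 3),
                      _["hess"] = NumericVector(H, H + 3));
}

// ---------------------------------------------------------------------------
// Stage 3: INR (nonlinear NPT->INR link, relative error, random effect on
// lambda).  NPT individual predictions at the INR observation times are
// precomputed; inhibition fraction clamped to [0, 1].  The error variance
// depends on eta (interaction), handled exactly by the Laplace expansion
// with the Fisher metric for the inner Newton steps.
// ---------------------------------------------------------------------------

struct InrEval : Evaluator {
  const double *np, *oy;
  int no;
  double b0, base, tv, inr_max, om2, sg2;
  bool has_eta;
  double eval(const double* eta, double* grad, double* gn) {
    double e0 = has_eta ? eta[0] : 0.0;
    double lam = tv * std::exp(e0);
    double q = 0.0, g = 0.0, m = 0.0;
    for (int j = 0; j < no; ++j) {
      double frac = (b0 - np[j]) / b0;
      if (frac < 0.0) frac = 0.0;
      if (frac > 1.0) frac = 1.0;
      double pw = frac > 0.0 ? std::pow(frac, lam) : 0.0;
      double f = base + inr_max * pw;
      double v = sg2 * f * f;
      if (v < 1e-12) v = 1e-12;
      double r = oy[j] - f;
      q += LOG2PI + std::log(v) + r * r / v;
      if (grad) {
        double fp = frac > 0.0 ? inr_max * pw * std::log(frac) * lam : 0.0;
        g += 2.0 * fp / f - 2.0 * r * fp / v - 2.0 * r * r * fp / (v * f);
        m += 2.0 * (fp * fp / v + 2.0 * fp * fp / (f * f));
      }
    }
    if (has_eta) {
      q += LOG2PI + std::log(om2) + e0 * e0 / om2;
      if (grad) { g += 2.0 * e0 / om2; m += 2.0 / om2; }
    }
    if (grad) { grad[0] = g; gn[0] = 0.5 * m; }
    return q;
  }
};

// [[Rcpp::export]]
List cpp_inr_laplace(NumericVector npt_pred, NumericVector obs_y,
                     IntegerVector optr, NumericVector npt0,
                     NumericVector inr_base, NumericVector lam_typ,
                     double inr_max, double omega_sd, double sigma_rel,
                     NumericVector eta_start, bool want_pred) {
  int n = lam_typ.size();
  if (sigma_rel <= 0.0) stop("sigma must be positive");
  NumericVector eta_hat = clone(eta_start);
  bool has_eta = omega_sd > 1e-12;
  double total = 0.0;
  NumericVector pred_pop, pred_ind, pred_grad;
  if (want_pred) {
    pred_pop = NumericVector(obs_y.size());
    pred_ind = NumericVector(obs_y.size());
    pred_grad = NumericVector(obs_y.size());
  }
  InrEval ev;
  ev.inr_max = inr_max; ev.om2 = omega_sd * omega_sd;
  ev.sg2 = sigma_rel * sigma_rel; ev.has_eta = has_eta;
  for (int i = 0; i < n; ++i) {
    ev.np = npt_pred.begin() + optr[i];
    ev.oy = obs_y.begin() + optr[i];
    ev.no = optr[i + 1] - optr[i];
    ev.b0 = npt0[i]; ev.base = inr_base[i]; ev.tv = lam_typ[i];
    if (ev.no == 0) { eta_hat[i] = 0.0; continue; }
    double e[2] = {has_eta ? eta_hat[i] : 0.0, 0.0};
    total += laplace_subject(ev, e, has_eta ? 1 : 0);
    eta_hat[i] = e[0];
    if (want_pred) {
      double lam0 = ev.tv, lami = ev.tv * std::exp(e[0]);
      for (int j = 0; j < ev.no; ++j) {
        double frac = (ev.b0 - ev.np[j]) / ev.b0;
        if (frac < 0.0) frac = 0.0;
        if (frac > 1.0) frac = 1.0;
        double pw = frac > 0.0 ? std::pow(frac, lam0) : 0.0;
        pred_pop[optr[i] + j] = ev.base + inr_max * pw;
        pred_grad[optr[i] + j] =
          frac > 0.0 ? inr_max * pw * std::log(frac) * lam0 : 0.0;
        pred_ind[optr[i] + j] = ev.base + inr_max * std::pow(frac, lami);
      }
    }
  }
  List out = List::create(_["ofv"] = total, _["eta"] = eta_hat);
  if (want_pred) {
    out["pred_pop"] = pred_pop; out["pred_ind"] = pred_ind;
    out["pred_grad"] = pred_grad;
  }
  return out;
}
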