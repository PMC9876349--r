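// Core numerics for the spheroid growth models:
//  - Newton/bisection inversions of the algebraic structure constraints
//    (necrotic and inhibited radii given the outer radius),
//  - adaptive Cash-Karp RK45 integration of the Greenspan model and of the
//    deoxygenation / re-oxygenation switching models.
// All radii in micrometres, times in days, volumes in cubic micrometres.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI4_3 = 4.0 * M_PI / 3.0;

// ---------------------------------------------------------------------------
// Algebraic inversions
// ---------------------------------------------------------------------------

// Necrotic radius: root in [0, Ro) of
//   Rc^2 = Ro^2 - 3 Rn^2 + 2 Rn^3 / Ro
// The RHS is strictly decreasing in Rn on (0, Ro), so the root is unique.
// Returns 0 when Ro <= Rc (core not yet formed).
static double necrotic_root(double Ro, double Rc) {
  if (!(Ro > 0.0)) return 0.0;
  if (Ro <= Rc) return 0.0;
  double lo = 0.0, hi = Ro;
  double x = Ro * 0.5;
  for (int it = 0; it < 100; ++it) {
    double f = Ro * Ro - 3.0 * x * x + 2.0 * x * x * x / Ro - Rc * Rc;
    if (f > 0.0) lo = x; else hi = x;           // f decreasing in x
    double df = -6.0 * x + 6.0 * x * x / Ro;
    double xn = (df != 0.0) ? x - f / df : 0.5 * (lo + hi);
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
    if (std::fabs(xn - x) < 1e-12 * Ro + 1e-13) { x = xn; break; }
    x = xn;
  }
  return x;
}

// Inhibited radius: root in [Rn, Ro) of
//   Rbar^2 = Ro^2 - Ri^2 - 2 Rn^3 (1/Ri - 1/Ro)
// The RHS is strictly decreasing in Ri on [Rn, Ro]. Returns 0 when the
// spheroid is too small (Ro <= Rbar) or when the waste concentration never
// reaches the inhibition threshold (its maximum, at r = Rn, is below Rbar^2).
static double inhibited_root(double Ro, double Rn, double Rbar) {
  if (!(Ro > 0.0)) return 0.0;
  if (Ro <= Rbar) return 0.0;
  if (Rn <= 0.0) {
    double d = Ro * Ro - Rbar * Rbar;
    return d > 0.0 ? std::sqrt(d) : 0.0;
  }
  // value of the constraint function at Ri = Rn (maximum over [Rn, Ro])
  double gmax = Ro * Ro - 3.0 * Rn * Rn + 2.0 * Rn * Rn * Rn / Ro - Rbar * Rbar;
  if (gmax <= 0.0) return (gmax == 0.0) ? Rn : 0.0;
  double lo = Rn, hi = Ro;
  double x = 0.5 * (Rn + Ro);
  for (int it = 0; it < 100; ++it) {
    double g = Ro * Ro - x * x - 2.0 * Rn * Rn * Rn * (1.0 / x - 1.0 / Ro) -
               Rbar * Rbar;
    if (g > 0.0) lo = x; else hi = x;           // g decreasing in x
    double dg = -2.0 * x + 2.0 * Rn * Rn * Rn / (x * x);
    double xn = (dg != 0.0) ? x - g / dg : 0.5 * (lo + hi);
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
    if (std::fabs(xn - x) < 1e-12 * Ro + 1e-13) { x = xn; break; }
    x = xn;
  }
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_necrotic_root(NumericVector Ro, NumericVector Rc) {
  R_xlen_t n = std::max(Ro.size(), Rc.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = necrotic_root(Ro[i % Ro.size()], Rc[i % Rc.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_inhibited_root(NumericVector Ro, NumericVector Rn,
                                 NumericVector Rbar) {
  R_xlen_t n = std::max(Ro.size(), std::max(Rn.size(), Rbar.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = inhibited_root(Ro[i % Ro.size()], Rn[i % Rn.size()],
                            Rbar[i % Rbar.size()]);
  return out;
}

// ---------------------------------------------------------------------------
// Cash-Karp RK45 stepper (state dimension <= 2)
// ---------------------------------------------------------------------------

struct StepResult { bool ok; double err; };

template <class RHS>
static StepResult ck45_step(const RHS& rhs, double t, const double* y, int n,
                            double h, double* yout, double* yerr) {
  static const double a21 = 1.0 / 5.0;
  static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
  static const double a41 = 3.0 / 10.0, a42 = -9.0 / 10.0, a43 = 6.0 / 5.0;
  static const double a51 = -11.0 / 54.0, a52 = 5.0 / 2.0,
                      a53 = -70.0 / 27.0, a54 = 35.0 / 27.0;
  static const double a61 = 1631.0 / 55296.0, a62 = 175.0 / 512.0,
                      a63 = 575.0 / 13824.0, a64 = 44275.0 / 110592.0,
                      a65 = 253.0 / 4096.0;
  static const double c2 = 1.0 / 5.0, c3 = 3.0 / 10.0, c4 = 3.0 / 5.0,
                      c5 = 1.0, c6 = 7.0 / 8.0;
  static const double b1 = 37.0 / 378.0, b3 = 250.0 / 621.0,
                      b4 = 125.0 / 594.0, b6 = 512.0 / 1771.0;
  static const double d1 = b1 - 2825.0 / 27648.0, d3 = b3 - 18575.0 / 48384.0,
                      d4 = b4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                      d6 = b6 - 1.0 / 4.0;
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], tmp[2];
  if (!rhs(t, y, k1)) return {false, 0.0};
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * a21 * k1[i];
  if (!rhs(t + c2 * h, tmp, k2)) return {false, 0.0};
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  if (!rhs(t + c3 * h, tmp, k3)) return {false, 0.0};
  for (int i = 0; i < n; ++i)
    tmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  if (!rhs(t + c4 * h, tmp, k4)) return {false, 0.0};
  for (int i = 0; i < n; ++i)
    tmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  if (!rhs(t + c5 * h, tmp, k5)) return {false, 0.0};
  for (int i = 0; i < n; ++i)
    tmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                         a64 * k4[i] + a65 * k5[i]);
  if (!rhs(t + c6 * h, tmp, k6)) return {false, 0.0};
  for (int i = 0; i < n; ++i) {
    yout[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b6 * k6[i]);
    yerr[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                   d6 * k6[i]);
  }
  return {true, 0.0};
}

// Advance y from t0 to t1 with local error control. Returns false on failure.
template <class RHS>
static bool integrate_to(const RHS& rhs, double t0, double t1, double* y,
                         int n, double rtol, double atol, double* hguess) {
  double t = t0;
  double h = *hguess;
  if (h <= 0.0) h = (t1 - t0) * 0.01 + 1e-6;
  int maxsteps = 2000000;
  while (t < t1 && maxsteps-- > 0) {
    if (t + h > t1) h = t1 - t;
    double yout[2], yerr[2];
    StepResult sr = ck45_step(rhs, t, y, n, h, yout, yerr);
    if (!sr.ok) return false;
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yout[i]));
      err = std::max(err, std::fabs(yerr[i]) / sc);
    }
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) y[i] = yout[i];
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.25));
    }
    if (h < 1e-12) return false;
  }
  *hguess = h;
  return maxsteps > 0;
}

// ---------------------------------------------------------------------------
// Greenspan model (constant environment)
// ---------------------------------------------------------------------------

struct GreenspanRHS {
  double s, lambda, Rc, Rbar;
  bool operator()(double, const double* y, double* dy) const {
    double Ro = y[0];
    if (!(Ro > 0.0) || !std::isfinite(Ro)) return false;
    double Rn = necrotic_root(Ro, Rc);
    double Ri = inhibited_root(Ro, Rn, Rbar);
    double inner = std::max(Ri * Ri * Ri, Rn * Rn * Rn);
    dy[0] = s / (3.0 * Ro * Ro) * (Ro * Ro * Ro - inner) -
            lambda * Rn * Rn * Rn / (Ro * Ro);
    return true;
  }
};

// Locate the time in (tlo, thi) at which Ro crosses `target`, by bisection
// with re-integration from (tlo, ylo). Accurate well below 1e-6 days.
template <class RHS>
static double locate_crossing(const RHS& rhs, double tlo, double ylo,
                              double thi, double target, double rtol,
                              double atol) {
  double lo = tlo, hi = thi;
  for (int it = 0; it < 60 && (hi - lo) > 1e-10; ++it) {
    double mid = 0.5 * (lo + hi);
    double y[1] = {ylo};
    double h = (mid - tlo) * 0.1 + 1e-8;
    if (!integrate_to(rhs, tlo, mid, y, 1, rtol, atol, &h)) break;
    if (y[0] < target) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
List cpp_solve_greenspan(double Ro0, double s, double lambda, double Rc,
                         double Rbar, NumericVector times, double rtol,
                         double atol) {
  R_xlen_t nt = times.size();
  NumericVector Ro(nt), Rn(nt), Ri(nt);
  GreenspanRHS rhs{s, lambda, Rc, Rbar};
  double y[1] = {Ro0};
  double t = times[0];
  double h = 0.0;
  double t_inh = NA_REAL, t_nec = NA_REAL;
  if (Ro0 > Rbar) t_inh = times[0];
  if (Ro0 > Rc) t_nec = times[0];
  for (R_xlen_t i = 0; i < nt; ++i) {
    double tprev = t, yprev = y[0];
    if (times[i] > t) {
      if (!integrate_to(rhs, t, times[i], y, 1, rtol, atol, &h))
        stop("Greenspan solver failed at t = %g (last Ro = %g)", t, y[0]);
      t = times[i];
    }
    if (ISNA(t_inh) && yprev <= Rbar && y[0] > Rbar)
      t_inh = locate_crossing(rhs, tprev, yprev, t, Rbar, rtol, atol);
    if (ISNA(t_nec) && yprev <= Rc && y[0] > Rc)
      t_nec = locate_crossing(rhs, tprev, yprev, t, Rc, rtol, atol);
    Ro[i] = y[0];
    Rn[i] = necrotic_root(y[0], Rc);
    Ri[i] = inhibited_root(y[0], Rn[i], Rbar);
  }
  return List::create(_["time"] = times, _["R_o"] = Ro, _["R_n"] = Rn,
                      _["R_i"] = Ri, _["t_inhibited_forms"] = t_inh,
                      _["t_necrotic_forms"] = t_nec);
}

// ---------------------------------------------------------------------------
// Switching models
// ---------------------------------------------------------------------------

static inline double relax_c(double vn, double vh, double tau, double t,
                             double ts) {
  return vh + (vn - vh) * std::exp(-(t - ts) / tau);
}

struct SwitchPars {
  // endpoint values: "a" = pre-switch, "b" = post-switch endpoint
  double u_a, u_b, tau_u;        // lumped consumption, pressure / um^2
  double Rbar_a, Rbar_b, tau_Rbar;
  double s_a, s_b, tau_s;
  double lambda_a, lambda_b, tau_lambda;
  double p_post;                 // ambient pressure after the switch
  double ts;
  // necrotic-core exchange rates
  double lhat0, tau_lhat;        // deoxygenation: death in the new anoxic shell
  double ltilde0, tau_ltilde;    // re-oxygenation: clearance of oxygenated core
  double nu;                     // recovered fraction of cleared core volume
  double lambda_eq;              // fast tracking of the algebraic core
  bool reoxy;
};

// Post-switch RHS; state y = (Ro, Vn).
struct SwitchRHS {
  SwitchPars p;
  bool operator()(double t, const double* y, double* dy) const {
    double Ro = y[0];
    double Vn = std::max(y[1], 0.0);
    if (!(Ro > 0.0) || !std::isfinite(Ro) || !std::isfinite(Vn)) return false;
    double u = relax_c(p.u_a, p.u_b, p.tau_u, t, p.ts);
    double Rc_t = std::sqrt(p.p_post / u);
    double Rbar_t = relax_c(p.Rbar_a, p.Rbar_b, p.tau_Rbar, t, p.ts);
    double s_t = relax_c(p.s_a, p.s_b, p.tau_s, t, p.ts);
    double lam_t = relax_c(p.lambda_a, p.lambda_b, p.tau_lambda, t, p.ts);
    double Rn = std::cbrt(Vn / PI4_3);
    double Rnp = necrotic_root(Ro, Rc_t);
    double Vnp = PI4_3 * Rnp * Rnp * Rnp;
    double Ri = inhibited_root(Ro, Rn, Rbar_t);
    double inner = std::max(Ri * Ri * Ri, Rn * Rn * Rn);
    double dRo = s_t / 3.0 * (Ro * Ro * Ro - inner) - lam_t * Rn * Rn * Rn;
    double dVn;
    // The shell exchange rates grow exponentially so that the core
    // converges onto its quasi-steady prediction; once they exceed every
    // other rate by orders of magnitude the dynamics are indistinguishable
    // from perfect tracking, so they are capped to keep the system
    // integrable by an explicit method (tracking error ~ lambda/cap).
    const double rate_cap = 500.0;
    if (!p.reoxy) {
      double lhat = std::min(p.lhat0 * std::exp((t - p.ts) / p.tau_lhat),
                             rate_cap);
      dVn = 3.0 * lhat * std::max(Vnp - Vn, 0.0) - 3.0 * lam_t * Vn;
    } else {
      double lt = std::min(p.ltilde0 * std::exp((t - p.ts) / p.tau_ltilde),
                           rate_cap);
      double shell = std::max(Vn - Vnp, 0.0);
      double fill = std::max(Vnp - Vn, 0.0);
      dVn = 3.0 * p.lambda_eq * fill - 3.0 * lt * shell - 3.0 * lam_t * Vn;
      dRo -= (1.0 - p.nu) * lt * shell * 3.0 / (4.0 * M_PI);
    }
    if (y[1] <= 0.0 && dVn < 0.0) dVn = 0.0;
    dy[0] = dRo / (Ro * Ro);
    dy[1] = dVn;
    return true;
  }
};

// Pre-switch RHS for re-oxygenation runs: constant pre-switch coefficients,
// core tracks the algebraic value through the lambda_eq channel so a free
// initial core radius is admissible.
struct PreSwitchRHS {
  double s, lambda, Rc, Rbar, lambda_eq;
  bool operator()(double, const double* y, double* dy) const {
    double Ro = y[0];
    double Vn = std::max(y[1], 0.0);
    if (!(Ro > 0.0) || !std::isfinite(Ro) || !std::isfinite(Vn)) return false;
    double Rn = std::cbrt(Vn / PI4_3);
    double Rnp = necrotic_root(Ro, Rc);
    double Vnp = PI4_3 * Rnp * Rnp * Rnp;
    double Ri = inhibited_root(Ro, Rn, Rbar);
    double inner = std::max(Ri * Ri * Ri, Rn * Rn * Rn);
    double dVn = 3.0 * lambda_eq * (Vnp - Vn) - 3.0 * lambda * Vn;
    if (y[1] <= 0.0 && dVn < 0.0) dVn = 0.0;
    dy[0] = (s / 3.0 * (Ro * Ro * Ro - inner) - lambda * Rn * Rn * Rn) /
            (Ro * Ro);
    dy[1] = dVn;
    return true;
  }
};

static List switch_trajectory(const SwitchPars& sp, double Ro0, double Vn0,
                              bool dynamic_pre, double pre_Rc,
                              NumericVector times, double rtol, double atol) {
  R_xlen_t nt = times.size();
  NumericVector Ro(nt), Vn(nt), Rn(nt), Ri(nt), Rnp(nt), Rc_t(nt), Rbar_t(nt),
      s_t(nt), lam_t(nt), exch(nt);
  SwitchRHS post{sp};
  GreenspanRHS pre1{sp.s_a, sp.lambda_a, pre_Rc, sp.Rbar_a};
  PreSwitchRHS pre2{sp.s_a, sp.lambda_a, pre_Rc, sp.Rbar_a, sp.lambda_eq};
  double y[2] = {Ro0, Vn0};
  double t = times[0];
  double h = 0.0;
  bool switched = t >= sp.ts;
  for (R_xlen_t i = 0; i < nt; ++i) {
    double tnext = times[i];
    if (tnext > t) {
      if (!switched && tnext > sp.ts) {
        // advance exactly to the switch, then hand over continuously
        bool ok = dynamic_pre
                      ? integrate_to(pre2, t, sp.ts, y, 2, rtol, atol, &h)
                      : integrate_to(pre1, t, sp.ts, y, 1, rtol, atol, &h);
        if (!ok) stop("pre-switch solver failed near t = %g", t);
        if (!dynamic_pre) {
          double rn = necrotic_root(y[0], pre_Rc);
          y[1] = PI4_3 * rn * rn * rn;
        }
        t = sp.ts;
        switched = true;
        h = 0.0;
      }
      bool post_seg = switched || tnext <= sp.ts;
      if (t < tnext) {
        bool ok;
        if (t >= sp.ts) ok = integrate_to(post, t, tnext, y, 2, rtol, atol, &h);
        else if (dynamic_pre)
          ok = integrate_to(pre2, t, tnext, y, 2, rtol, atol, &h);
        else
          ok = integrate_to(pre1, t, tnext, y, 1, rtol, atol, &h);
        if (!ok)
          stop("switching-model solver failed near t = %g (Ro = %g)", t, y[0]);
        t = tnext;
      }
      (void)post_seg;
    }
    bool after = t >= sp.ts;
    double rc = after ? std::sqrt(sp.p_post /
                                  relax_c(sp.u_a, sp.u_b, sp.tau_u, t, sp.ts))
                      : pre_Rc;
    double rbar = after ? relax_c(sp.Rbar_a, sp.Rbar_b, sp.tau_Rbar, t, sp.ts)
                        : sp.Rbar_a;
    double sv = after ? relax_c(sp.s_a, sp.s_b, sp.tau_s, t, sp.ts) : sp.s_a;
    double lv = after ? relax_c(sp.lambda_a, sp.lambda_b, sp.tau_lambda, t,
                                sp.ts)
                      : sp.lambda_a;
    double vn = (after || dynamic_pre)
                    ? std::max(y[1], 0.0)
                    : [&] { double rn = necrotic_root(y[0], pre_Rc);
                            return PI4_3 * rn * rn * rn; }();
    double rn = std::cbrt(vn / PI4_3);
    Ro[i] = y[0];
    Vn[i] = vn;
    Rn[i] = rn;
    Rnp[i] = necrotic_root(y[0], rc);
    Ri[i] = inhibited_root(y[0], rn, rbar);
    Rc_t[i] = rc;
    Rbar_t[i] = rbar;
    s_t[i] = sv;
    lam_t[i] = lv;
    exch[i] = !after ? 0.0
              : (!sp.reoxy ? sp.lhat0 * std::exp((t - sp.ts) / sp.tau_lhat)
                           : sp.ltilde0 * std::exp((t - sp.ts) / sp.tau_ltilde));
  }
  return List::create(_["time"] = times, _["R_o"] = Ro, _["R_n"] = Rn,
                      _["R_i"] = Ri, _["R_n_plus"] = Rnp, _["V_n"] = Vn,
                      _["R_c_t"] = Rc_t, _["Rbar_t"] = Rbar_t, _["s_t"] = s_t,
                      _["lambda_t"] = lam_t, _["exchange_rate"] = exch);
}

// [[Rcpp::export]]
List cpp_solve_deoxygenation(double Ro0, double u_n, double u_h,
                             double tau_alpha, double Rbar_n, double Rbar_h,
                             double tau_Rbar, double s_n, double s_h,
                             double tau_s, double lambda_n, double lambda_h,
                             double tau_lambda, double lhat0, double tau_lhat,
                             double ts, double p_pre, double p_post,
                             NumericVector times, double rtol, double atol) {
  SwitchPars sp;
  sp.u_a = u_n; sp.u_b = u_h; sp.tau_u = tau_alpha;
  sp.Rbar_a = Rbar_n; sp.Rbar_b = Rbar_h; sp.tau_Rbar = tau_Rbar;
  sp.s_a = s_n; sp.s_b = s_h; sp.tau_s = tau_s;
  sp.lambda_a = lambda_n; sp.lambda_b = lambda_h; sp.tau_lambda = tau_lambda;
  sp.p_post = p_post; sp.ts = ts;
  sp.lhat0 = lhat0; sp.tau_lhat = tau_lhat;
  sp.ltilde0 = 0.0; sp.tau_ltilde = 1.0; sp.nu = 0.0; sp.lambda_eq = 0.0;
  sp.reoxy = false;
  double pre_Rc = std::sqrt(p_pre / u_n);
  return switch_trajectory(sp, Ro0, 0.0, false, pre_Rc, times, rtol, atol);
}

// [[Rcpp::export]]
List cpp_solve_reoxygenation(double Ro0, double Rn0, double u_n, double u_h,
                             double tau_alpha, double Rbar_n, double Rbar_h,
                             double tau_Rbar, double s_n, double s_h,
                             double tau_s, double lambda_n, double lambda_h,
                             double tau_lambda, double ltilde0,
                             double tau_ltilde, double nu, double lambda_eq,
                             double ts, double p_pre, double p_post,
                             NumericVector times, double rtol, double atol) {
  SwitchPars sp;
  // pre-switch = hypoxia endpoints, post-switch relaxes h -> n
  sp.u_a = u_h; sp.u_b = u_n; sp.tau_u = tau_alpha;
  sp.Rbar_a = Rbar_h; sp.Rbar_b = Rbar_n; sp.tau_Rbar = tau_Rbar;
  sp.s_a = s_h; sp.s_b = s_n; sp.tau_s = tau_s;
  sp.lambda_a = lambda_h; sp.lambda_b = lambda_n; sp.tau_lambda = tau_lambda;
  sp.p_post = p_post; sp.ts = ts;
  sp.lhat0 = 0.0; sp.tau_lhat = 1.0;
  sp.ltilde0 = ltilde0; sp.tau_ltilde = tau_ltilde; sp.nu = nu;
  sp.lambda_eq = lambda_eq;
  sp.reoxy = true;
  double pre_Rc = std::sqrt(p_pre / u_h);
  double Vn0 = PI4_3 * Rn0 * Rn0 * Rn0;
  return switch_trajectory(sp, Ro0, Vn0, true, pre_Rc, times, rtol, atol);
}
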