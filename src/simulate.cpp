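#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed parameter ordering shared with R/parameters.R (par_order()).
// Any change here must be mirrored there.
enum ParIdx {
  P_PU, R_PU, R_PV, L_PV, R_PVC, C_PVC,
  KS_LA, E_MIN_LA, E_MAX_LA, V0_LA, M1_LA, M2_LA, A1_LA, A2_LA, RV_LA, ON_LA,
  KS_LV, E_MIN_LV, E_MAX_LV, V0_LV, M1_LV, M2_LV, A1_LV, A2_LV, RV_LV, ON_LV,
  R_MV, L_MV,
  EOA_AV, A_AO, L_AV,
  R_AA, L_AA, R_AAV, C_AA,
  R_PSA, R_DSA, C_PSA,
  R_PIA, C_PIA, R_DIA,
  R_DA, L_DA, R_DAV, C_DA,
  R_PDA, R_DDA, C_PDA,
  T_CYC, RHO,
  NPAR
};

static const double MMHG_PER_BARYE = 1.0 / 1333.22;
static const int NSTATE = 13;

// State ordering: V_LA, V_LV, Q_pv, Q_mv, Q_av, Q_aa, Q_da,
//                 P_pvc, P_caa, P_cpsa, P_cpia, P_cda, P_cpda
enum StIdx {
  iV_LA, iV_LV, iQ_PV, iQ_MV, iQ_AV, iQ_AA, iQ_DA,
  iP_PVC, iP_CAA, iP_CPSA, iP_CPIA, iP_CDA, iP_CPDA
};

// Normalized double-Hill shape g(s) on s in [0,1): rises with Hill
// exponent m1 (half-activation at a1), falls with exponent m2 (a2).
static inline double hill_shape(double s, double m1, double m2,
                                double a1, double a2) {
  double x1 = std::pow(s / a1, m1);
  double x2 = std::pow(s / a2, m2);
  return (x1 / (1.0 + x1)) * (1.0 / (1.0 + x2));
}

// Maximum of the normalized shape over one cycle: coarse grid followed by
// golden-section refinement.  Depends only on the four shape constants.
// [[Rcpp::export]]
double cpp_hill_shape_max(double m1, double m2, double a1, double a2) {
  const int n = 4096;
  double best = 0.0; int ibest = 0;
  for (int i = 1; i < n; ++i) {
    double s = (double)i / n;
    double g = hill_shape(s, m1, m2, a1, a2);
    if (g > best) { best = g; ibest = i; }
  }
  double lo = std::max(1e-12, (double)(ibest - 1) / n);
  double hi = std::min(1.0 - 1e-12, (double)(ibest + 1) / n);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
  double fc = hill_shape(c, m1, m2, a1, a2);
  double fd = hill_shape(d, m1, m2, a1, a2);
  for (int k = 0; k < 80; ++k) {
    if (fc < fd) {
      lo = c; c = d; fc = fd;
      d = lo + gr * (hi - lo); fd = hill_shape(d, m1, m2, a1, a2);
    } else {
      hi = d; d = c; fd = fc;
      c = hi - gr * (hi - lo); fc = hill_shape(c, m1, m2, a1, a2);
    }
  }
  return std::max(best, std::max(fc, fd));
}

// Elastance at absolute time t (s); gmax is the cached shape maximum.
static inline double elastance_at(double t, double emin, double emax,
                                  double m1, double m2, double a1, double a2,
                                  double onset, double T, double gmax) {
  // (t - onset) mod T, mapped to [0, 1).  fmod is avoided deliberately:
  // with this toolchain it links a glibc symbol version the runtime
  // loader cannot resolve.
  double u = (t - onset) / T;
  double s = u - std::floor(u);
  if (s <= 0.0) return emin;
  double g = hill_shape(s, m1, m2, a1, a2);
  return (emax - emin) * g / gmax + emin;
}

// [[Rcpp::export]]
NumericVector cpp_elastance(NumericVector t, double emin, double emax,
                            double m1, double m2, double a1, double a2,
                            double onset, double T) {
  double gmax = cpp_hill_shape_max(m1, m2, a1, a2);
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = elastance_at(t[i], emin, emax, m1, m2, a1, a2, onset, T, gmax);
  return out;
}

struct Model {
  const double *p;
  double elco;           // energy loss coefficient, cm^2
  double gmax_la, gmax_lv;
  double p_ven;          // venous reference pressure at Windkessel outlets
  bool mv_open, av_open;
  double E_la, E_lv;     // elastances frozen at the implicit time level

  void set_time(double t) {
    E_la = elastance_at(t, p[E_MIN_LA], p[E_MAX_LA], p[M1_LA], p[M2_LA],
                        p[A1_LA], p[A2_LA], p[ON_LA], p[T_CYC], gmax_la);
    E_lv = elastance_at(t, p[E_MIN_LV], p[E_MAX_LV], p[M1_LV], p[M2_LV],
                        p[A1_LV], p[A2_LV], p[ON_LV], p[T_CYC], gmax_lv);
  }

  // Algebraic node pressures for a given state.
  inline double pressure_la(const double *x) const {
    return E_la * (x[iV_LA] - p[V0_LA]) * (1.0 - p[KS_LA] * x[iQ_MV]);
  }
  inline double pressure_lv(const double *x) const {
    return E_lv * (x[iV_LV] - p[V0_LV]) * (1.0 - p[KS_LV] * x[iQ_AV]);
  }
  inline double pressure_ao(const double *x) const {
    return x[iP_CAA] + p[R_AAV] * (x[iQ_AV] - x[iQ_AA]);
  }
  inline double pressure_arch(const double *x) const {
    double g = 1.0 / p[R_PSA] + 1.0 / p[R_PIA] + 1.0 / p[R_DAV];
    return (x[iQ_AA] - x[iQ_DA] + x[iP_CPSA] / p[R_PSA] +
            x[iP_CPIA] / p[R_PIA] + x[iP_CDA] / p[R_DAV]) / g;
  }

  void rhs(const double *x, double *dx) const {
    double P_la = pressure_la(x);
    double P_lv = pressure_lv(x);
    double P_ao = pressure_ao(x);
    double P_arch = pressure_arch(x);
    double Q_sa = (P_arch - x[iP_CPSA]) / p[R_PSA];
    double Q_ia = (P_arch - x[iP_CPIA]) / p[R_PIA];
    double i_cda = (P_arch - x[iP_CDA]) / p[R_DAV];
    double P_term = x[iP_CPDA] + p[R_PDA] * x[iQ_DA];
    double i_pvc = ((p[P_PU] - x[iP_PVC]) - p[R_PU] * x[iQ_PV]) /
                   (p[R_PU] + p[R_PVC]);
    double P_pvn = x[iP_PVC] + p[R_PVC] * i_pvc;

    dx[iV_LA] = x[iQ_PV] - x[iQ_MV];
    dx[iV_LV] = x[iQ_MV] - x[iQ_AV];
    dx[iQ_PV] = (P_pvn - P_la - p[R_PV] * x[iQ_PV]) / p[L_PV];
    if (mv_open) {
      dx[iQ_MV] = (P_la - (p[RV_LA] + p[R_MV]) * x[iQ_MV] - P_lv) / p[L_MV];
    } else dx[iQ_MV] = 0.0;
    if (av_open) {
      double q = x[iQ_AV];
      double quad = p[RHO] * q * std::fabs(q) /
                    (2.0 * elco * elco) * MMHG_PER_BARYE;
      dx[iQ_AV] = (P_lv - p[RV_LV] * q - quad - P_ao) / p[L_AV];
    } else dx[iQ_AV] = 0.0;
    dx[iQ_AA] = (P_ao - P_arch - p[R_AA] * x[iQ_AA]) / p[L_AA];
    dx[iQ_DA] = (P_arch - P_term - p[R_DA] * x[iQ_DA]) / p[L_DA];
    dx[iP_PVC] = i_pvc / p[C_PVC];
    dx[iP_CAA] = (x[iQ_AV] - x[iQ_AA]) / p[C_AA];
    dx[iP_CPSA] = (Q_sa - (x[iP_CPSA] - p_ven) / p[R_DSA]) / p[C_PSA];
    dx[iP_CPIA] = (Q_ia - (x[iP_CPIA] - p_ven) / p[R_DIA]) / p[C_PIA];
    dx[iP_CDA] = i_cda / p[C_DA];
    dx[iP_CPDA] = (x[iQ_DA] - (x[iP_CPDA] - p_ven) / p[R_DDA]) / p[C_PDA];
  }
};

// Solve A x = b in place (A n x n row-major), Gaussian elimination with
// partial pivoting.  Small fixed n, no pivoting pathology expected.
static bool solve_lin(double *A, double *b, int n) {
  for (int k = 0; k < n; ++k) {
    int piv = k; double amax = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(A[i * n + k]);
      if (v > amax) { amax = v; piv = i; }
    }
    if (amax < 1e-300) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = A[i * n + k] / A[k * n + k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) A[i * n + j] -= f * A[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= A[i * n + j] * b[j];
    b[i] = s / A[i * n + i];
  }
  return true;
}

// One implicit sub-step of length h starting at time t0.  A damped
// theta scheme: x1 = x0 + h [(1-theta) f(t0, x0) + theta f(t0+h, x1)].
// theta = 0.55 keeps strong damping of the stiff capacitor/inertance
// modes (A-stable, |R(inf)| < 1) while shrinking the first-order
// truncation error by an order of magnitude versus backward Euler,
// which the step-size convergence requirement on the flow waveforms
// needs.  x is updated in place.
static const double THETA = 0.55;

static void be_substep(Model &m, double *x, double t0, double h,
                       int newton_iters) {
  double xn[NSTATE], f0[NSTATE], fx[NSTATE], fpert[NSTATE];
  double Jm[NSTATE * NSTATE], A[NSTATE * NSTATE], b[NSTATE];
  m.set_time(t0);
  m.rhs(x, f0);
  m.set_time(t0 + h);
  for (int i = 0; i < NSTATE; ++i) xn[i] = x[i];

  // Jacobian of f at the step start (frozen over Newton iterations)
  m.rhs(x, fx);
  for (int j = 0; j < NSTATE; ++j) {
    double eps = 1e-6 * (1.0 + std::fabs(x[j]));
    double save = x[j];
    x[j] = save + eps;
    m.rhs(x, fpert);
    x[j] = save;
    for (int i = 0; i < NSTATE; ++i)
      Jm[i * NSTATE + j] = (fpert[i] - fx[i]) / eps;
  }

  double ht = THETA * h;
  for (int it = 0; it < newton_iters; ++it) {
    m.rhs(x, fx);
    // residual r = x - xn - h[(1-theta) f0 + theta f(x)]
    double rmax = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      b[i] = -(x[i] - xn[i] - h * (1.0 - THETA) * f0[i] - ht * fx[i]);
      double r = std::fabs(b[i]);
      if (r > rmax) rmax = r;
      for (int j = 0; j < NSTATE; ++j)
        A[i * NSTATE + j] = (i == j ? 1.0 : 0.0) - ht * Jm[i * NSTATE + j];
    }
    if (rmax < 1e-12) break;
    if (!solve_lin(A, b, NSTATE))
      stop("singular Newton system at t = %f", t0 + h);
    for (int i = 0; i < NSTATE; ++i) x[i] += b[i];
  }
  if (!m.mv_open) x[iQ_MV] = 0.0;
  if (!m.av_open) x[iQ_AV] = 0.0;
}

// Valve event indicators.  A closed valve opens when the pressure
// gradient becomes positive.  An open valve closes when the flow
// reaches zero from above WITH an adverse gradient: grazing zero-flow
// dips under a forward gradient (mid-diastolic diastasis) leave the
// valve open, which removes open/close chatter and keeps the solution
// continuous in the parameters.
static inline double mv_indicator(const Model &m, const double *x) {
  double g = m.pressure_la(x) - m.pressure_lv(x);
  return m.mv_open ? std::max(x[iQ_MV], g) : g;
}
static inline double av_indicator(const Model &m, const double *x) {
  double g = m.pressure_lv(x) - m.pressure_ao(x);
  return m.av_open ? std::max(x[iQ_AV], g) : g;
}

// Backward-Euler integration of the full circuit with sub-step valve
// event localization: when a diode condition changes sign inside a
// step, the step is redone in two parts with the switch applied at the
// interpolated event time.  Without this, event times quantize on the
// solver grid and the fit cost becomes ragged in the parameters.
// Returns a matrix with one row per stored step and columns
// t, 13 states, P_la, P_lv, P_ao, F4, mv_open, av_open.
// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector par, double duration, double dt,
                           NumericVector init, double p_ven,
                           double store_from, int newton_iters) {
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  if (init.size() != NSTATE) stop("initial state has wrong length");
  Model m;
  m.p = REAL(par);
  if (!(par[EOA_AV] > 0 && par[EOA_AV] < par[A_AO]))
    stop("invalid aortic valve geometry: need 0 < eoa_av < a_ao");
  m.elco = par[EOA_AV] * par[A_AO] / (par[A_AO] - par[EOA_AV]);
  m.gmax_la = cpp_hill_shape_max(par[M1_LA], par[M2_LA], par[A1_LA], par[A2_LA]);
  m.gmax_lv = cpp_hill_shape_max(par[M1_LV], par[M2_LV], par[A1_LV], par[A2_LV]);
  m.p_ven = p_ven;
  m.mv_open = false;
  m.av_open = false;

  int nstep = (int)std::round(duration / dt);
  int first_store = 0;
  if (store_from > 0) first_store = (int)std::floor(store_from / dt);
  if (first_store > nstep) first_store = nstep;
  int nout = nstep - first_store + 1;

  NumericMatrix out(nout, 1 + NSTATE + 4 + 2);
  double x[NSTATE], xsave[NSTATE];
  for (int i = 0; i < NSTATE; ++i) x[i] = init[i];

  int row = 0;
  for (int n = 0; n <= nstep; ++n) {
    double t = n * dt;
    if (n >= first_store) {
      m.set_time(t);
      out(row, 0) = t;
      for (int i = 0; i < NSTATE; ++i) out(row, 1 + i) = x[i];
      double P_la = m.pressure_la(x), P_lv = m.pressure_lv(x);
      double P_ao = m.pressure_ao(x), P_arch = m.pressure_arch(x);
      double Q_sa = (P_arch - x[iP_CPSA]) / par[R_PSA];
      out(row, 14) = P_la;
      out(row, 15) = P_lv;
      out(row, 16) = P_ao;
      out(row, 17) = x[iQ_AA] - Q_sa;        // F4: flow past the arch branch
      out(row, 18) = m.mv_open ? 1.0 : 0.0;
      out(row, 19) = m.av_open ? 1.0 : 0.0;
      ++row;
    }
    if (n == nstep) break;

    // advance t -> t + dt, locating at most a few valve events inside
    double t_cur = t;
    double h_left = dt;
    for (int ev = 0; ev < 4 && h_left > 1e-12; ++ev) {
      m.set_time(t_cur);
      double g_mv0 = mv_indicator(m, x);
      double g_av0 = av_indicator(m, x);
      for (int i = 0; i < NSTATE; ++i) xsave[i] = x[i];
      be_substep(m, x, t_cur, h_left, newton_iters);
      m.set_time(t_cur + h_left);
      double g_mv1 = mv_indicator(m, x);
      double g_av1 = av_indicator(m, x);

      // event = indicator crossing zero downward (open valve flow) or
      // upward (closed valve gradient)
      bool ev_mv = m.mv_open ? (g_mv0 > 0.0 && g_mv1 <= 0.0)
                             : (g_mv0 <= 0.0 && g_mv1 > 0.0);
      bool ev_av = m.av_open ? (g_av0 > 0.0 && g_av1 <= 0.0)
                             : (g_av0 <= 0.0 && g_av1 > 0.0);
      // a closed valve whose gradient is already positive at the step
      // start opens immediately (can happen right after another event)
      if (!m.mv_open && g_mv0 > 0.0) { ev_mv = true; }
      if (!m.av_open && g_av0 > 0.0) { ev_av = true; }

      if (!ev_mv && !ev_av) { t_cur += h_left; h_left = 0.0; break; }

      double a_mv = 2.0, a_av = 2.0;   // event fractions within the step
      if (ev_mv) a_mv = (!m.mv_open && g_mv0 > 0.0) ? 0.0
                        : g_mv0 / (g_mv0 - g_mv1);
      if (ev_av) a_av = (!m.av_open && g_av0 > 0.0) ? 0.0
                        : g_av0 / (g_av0 - g_av1);
      bool first_mv = a_mv <= a_av;
      double a = std::min(a_mv, a_av);
      if (a < 0.0) a = 0.0;
      if (a > 1.0) a = 1.0;
      double h_ev = a * h_left;

      // redo the partial step up to the event, then switch the valve
      for (int i = 0; i < NSTATE; ++i) x[i] = xsave[i];
      if (h_ev > 1e-12) be_substep(m, x, t_cur, h_ev, newton_iters);
      if (first_mv) {
        if (m.mv_open) { m.mv_open = false; x[iQ_MV] = 0.0; }
        else           { m.mv_open = true;  x[iQ_MV] = 0.0; }
      } else {
        if (m.av_open) { m.av_open = false; x[iQ_AV] = 0.0; }
        else           { m.av_open = true;  x[iQ_AV] = 0.0; }
      }
      t_cur += h_ev;
      h_left -= h_ev;
    }
    if (h_left > 1e-12) {
      // event budget exhausted; finish the step with current flags
      be_substep(m, x, t_cur, h_left, newton_iters);
    }

    for (int i = 0; i < NSTATE; ++i) {
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e7)
        stop("simulation diverged at t = %f (state %d)", t + dt, i);
    }
  }

  colnames(out) = CharacterVector::create(
    "t", "V_LA", "V_LV", "Q_pv", "Q_mv", "Q_av", "Q_aa", "Q_da",
    "P_pvc", "P_caa", "P_cpsa", "P_cpia", "P_cda", "P_cpda",
    "P_LA", "P_LV", "P_ao", "F4", "mv_open", "av_open");
  return out;
}
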