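// Semi-implicit (Crank-Nicolson) integrator for the myelinated-axon cable
// equation with MRG-class nodal kinetics and Rush-Larsen gate updates.
// Units: mV, ms, uF, mS (so currents are in uA). The extracellular drive
// enters through the axial operator applied to ve(t) = w(t) * ve_static.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x/y)), safe near x = 0
static inline double f1(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-7) return y * (1.0 + r / 2.0);
  return x / (-std::expm1(-r));
}
// x / (exp(x/y) - 1), safe near x = 0
static inline double f2(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-7) return y * (1.0 - r / 2.0);
  return x / std::expm1(r);
}

struct Rates { double am, bm, ah, bh, ap, bp, as, bs; };

// Cached gate tables: steady state and exp(-dt*(a+b)) per gate on a
// uniform voltage grid, rebuilt only when (q1,q2,q3,dt) changes.
struct GateTables {
  double q1 = NA_REAL, q2 = NA_REAL, q3 = NA_REAL, dt = NA_REAL;
  static constexpr double vmin = -250.0, vmax = 200.0, dv = 0.1;
  static constexpr int n = (int)((vmax - vmin) / dv) + 1;
  std::vector<double> minf, mexp, hinf, hexp, pinf, pexp, sinf, sexp;
};
static GateTables gt;

static void build_tables(double q1, double q2, double q3, double dt);
static inline Rates rates(double v, double q1, double q2, double q3) {
  Rates r;
  r.am = q1 * 6.57 * f1(v + 20.4, 10.3);
  r.bm = q1 * 0.304 * f2(v + 25.7, 9.16);
  r.ah = q2 * 0.34 * f2(v + 114.0, 11.0);
  r.bh = q2 * 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
  r.ap = q1 * 0.0353 * f1(v + 27.0, 10.2);
  r.bp = q1 * 0.000883 * f2(v + 34.0, 10.0);
  r.as = q3 * 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
  r.bs = q3 * 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
  return r;
}

static void build_tables(double q1, double q2, double q3, double dt) {
  if (gt.q1 == q1 && gt.q2 == q2 && gt.q3 == q3 && gt.dt == dt) return;
  gt.q1 = q1; gt.q2 = q2; gt.q3 = q3; gt.dt = dt;
  gt.minf.resize(GateTables::n); gt.mexp.resize(GateTables::n);
  gt.hinf.resize(GateTables::n); gt.hexp.resize(GateTables::n);
  gt.pinf.resize(GateTables::n); gt.pexp.resize(GateTables::n);
  gt.sinf.resize(GateTables::n); gt.sexp.resize(GateTables::n);
  for (int i = 0; i < GateTables::n; ++i) {
    double v = GateTables::vmin + i * GateTables::dv;
    Rates r = rates(v, q1, q2, q3);
    double tm = r.am + r.bm, th = r.ah + r.bh,
           tp = r.ap + r.bp, ts = r.as + r.bs;
    gt.minf[i] = r.am / tm; gt.mexp[i] = std::exp(-dt * tm);
    gt.hinf[i] = r.ah / th; gt.hexp[i] = std::exp(-dt * th);
    gt.pinf[i] = r.ap / tp; gt.pexp[i] = std::exp(-dt * tp);
    gt.sinf[i] = r.as / ts; gt.sexp[i] = std::exp(-dt * ts);
  }
}

static inline void table_at(double v, double* out8) {
  double u = (v - GateTables::vmin) / GateTables::dv;
  if (u < 0.0) u = 0.0;
  if (u > GateTables::n - 1.001) u = GateTables::n - 1.001;
  int i = (int)u;
  double f = u - i;
  out8[0] = gt.minf[i] + f * (gt.minf[i + 1] - gt.minf[i]);
  out8[1] = gt.mexp[i] + f * (gt.mexp[i + 1] - gt.mexp[i]);
  out8[2] = gt.hinf[i] + f * (gt.hinf[i + 1] - gt.hinf[i]);
  out8[3] = gt.hexp[i] + f * (gt.hexp[i + 1] - gt.hexp[i]);
  out8[4] = gt.pinf[i] + f * (gt.pinf[i + 1] - gt.pinf[i]);
  out8[5] = gt.pexp[i] + f * (gt.pexp[i + 1] - gt.pexp[i]);
  out8[6] = gt.sinf[i] + f * (gt.sinf[i + 1] - gt.sinf[i]);
  out8[7] = gt.sexp[i] + f * (gt.sexp[i + 1] - gt.sexp[i]);
}

// [[Rcpp::export]]
List cable_run(NumericVector cm, NumericVector ga, LogicalVector is_node,
               NumericVector gnaf, NumericVector gnap, NumericVector gks,
               NumericVector gl, NumericVector epas,
               double ena, double ek, double vinit,
               NumericVector ve, double dt, int nsteps, int i_on, int i_off,
               double q1, double q2, double q3,
               IntegerVector detect, double detect_level, int record_mode) {
  const int n = cm.size();
  const int nd = detect.size();
  build_tables(q1, q2, q3, dt);
  // plain-array working copies of the R inputs for the hot loop
  std::vector<double> cmv(cm.begin(), cm.end()), gav(ga.begin(), ga.end());
  std::vector<double> gnafv(gnaf.begin(), gnaf.end()),
      gnapv(gnap.begin(), gnap.end()), gksv(gks.begin(), gks.end()),
      glv(gl.begin(), gl.end()), epasv(epas.begin(), epas.end()),
      vev(ve.begin(), ve.end());
  std::vector<int> nodev(is_node.begin(), is_node.end());
  std::vector<int> detv(detect.begin(), detect.end());
  std::vector<double> v(n, vinit), m(n), h(n), p(n), s(n);
  std::vector<double> gion(n), ionE(n), diag(n), rhs(n), cp(n), lve(n);
  // gate steady state at vinit
  {
    Rates r0 = rates(vinit, q1, q2, q3);
    for (int i = 0; i < n; ++i) {
      m[i] = r0.am / (r0.am + r0.bm);
      h[i] = r0.ah / (r0.ah + r0.bh);
      p[i] = r0.ap / (r0.ap + r0.bp);
      s[i] = r0.as / (r0.as + r0.bs);
    }
  }
  // precompute L * ve (axial drive from the extracellular profile)
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    if (i > 0) acc += gav[i - 1] * (vev[i - 1] - vev[i]);
    if (i < n - 1) acc += gav[i] * (vev[i + 1] - vev[i]);
    lve[i] = acc;
  }
  std::vector<double> cross(nd, NA_REAL), vmax(nd, vinit);
  std::vector<double> vprev_det(nd, vinit);
  int n_rec = 0;
  NumericMatrix traces;
  if (record_mode == 1) { traces = NumericMatrix(nsteps + 1, nd); n_rec = nsteps + 1; }
  else if (record_mode == 2) { traces = NumericMatrix(nsteps + 1, n); n_rec = nsteps + 1; }
  if (record_mode == 1)
    for (int j = 0; j < nd; ++j) traces(0, j) = v[detv[j]];
  else if (record_mode == 2)
    for (int j = 0; j < n; ++j) traces(0, j) = v[j];

  const double t_on = i_on * dt;
  for (int step = 0; step < nsteps; ++step) {
    // waveform weights at t_n, t_{n+1}: 1 inside the pulse
    double w0 = (step >= i_on && step < i_off) ? 1.0 : 0.0;
    double w1 = (step + 1 >= i_on && step + 1 < i_off) ? 1.0 : 0.0;
    double wmid = 0.5 * (w0 + w1);
    // Rush-Larsen gate update using v at t_n (nodes only; tabulated)
    for (int i = 0; i < n; ++i) {
      if (!nodev[i]) continue;
      double tb[8];
      table_at(v[i], tb);
      m[i] = tb[0] + (m[i] - tb[0]) * tb[1];
      h[i] = tb[2] + (h[i] - tb[2]) * tb[3];
      p[i] = tb[4] + (p[i] - tb[4]) * tb[5];
      s[i] = tb[6] + (s[i] - tb[6]) * tb[7];
    }
    // frozen ionic conductances over the step
    for (int i = 0; i < n; ++i) {
      if (nodev[i]) {
        double gna = gnafv[i] * m[i] * m[i] * m[i] * h[i];
        double gnp = gnapv[i] * p[i] * p[i] * p[i];
        double gk = gksv[i] * s[i];
        gion[i] = gna + gnp + gk + glv[i];
        ionE[i] = gna * ena + gnp * ena + gk * ek + glv[i] * epasv[i];
      } else {
        gion[i] = glv[i];
        ionE[i] = glv[i] * epasv[i];
      }
    }
    // tridiagonal CN system
    for (int i = 0; i < n; ++i) {
      double lv = 0.0, gsum = 0.0;
      if (i > 0) { lv += gav[i - 1] * (v[i - 1] - v[i]); gsum += gav[i - 1]; }
      if (i < n - 1) { lv += gav[i] * (v[i + 1] - v[i]); gsum += gav[i]; }
      diag[i] = cmv[i] / dt + 0.5 * gion[i] + 0.5 * gsum;
      rhs[i] = (cmv[i] / dt - 0.5 * gion[i]) * v[i] + 0.5 * lv + ionE[i] +
               wmid * lve[i];
    }
    // Thomas solve (off-diagonals are -ga/2)
    cp[0] = -0.5 * gav[0] / diag[0];
    rhs[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      double mlt = 1.0 / (diag[i] - (-0.5 * gav[i - 1]) * cp[i - 1]);
      if (i < n - 1) cp[i] = -0.5 * gav[i] * mlt;
      rhs[i] = (rhs[i] - (-0.5 * gav[i - 1]) * rhs[i - 1]) * mlt;
    }
    v[n - 1] = rhs[n - 1];
    for (int i = n - 2; i >= 0; --i) v[i] = rhs[i] - cp[i] * v[i + 1];

    double t1 = (step + 1) * dt;
    for (int j = 0; j < nd; ++j) {
      double vd = v[detv[j]];
      if (vd > vmax[j]) vmax[j] = vd;
      if (ISNA(cross[j]) && vprev_det[j] < detect_level &&
          vd >= detect_level && t1 > t_on)
        cross[j] = t1;
      vprev_det[j] = vd;
    }
    if (record_mode == 1)
      for (int j = 0; j < nd; ++j) traces(step + 1, j) = v[detv[j]];
    else if (record_mode == 2)
      for (int j = 0; j < n; ++j) traces(step + 1, j) = v[j];
    if (record_mode == 0) {
      bool all_crossed = true;
      for (int j = 0; j < nd; ++j) if (ISNA(cross[j])) all_crossed = false;
      if (all_crossed) break;
    }
  }
  bool activated = true;
  for (int j = 0; j < nd; ++j) if (ISNA(cross[j])) activated = false;
  return List::create(_["activated"] = activated,
                      _["cross_times"] = NumericVector(cross.begin(), cross.end()),
                      _["vmax"] = NumericVector(vmax.begin(), vmax.end()),
                      _["v_final"] = NumericVector(v.begin(), v.end()),
                      _["n_rec"] = n_rec,
                      _["traces"] = (record_mode > 0 ? (SEXP)traces : R_NilValue));
}
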