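// ODE cores for the GI (glucose-insulin) and GIG (glucose-insulin-glucagon)
// clamp models, an embedded Cash-Karp Runge-Kutta 4(5) integrator, and
// batched objective evaluation used by the meta-evolutionary search.
//
// Parameter vector layout (shared; the GI model reads only p[0..7]):
//   p[0..7]  k1..k8
//   p[8]  kGN   glucagon sensitivity (glucose production per glucagon conc)
//   p[9]  kGgS  glucagon secretion gain
//   p[10] kGgC  glucagon clearance (1/min)
//   p[11] kratio molar ratio of posthepatic insulin to C-peptide
//   p[12] kCPC  C-peptide clearance (1/min)
//   p[13] I_half structural constant of saturable insulin inhibition (pmol/L)
//   p[14] G_half structural constant of glucose inhibition (mmol/L)
//   p[15] eps_I  insulin floor for the inverse-insulin secretion variant
//   p[16] supp   glucagon secretion mode: 0 saturable-insulin, 1 inverse-
//                insulin, 2 saturable-glucose, 3 both, 4 constant
//
// Infusions f1 (glucose) and f2 (insulin) are per-minute knot vectors,
// linear within each minute; cf1/cf2 convert per-kg infusion rates to
// concentration fluxes. States: GI (Gc, Y, I); GIG (Gc, Y, I, Gg, CP).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int MAXSTATE = 5;

struct ModelSpec {
  int model;              // 1 = GI, 2 = GIG
  const double *p;
  const double *f1, *f2;  // knots at integer minutes, length nknot
  int nknot;
  double cf1, cf2;
};

// Infusions are piecewise constant per minute: f(t) = f[floor(t)]. This is
// exactly how the synthetic generator applies them, so fitting and
// generation share one convention.
static inline double interp_inf(const double *f, int nknot, double t) {
  if (t <= 0.0) return f[0];
  int i = (int)t;
  if (i >= nknot - 1) return f[nknot - 1];
  return f[i];
}

static inline bool rhs(const ModelSpec &m, double t, const double *y,
                       double *dy) {
  const double *p = m.p;
  double Gc = y[0], Y = y[1], I = y[2];
  double X = Y - p[5] > 0.0 ? Y - p[5] : 0.0;  // k6 threshold
  double fin1 = m.cf1 * interp_inf(m.f1, m.nknot, t);
  double fin2 = m.cf2 * interp_inf(m.f2, m.nknot, t);
  if (m.model == 1) {
    dy[0] = fin1 + p[0] - (p[1] + p[3] * I + p[7]) * Gc;
    dy[1] = p[2] * (Gc - Y);
    dy[2] = fin2 + p[4] * X - p[6] * I;
  } else {
    double Gg = y[3], CP = y[4];
    double S = p[4] * X;  // pre-hepatic secretion, pmol/L/min
    double sec;
    int mode = (int)p[16];
    switch (mode) {
    case 0: sec = p[9] / (1.0 + I / p[13]); break;
    case 1: sec = p[9] / (I > p[15] ? I : p[15]); break;
    case 2: sec = p[9] / (1.0 + Gc / p[14]); break;
    case 3: sec = p[9] / ((1.0 + I / p[13]) * (1.0 + Gc / p[14])); break;
    default: sec = p[9];
    }
    dy[0] = fin1 + p[0] + p[8] * Gg - (p[1] + p[3] * I + p[7]) * Gc;
    dy[1] = p[2] * (Gc - Y);
    dy[2] = fin2 + p[11] * S - p[6] * I;
    dy[3] = sec - p[10] * Gg;
    dy[4] = S / 1000.0 - p[12] * CP;  // C-peptide in nmol/L
  }
  for (int i = 0; i < (m.model == 1 ? 3 : 5); ++i)
    if (!R_finite(dy[i])) return false;
  return true;
}

// Cash-Karp coefficients
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
                    c6 = 512.0 / 1771.0;
static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                    d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                    d6 = c6 - 1.0 / 4.0;

// Integrate from t0 to t1, updating y in place. Returns false on failure.
static bool integrate_span(const ModelSpec &m, double t0, double t1, double *y,
                           int ns, double rtol, double atol, long *steps,
                           long max_steps) {
  double t = t0;
  double h = (t1 - t0) * 0.25;
  if (h <= 0.0) return true;
  double k1v[MAXSTATE], k2v[MAXSTATE], k3v[MAXSTATE], k4v[MAXSTATE],
      k5v[MAXSTATE], k6v[MAXSTATE], ytmp[MAXSTATE], yout[MAXSTATE],
      yerr[MAXSTATE];
  while (t < t1 - 1e-12) {
    if (++(*steps) > max_steps) return false;
    if (t + h > t1) h = t1 - t;
    if (!rhs(m, t, y, k1v)) return false;
    for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * b21 * k1v[i];
    if (!rhs(m, t + h / 5.0, ytmp, k2v)) return false;
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (b31 * k1v[i] + b32 * k2v[i]);
    if (!rhs(m, t + 3.0 * h / 10.0, ytmp, k3v)) return false;
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (b41 * k1v[i] + b42 * k2v[i] + b43 * k3v[i]);
    if (!rhs(m, t + 3.0 * h / 5.0, ytmp, k4v)) return false;
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (b51 * k1v[i] + b52 * k2v[i] + b53 * k3v[i] +
                            b54 * k4v[i]);
    if (!rhs(m, t + h, ytmp, k5v)) return false;
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (b61 * k1v[i] + b62 * k2v[i] + b63 * k3v[i] +
                            b64 * k4v[i] + b65 * k5v[i]);
    if (!rhs(m, t + 7.0 * h / 8.0, ytmp, k6v)) return false;
    double errmax = 0.0;
    for (int i = 0; i < ns; ++i) {
      yout[i] = y[i] + h * (c1 * k1v[i] + c3 * k3v[i] + c4 * k4v[i] +
                            c6 * k6v[i]);
      yerr[i] = h * (d1 * k1v[i] + d3 * k3v[i] + d4 * k4v[i] + d5 * k5v[i] +
                     d6 * k6v[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yout[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < ns; ++i) {
        // negative undershoot at solver-tolerance scale is clipped
        y[i] = yout[i] < 0.0 ? 0.0 : yout[i];
        if (!R_finite(y[i])) return false;
      }
      double fac = errmax > 1e-10 ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h *= std::min(5.0, fac);
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errmax, -0.25));
    }
    if (h < 1e-10) return false;
  }
  return true;
}

// Simulate on the integer-minute grid t = 0..duration. Returns a
// (duration+1) x nstate matrix, or a 1x1 NA matrix on failure.
static bool sim_grid(const ModelSpec &m, const double *y0, int ns,
                     int duration, double rtol, double atol, long max_steps,
                     double *out /* (duration+1) x ns, column major */) {
  double y[MAXSTATE];
  for (int i = 0; i < ns; ++i) y[i] = y0[i];
  long steps = 0;
  int nrow = duration + 1;
  for (int i = 0; i < ns; ++i) out[i * nrow] = y[i];
  for (int minute = 0; minute < duration; ++minute) {
    if (!integrate_span(m, minute, minute + 1, y, ns, rtol, atol, &steps,
                        max_steps))
      return false;
    for (int i = 0; i < ns; ++i) out[i * nrow + minute + 1] = y[i];
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix sim_core(int model, NumericVector par, NumericVector y0,
                       NumericVector f1, NumericVector f2, double cf1,
                       double cf2, int duration, double rtol, double atol,
                       double max_steps) {
  int ns = model == 1 ? 3 : 5;
  if (y0.size() != ns) stop("initial state has wrong length");
  ModelSpec m{model, REAL(par), REAL(f1), REAL(f2), (int)f1.size(), cf1, cf2};
  NumericMatrix out(duration + 1, ns);
  bool ok = sim_grid(m, REAL(y0), ns, duration, rtol, atol, (long)max_steps,
                     REAL(out));
  if (!ok) {
    NumericMatrix bad(1, 1);
    bad(0, 0) = NA_REAL;
    return bad;
  }
  return out;
}

// 5-point trailing mean of the minute-grid glucose at integer minute t >= 5:
// mean of samples at t-4 .. t (the samples falling in (t-5, t]).
static inline double wavg5(const double *gc, int t) {
  return (gc[t - 4] + gc[t - 3] + gc[t - 2] + gc[t - 1] + gc[t]) / 5.0;
}

struct ObsSet {
  const int *tGc; int nGc; const double *oGc;
  const int *tI;  int nI;  const double *oI;
  const int *tGg; int nGg; const double *oGg;
  const int *tCP; int nCP; const double *oCP;
  const double *scale;   // observed maxima: Gc, I, Gg, CP
  const double *w;       // variable weights
};

// RSS of one simulated parameter set against normalized observations.
// Simulated glucose passes through the same 5-min trailing mean as the
// measured series; all simulated values are normalized by the observed
// maxima so the objective is a fixed function of the parameters.
static double rss_one(const ModelSpec &m, const double *y0, int ns,
                      int duration, double rtol, double atol, long max_steps,
                      const ObsSet &obs, double *buf) {
  if (!sim_grid(m, y0, ns, duration, rtol, atol, max_steps, buf))
    return R_PosInf;
  int nrow = duration + 1;
  const double *gc = buf, *ii = buf + 2 * nrow;
  const double *gg = buf + 3 * nrow, *cp = buf + 4 * nrow;
  double rss = 0.0, s;
  double acc = 0.0;
  for (int i = 0; i < obs.nGc; ++i) {
    int t = obs.tGc[i];
    s = (t >= 5 ? wavg5(gc, t) : gc[t]) / obs.scale[0] - obs.oGc[i];
    acc += s * s;
  }
  rss += obs.w[0] * acc;
  acc = 0.0;
  for (int i = 0; i < obs.nI; ++i) {
    s = ii[obs.tI[i]] / obs.scale[1] - obs.oI[i];
    acc += s * s;
  }
  rss += obs.w[1] * acc;
  if (m.model == 2) {
    acc = 0.0;
    for (int i = 0; i < obs.nGg; ++i) {
      s = gg[obs.tGg[i]] / obs.scale[2] - obs.oGg[i];
      acc += s * s;
    }
    rss += obs.w[2] * acc;
    acc = 0.0;
    for (int i = 0; i < obs.nCP; ++i) {
      s = cp[obs.tCP[i]] / obs.scale[3] - obs.oCP[i];
      acc += s * s;
    }
    rss += obs.w[3] * acc;
  }
  return R_finite(rss) ? rss : R_PosInf;
}

static ObsSet make_obs(const IntegerVector &tGc, const NumericVector &oGc,
                       const IntegerVector &tI, const NumericVector &oI,
                       const IntegerVector &tGg, const NumericVector &oGg,
                       const IntegerVector &tCP, const NumericVector &oCP,
                       const NumericVector &scale, const NumericVector &w) {
  ObsSet o;
  o.tGc = INTEGER(tGc); o.nGc = tGc.size(); o.oGc = REAL(oGc);
  o.tI = INTEGER(tI);   o.nI = tI.size();   o.oI = REAL(oI);
  o.tGg = INTEGER(tGg); o.nGg = tGg.size(); o.oGg = REAL(oGg);
  o.tCP = INTEGER(tCP); o.nCP = tCP.size(); o.oCP = REAL(oCP);
  o.scale = REAL(scale); o.w = REAL(w);
  return o;
}

// [[Rcpp::export]]
NumericVector objective_batch(int model, NumericMatrix par_matrix,
                              NumericVector y0, NumericVector f1,
                              NumericVector f2, double cf1, double cf2,
                              int duration, IntegerVector tGc,
                              NumericVector oGc, IntegerVector tI,
                              NumericVector oI, IntegerVector tGg,
                              NumericVector oGg, IntegerVector tCP,
                              NumericVector oCP, NumericVector scale,
                              NumericVector w, double rtol, double atol,
                              double max_steps) {
  int ns = model == 1 ? 3 : 5;
  int n = par_matrix.nrow(), np = par_matrix.ncol();
  ObsSet obs = make_obs(tGc, oGc, tI, oI, tGg, oGg, tCP, oCP, scale, w);
  std::vector<double> buf((duration + 1) * MAXSTATE);
  std::vector<double> p(np);
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < np; ++j) p[j] = par_matrix(r, j);
    ModelSpec m{model, p.data(), REAL(f1), REAL(f2), (int)f1.size(), cf1,
                cf2};
    out[r] = rss_one(m, REAL(y0), ns, duration, rtol, atol, (long)max_steps,
                     obs, buf.data());
  }
  return out;
}

// Stacked weighted residual vector (sqrt(w_v) * (sim - obs)) whose squared
// norm equals the objective RSS; used by the local least-squares refinement.
// [[Rcpp::export]]
NumericVector objective_residuals(int model, NumericVector par,
                                  NumericVector y0, NumericVector f1,
                                  NumericVector f2, double cf1, double cf2,
                                  int duration, IntegerVector tGc,
                                  NumericVector oGc, IntegerVector tI,
                                  NumericVector oI, IntegerVector tGg,
                                  NumericVector oGg, IntegerVector tCP,
                                  NumericVector oCP, NumericVector scale,
                                  NumericVector w, double rtol, double atol,
                                  double max_steps) {
  int ns = model == 1 ? 3 : 5;
  ObsSet obs = make_obs(tGc, oGc, tI, oI, tGg, oGg, tCP, oCP, scale, w);
  std::vector<double> buf((duration + 1) * MAXSTATE);
  ModelSpec m{model, REAL(par), REAL(f1), REAL(f2), (int)f1.size(), cf1, cf2};
  int ntot = obs.nGc + obs.nI + (model == 2 ? obs.nGg + obs.nCP : 0);
  NumericVector out(ntot);
  if (!sim_grid(m, REAL(y0), ns, duration, rtol, atol, (long)max_steps,
                buf.data())) {
    std::fill(out.begin(), out.end(), 1e6);  // large finite penalty
    return out;
  }
  int nrow = duration + 1, k = 0;
  const double *gc = buf.data(), *ii = buf.data() + 2 * nrow;
  const double *gg = buf.data() + 3 * nrow, *cp = buf.data() + 4 * nrow;
  double sw0 = std::sqrt(obs.w[0]), sw1 = std::sqrt(obs.w[1]);
  for (int i = 0; i < obs.nGc; ++i) {
    int t = obs.tGc[i];
    out[k++] = sw0 * ((t >= 5 ? wavg5(gc, t) : gc[t]) / obs.scale[0] -
                      obs.oGc[i]);
  }
  for (int i = 0; i < obs.nI; ++i)
    out[k++] = sw1 * (ii[obs.tI[i]] / obs.scale[1] - obs.oI[i]);
  if (model == 2) {
    double sw2 = std::sqrt(obs.w[2]), sw3 = std::sqrt(obs.w[3]);
    for (int i = 0; i < obs.nGg; ++i)
      out[k++] = sw2 * (gg[obs.tGg[i]] / obs.scale[2] - obs.oGg[i]);
    for (int i = 0; i < obs.nCP; ++i)
      out[k++] = sw3 * (cp[obs.tCP[i]] / obs.scale[3] - obs.oCP[i]);
  }
  return out;
}
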