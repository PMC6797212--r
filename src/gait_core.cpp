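// Core forward-dynamics engine for the planar 9-DOF walking model.
//
// Generalized coordinates q (radians / meters):
//   0 pelvis_x, 1 pelvis_y, 2 pelvis_tilt, 3 hip_L, 4 knee_L, 5 ankle_L,
//   6 hip_R, 7 knee_R, 8 ankle_R
// Sign conventions: flexion positive at hip and knee, dorsiflexion positive
// at the ankle, anterior pelvis tilt positive; ground plane at y = 0.
// Bodies: 0 trunk (pelvis+torso+head, lumbar welded), 1-3 thigh/shank/foot L,
// 4-6 thigh/shank/foot R.  State vector y (54): q(9), qdot(9), a(18), lmn(18)
// where a is muscle activation and lmn normalized fiber length.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int NQ = 9;
static const int NM = 18;
static const int NY = 54;
static const int NBODY = 7;
static const int NCH = 56;   // delay channels: lmn(18), vmn(18), Fn(18), theta, thetadot

// phases
enum { PH_ES = 0, PH_MS, PH_PS, PH_S, PH_LP };
// law types
enum { LAW_C = 0, LAW_L = 1, LAW_V = 2, LAW_FP = 3, LAW_FM = 4, LAW_PD = 5 };

struct Vec2 { double x, y; };

// ---------------------------------------------------------------------------
// model / controller containers
// ---------------------------------------------------------------------------

struct Muscle {
  double fmax, lopt, lslack, eref, vmax, tau_a, tau_d, pscale, ftfrac, L0;
  int j[2];            // dof indices (-1 unused)
  double c1[2], c2[2]; // length polynomial coefficients per spanned dof
};

struct Sphere { int leg; double x, y, R, E, c, mu, vtrans; };
struct Lig    { int dof; double lo, hi, K, w; };

struct Model {
  double m[NBODY], I[NBODY];
  Vec2 rcom[NBODY];            // local COM offsets
  double Lth, Lsh;             // thigh / shank lengths
  Vec2 head;                   // head point, local on trunk
  double total_mass, grav, fall_frac;
  // curve shape coefficients
  double w_act, kpe, e0pe, kt, fvK, fvN;
  double sigma, rho;           // muscle specific tension, density (metabolics)
  std::vector<Muscle> mus;
  std::vector<Sphere> sph;
  std::vector<Lig> lig;
};

struct Law {
  int type, target, source, leg, phasemask;
  int p1, p2, p3;              // indices into the 74-vector (-1 unused)
  double delay;
};

struct Controller {
  std::vector<Law> laws;
  int thr_es_ms, thr_ps_s, thr_s_lp, thr_lp_es; // param indices
  double u_floor;
  int init_phase[2];
};

static Model parseModel(const List& ml) {
  Model M;
  NumericVector seg = ml["seg"];
  // order fixed by R side (as_core_model)
  M.m[0] = seg[0];  M.I[0] = seg[1];  M.rcom[0].x = 0; M.rcom[0].y = seg[2];
  M.head.x = 0;     M.head.y = seg[3];
  M.m[1] = M.m[4] = seg[4]; M.I[1] = M.I[4] = seg[5];
  M.Lth  = seg[6];  M.rcom[1].x = M.rcom[4].x = 0; M.rcom[1].y = M.rcom[4].y = -seg[7];
  M.m[2] = M.m[5] = seg[8]; M.I[2] = M.I[5] = seg[9];
  M.Lsh  = seg[10]; M.rcom[2].x = M.rcom[5].x = 0; M.rcom[2].y = M.rcom[5].y = -seg[11];
  M.m[3] = M.m[6] = seg[12]; M.I[3] = M.I[6] = seg[13];
  M.rcom[3].x = M.rcom[6].x = seg[14]; M.rcom[3].y = M.rcom[6].y = seg[15];
  M.total_mass = seg[16];
  M.grav = as<double>(ml["grav"]);
  M.fall_frac = as<double>(ml["fall_frac"]);
  NumericVector cv = ml["curves"];
  M.w_act = cv[0]; M.kpe = cv[1]; M.e0pe = cv[2]; M.kt = cv[3];
  M.fvK = cv[4]; M.fvN = cv[5];
  NumericVector mb = ml["metab"];
  M.sigma = mb[0]; M.rho = mb[1];
  NumericMatrix mm = ml["mus"];
  for (int i = 0; i < mm.nrow(); ++i) {
    Muscle mu;
    mu.fmax = mm(i,0); mu.lopt = mm(i,1); mu.lslack = mm(i,2); mu.eref = mm(i,3);
    mu.vmax = mm(i,4); mu.tau_a = mm(i,5); mu.tau_d = mm(i,6); mu.pscale = mm(i,7);
    mu.ftfrac = mm(i,8); mu.L0 = mm(i,9);
    mu.j[0] = (int) mm(i,10); mu.c1[0] = mm(i,11); mu.c2[0] = mm(i,12);
    mu.j[1] = (int) mm(i,13); mu.c1[1] = mm(i,14); mu.c2[1] = mm(i,15);
    M.mus.push_back(mu);
  }
  NumericMatrix cm = ml["contact"];
  for (int i = 0; i < cm.nrow(); ++i) {
    Sphere s; s.leg = (int) cm(i,0); s.x = cm(i,1); s.y = cm(i,2); s.R = cm(i,3);
    s.E = cm(i,4); s.c = cm(i,5); s.mu = cm(i,6); s.vtrans = cm(i,7);
    M.sph.push_back(s);
  }
  NumericMatrix lm = ml["lig"];
  for (int i = 0; i < lm.nrow(); ++i) {
    Lig l; l.dof = (int) lm(i,0); l.lo = lm(i,1); l.hi = lm(i,2);
    l.K = lm(i,3); l.w = lm(i,4);
    M.lig.push_back(l);
  }
  return M;
}

static Controller parseController(const List& cl) {
  Controller C;
  IntegerMatrix lw = cl["laws"];
  NumericVector dl = cl["delays"];
  for (int i = 0; i < lw.nrow(); ++i) {
    Law L;
    L.type = lw(i,0); L.target = lw(i,1); L.source = lw(i,2); L.leg = lw(i,3);
    L.phasemask = lw(i,4); L.p1 = lw(i,5); L.p2 = lw(i,6); L.p3 = lw(i,7);
    L.delay = dl[i];
    C.laws.push_back(L);
  }
  IntegerVector ti = cl["thr_idx"];
  C.thr_es_ms = ti[0]; C.thr_ps_s = ti[1]; C.thr_s_lp = ti[2]; C.thr_lp_es = ti[3];
  C.u_floor = as<double>(cl["u_floor"]);
  IntegerVector ip = cl["init_phase"];
  C.init_phase[0] = ip[0]; C.init_phase[1] = ip[1];
  return C;
}

// ---------------------------------------------------------------------------
// curves (single source of truth; R wrappers call these)
// ---------------------------------------------------------------------------

static inline double act_fl(double lmn, double w) {
  double x = std::fabs((lmn - 1.0) / w);
  return std::exp(std::log(0.05) * x * x * x);
}
static inline double pas_fl(double lmn, double kpe, double e0) {
  if (lmn <= 1.0) return 0.0;
  return (std::exp(kpe * (lmn - 1.0) / e0) - 1.0) / (std::exp(kpe) - 1.0);
}
// force-velocity vs vbar = v / vmax (shortening negative); C1 at vbar = 0
static inline double fv_curve(double vbar, double K, double N) {
  if (vbar <= -1.0) return 0.0;
  if (vbar <= 0.0) return (1.0 + vbar) / (1.0 - vbar / K);
  double s = (1.0 + 1.0 / K) / (N - 1.0);
  return N - (N - 1.0) * std::exp(-s * vbar);
}
static inline double fv_inverse(double fv, double K, double N) {
  const double eps = 1e-9;
  if (fv < eps) fv = eps;
  if (fv > N - eps) fv = N - eps;
  if (fv <= 1.0) return (fv - 1.0) / (1.0 + fv / K);
  double s = (1.0 + 1.0 / K) / (N - 1.0);
  return -std::log((N - fv) / (N - 1.0)) / s;
}
static inline double ten_fl(double strain, double eref, double kt) {
  if (strain <= 0.0) return 0.0;
  return (std::exp(kt * strain / eref) - 1.0) / (std::exp(kt) - 1.0);
}

// Umberger-style energetics (W), per muscle; see metabolic_rate() docs in R.
static double metab_rate(double a, double u, double lmn, double v_lopt_s,
                         const Muscle& mu, double fl, double fce,
                         double sigma, double rho) {
  double mass = mu.fmax / sigma * rho * mu.lopt; // kg
  double A = (u > a) ? u : 0.5 * (u + a);
  double A_am = std::pow(A, 0.6);
  double A_s  = A * A;
  double ft = mu.ftfrac;
  double hb = 128.0 * ft + 25.0;                 // activation+maintenance, W/kg
  double scale_l = (lmn > 1.0) ? fl : 1.0;
  double h_am = (lmn > 1.0) ? hb * A_am * (0.4 + 0.6 * scale_l) : hb * A_am;
  double vmax_st = mu.vmax / 2.5;
  double a_st = 100.0 / vmax_st, a_ftc = 153.0 / mu.vmax, a_len = 0.3 * a_st;
  double h_sl;
  if (v_lopt_s <= 0.0) {  // shortening
    h_sl = -v_lopt_s * (a_st * (1.0 - ft) + a_ftc * ft) * A_s;
    if (lmn > 1.0) h_sl *= scale_l;
  } else {                // lengthening
    h_sl = v_lopt_s * a_len * A;
    if (lmn > 1.0) h_sl *= scale_l;
  }
  double heat = h_am + h_sl;
  if (heat < 1.0) heat = 1.0;                    // resting heat floor, W/kg
  double w = -fce * v_lopt_s * mu.lopt / mass;   // CE work rate, W/kg
  if (w < 0.0) w = 0.0;                          // no credit for negative work
  double per_kg = heat + w;
  if (per_kg < 0.0) per_kg = 0.0;
  return per_kg * mass;
}

// ---------------------------------------------------------------------------
// kinematics
// ---------------------------------------------------------------------------

// body-angle composition matrix S (bodies x dofs 2..8)
static const int SGN[NBODY][7] = {
  {1, 0, 0, 0, 0, 0, 0},   // trunk
  {1, 1, 0, 0, 0, 0, 0},   // thigh L
  {1, 1,-1, 0, 0, 0, 0},   // shank L
  {1, 1,-1, 1, 0, 0, 0},   // foot  L
  {1, 0, 0, 0, 1, 0, 0},   // thigh R
  {1, 0, 0, 0, 1,-1, 0},   // shank R
  {1, 0, 0, 0, 1,-1, 1}    // foot  R
};

struct Kin {
  double phi[NBODY], phid[NBODY];
  double cphi[NBODY], sphi[NBODY];
};

static void computeKin(const double* q, const double* qd, Kin& K) {
  for (int b = 0; b < NBODY; ++b) {
    double p = 0, pd = 0;
    for (int j = 0; j < 7; ++j) {
      if (SGN[b][j]) { p += SGN[b][j] * q[2 + j]; pd += SGN[b][j] * qd[2 + j]; }
    }
    K.phi[b] = p; K.phid[b] = pd;
    K.cphi[b] = std::cos(p); K.sphi[b] = std::sin(p);
  }
}

// chain of (body, local vector) terms from pelvis to a point on body b
struct PointRes {
  Vec2 p, v, a0;
  double J[2][NQ];
};

static void pointKin(const Model& M, const Kin& K, const double* q,
                     const double* qd, int b, Vec2 r, PointRes& out) {
  out.p.x = q[0]; out.p.y = q[1];
  out.v.x = qd[0]; out.v.y = qd[1];
  out.a0.x = 0; out.a0.y = 0;
  std::memset(out.J, 0, sizeof(out.J));
  out.J[0][0] = 1.0; out.J[1][1] = 1.0;
  int chain[3]; Vec2 vecs[3]; int n = 0;
  if (b == 0) { chain[n] = 0; vecs[n++] = r; }
  else {
    int side = (b <= 3) ? 0 : 1;
    int thigh = side ? 4 : 1, shank = side ? 5 : 2, foot = side ? 6 : 3;
    Vec2 dth = {0, -M.Lth}, dsh = {0, -M.Lsh};
    if (b == thigh) { chain[n] = thigh; vecs[n++] = r; }
    else if (b == shank) { chain[n] = thigh; vecs[n++] = dth;
                           chain[n] = shank; vecs[n++] = r; }
    else { chain[n] = thigh; vecs[n++] = dth;
           chain[n] = shank; vecs[n++] = dsh;
           chain[n] = foot;  vecs[n++] = r; }
  }
  for (int t = 0; t < n; ++t) {
    int k = chain[t];
    double wx = K.cphi[k] * vecs[t].x - K.sphi[k] * vecs[t].y;
    double wy = K.sphi[k] * vecs[t].x + K.cphi[k] * vecs[t].y;
    double cx = -wy, cy = wx; // z-hat cross w
    out.p.x += wx; out.p.y += wy;
    out.v.x += K.phid[k] * cx; out.v.y += K.phid[k] * cy;
    out.a0.x -= K.phid[k] * K.phid[k] * wx;
    out.a0.y -= K.phid[k] * K.phid[k] * wy;
    for (int j = 0; j < 7; ++j) {
      if (SGN[k][j]) {
        out.J[0][2 + j] += SGN[k][j] * cx;
        out.J[1][2 + j] += SGN[k][j] * cy;
      }
    }
  }
}

// solve M x = b on active dofs via Cholesky
static bool cholSolve(double Mm[NQ][NQ], double* b, const bool* active, double* x) {
  int idx[NQ], n = 0;
  for (int i = 0; i < NQ; ++i) { x[i] = 0.0; if (active[i]) idx[n++] = i; }
  double A[NQ][NQ], rhs[NQ];
  for (int i = 0; i < n; ++i) {
    rhs[i] = b[idx[i]];
    for (int j = 0; j < n; ++j) A[i][j] = Mm[idx[i]][idx[j]];
  }
  for (int i = 0; i < n; ++i) {           // in-place Cholesky
    for (int j = 0; j <= i; ++j) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= A[i][k] * A[j][k];
      if (i == j) {
        if (s <= 1e-12) return false;
        A[i][i] = std::sqrt(s);
      } else A[i][j] = s / A[j][j];
    }
  }
  for (int i = 0; i < n; ++i) {           // forward
    double s = rhs[i];
    for (int k = 0; k < i; ++k) s -= A[i][k] * rhs[k];
    rhs[i] = s / A[i][i];
  }
  for (int i = n - 1; i >= 0; --i) {      // backward
    double s = rhs[i];
    for (int k = i + 1; k < n; ++k) s -= A[k][i] * rhs[k];
    rhs[i] = s / A[i][i];
  }
  for (int i = 0; i < n; ++i) x[idx[i]] = rhs[i];
  return true;
}

// ---------------------------------------------------------------------------
// simulation engine
// ---------------------------------------------------------------------------

struct History {           // delayed-channel ring (grow-only) buffer
  std::vector<double> t;
  std::vector<double> ch;  // NCH per entry
  void push(double tt, const double* c) {
    t.push_back(tt);
    ch.insert(ch.end(), c, c + NCH);
  }
  double lookup(int channel, double tq) const {
    if (t.empty()) return 0.0;
    if (tq <= t.front()) return ch[channel];
    if (tq >= t.back()) return ch[(t.size() - 1) * NCH + channel];
    size_t lo = 0, hi = t.size() - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (t[mid] <= tq) lo = mid; else hi = mid;
    }
    double w = (tq - t[lo]) / (t[hi] - t[lo]);
    double a = ch[lo * NCH + channel], b = ch[hi * NCH + channel];
    return a + w * (b - a);
  }
};

struct DerivOut {          // auxiliary quantities from one dynamics evaluation
  double u[NM], Fn[NM], vmn[NM], fl[NM];
  double jointmom[6], ligt[6];
  Vec2 grf[2], headacc, com;
  double edot;
  double qdd[NQ];
};

struct Engine {
  Model M;
  Controller C;
  const double* par;       // 74 controller values
  bool muscles_on, contact_on;
  bool active[NQ];
  int phase[2];
  History hist;
  double u_hold[NM];       // excitations are part of the aux output

  // excitation law loop on explicit channel values
  void excitations(const double* ch, const int* ph, double* u) const {
    for (int m = 0; m < NM; ++m) u[m] = 0.0;
    for (size_t i = 0; i < C.laws.size(); ++i) {
      const Law& L = C.laws[i];
      if (!(L.phasemask & (1 << ph[L.leg]))) continue;
      double contrib = 0.0;
      switch (L.type) {
      case LAW_C:  contrib = par[L.p1]; break;
      case LAW_L:  contrib = std::max(0.0, par[L.p1] * (ch[L.source] - par[L.p2])); break;
      case LAW_V:  contrib = std::max(0.0, par[L.p1] * ch[NM + L.source]); break;
      case LAW_FP: contrib =  par[L.p1] * ch[2 * NM + L.source]; break;
      case LAW_FM: contrib = -par[L.p1] * ch[2 * NM + L.source]; break;
      case LAW_PD: contrib = par[L.p1] * (ch[54] - par[L.p3]) + par[L.p2] * ch[55]; break;
      }
      u[L.target] += contrib;
    }
    for (int m = 0; m < NM; ++m) {
      if (u[m] > 1.0) u[m] = 1.0;
      if (u[m] < C.u_floor) u[m] = C.u_floor;
    }
  }

  void delayedChannels(double t, double* ch) const {
    // one value per channel is law-delay specific; build per-law inside deriv
    // instead (this helper is used only for the t=0 fill)
    for (int c = 0; c < NCH; ++c) ch[c] = hist.lookup(c, t);
  }

  // current (undelayed) channel values from state
  void channelsFromState(const double* y, double* ch) const {
    Kin K; computeKin(y, y + NQ, K);
    for (int m = 0; m < NM; ++m) {
      const Muscle& mu = M.mus[m];
      double L = mu.L0, Ld = 0.0;
      for (int s = 0; s < 2; ++s) {
        if (mu.j[s] < 0) continue;
        double th = y[mu.j[s]], thd = y[NQ + mu.j[s]];
        L += mu.c1[s] * th + mu.c2[s] * th * th;
        Ld += (mu.c1[s] + 2.0 * mu.c2[s] * th) * thd;
      }
      double lmn = y[36 + m];
      double lt = L - lmn * mu.lopt;
      double strain = (lt - mu.lslack) / mu.lslack;
      double Fn = ten_fl(strain, mu.eref, M.kt);
      double fl = act_fl(lmn, M.w_act);
      double fp = mu.pscale * pas_fl(lmn, M.kpe, M.e0pe);
      double a = y[18 + m];
      double fvreq = (Fn - fp) / std::max(a * fl, 1e-3);
      double vbar = fv_inverse(fvreq, M.fvK, M.fvN);
      ch[m] = lmn;
      ch[NM + m] = vbar * mu.vmax;
      ch[2 * NM + m] = Fn;
      (void) Ld;
    }
    ch[54] = y[2];
    ch[55] = y[NQ + 2];
  }

  // full dynamics evaluation
  bool deriv(double t, const double* y, double* dy, DerivOut& out) const {
    const double* q = y; const double* qd = y + NQ;
    Kin K; computeKin(q, qd, K);

    double tau[NQ] = {0};
    for (int j = 0; j < 6; ++j) { out.jointmom[j] = 0; out.ligt[j] = 0; }
    out.edot = 0.0;

    // --- muscles -----------------------------------------------------------
    double dch[NCH]; // scratch for per-law delayed values (filled lazily)
    if (muscles_on) {
      // excitations from delayed sensors: each law has its own delay, so the
      // lookup happens per law; assemble into out.u
      for (int m = 0; m < NM; ++m) out.u[m] = 0.0;
      for (size_t i = 0; i < C.laws.size(); ++i) {
        const Law& L = C.laws[i];
        if (!(L.phasemask & (1 << phase[L.leg]))) continue;
        double td = t - L.delay, contrib = 0.0;
        switch (L.type) {
        case LAW_C:  contrib = par[L.p1]; break;
        case LAW_L:  contrib = std::max(0.0, par[L.p1] *
                        (hist.lookup(L.source, td) - par[L.p2])); break;
        case LAW_V:  contrib = std::max(0.0, par[L.p1] *
                        hist.lookup(NM + L.source, td)); break;
        case LAW_FP: contrib =  par[L.p1] * hist.lookup(2 * NM + L.source, td); break;
        case LAW_FM: contrib = -par[L.p1] * hist.lookup(2 * NM + L.source, td); break;
        case LAW_PD: contrib = par[L.p1] * (hist.lookup(54, td) - par[L.p3]) +
                               par[L.p2] * hist.lookup(55, td); break;
        }
        out.u[L.target] += contrib;
      }
      for (int m = 0; m < NM; ++m) {
        if (out.u[m] > 1.0) out.u[m] = 1.0;
        if (out.u[m] < C.u_floor) out.u[m] = C.u_floor;
      }
    } else {
      for (int m = 0; m < NM; ++m) out.u[m] = 0.0;
    }
    (void) dch;

    for (int m = 0; m < NM; ++m) {
      const Muscle& mu = M.mus[m];
      double a = y[18 + m], lmn = y[36 + m], u = out.u[m];
      double tauact = (u > a) ? mu.tau_a : mu.tau_d;
      dy[18 + m] = muscles_on ? (u - a) / tauact : -a / mu.tau_d;
      if (!muscles_on) { out.Fn[m] = 0; out.vmn[m] = 0; out.fl[m] = act_fl(lmn, M.w_act);
                         dy[36 + m] = 0; continue; }
      double L = mu.L0;
      double r[2] = {0, 0};
      for (int s = 0; s < 2; ++s) {
        if (mu.j[s] < 0) continue;
        double th = q[mu.j[s]];
        L += mu.c1[s] * th + mu.c2[s] * th * th;
        r[s] = -(mu.c1[s] + 2.0 * mu.c2[s] * th);  // tendon-excursion identity
      }
      double lt = L - lmn * mu.lopt;
      double strain = (lt - mu.lslack) / mu.lslack;
      double Fn = ten_fl(strain, mu.eref, M.kt);
      double fl = act_fl(lmn, M.w_act);
      double fp = mu.pscale * pas_fl(lmn, M.kpe, M.e0pe);
      double fvreq = (Fn - fp) / std::max(a * fl, 1e-3);
      double vbar = fv_inverse(fvreq, M.fvK, M.fvN);
      double v = vbar * mu.vmax;                  // lopt/s
      dy[36 + m] = v;
      double F = Fn * mu.fmax;
      out.Fn[m] = Fn; out.vmn[m] = v; out.fl[m] = fl;
      for (int s = 0; s < 2; ++s) {
        if (mu.j[s] < 0) continue;
        tau[mu.j[s]] += r[s] * F;
        out.jointmom[mu.j[s] - 3] += r[s] * F;
      }
      double fce_active = mu.fmax * (a * fl * fv_curve(vbar, M.fvK, M.fvN));
      out.edot += metab_rate(a, u, lmn, v, mu, fl, fce_active, M.sigma, M.rho);
    }

    // --- ligaments ---------------------------------------------------------
    for (size_t i = 0; i < M.lig.size(); ++i) {
      const Lig& l = M.lig[i];
      double th = q[l.dof], tq = 0.0;
      if (th > l.hi)      tq = -l.K * (std::exp((th - l.hi) / l.w) - 1.0);
      else if (th < l.lo) tq =  l.K * (std::exp((l.lo - th) / l.w) - 1.0);
      tau[l.dof] += tq;
      out.ligt[l.dof - 3] = tq;
    }

    // --- rigid-body terms --------------------------------------------------
    double Mm[NQ][NQ] = {{0}}, bias[NQ] = {0}, Qg[NQ] = {0};
    double comx = 0, comy = 0;
    for (int b = 0; b < NBODY; ++b) {
      PointRes P; pointKin(M, K, q, qd, b, M.rcom[b], P);
      comx += M.m[b] * P.p.x; comy += M.m[b] * P.p.y;
      for (int i = 0; i < NQ; ++i) {
        bias[i] += M.m[b] * (P.J[0][i] * P.a0.x + P.J[1][i] * P.a0.y);
        Qg[i]   -= M.m[b] * M.grav * P.J[1][i];
        for (int j = i; j < NQ; ++j)
          Mm[i][j] += M.m[b] * (P.J[0][i] * P.J[0][j] + P.J[1][i] * P.J[1][j]);
      }
      for (int i = 2; i < NQ; ++i) {
        if (!SGN[b][i - 2]) continue;
        for (int j = i; j < NQ; ++j)
          if (SGN[b][j - 2]) Mm[i][j] += M.I[b] * SGN[b][i - 2] * SGN[b][j - 2];
      }
    }
    for (int i = 0; i < NQ; ++i)
      for (int j = 0; j < i; ++j) Mm[i][j] = Mm[j][i];
    out.com.x = comx / M.total_mass; out.com.y = comy / M.total_mass;

    // --- contact -----------------------------------------------------------
    out.grf[0].x = out.grf[0].y = out.grf[1].x = out.grf[1].y = 0.0;
    double Qc[NQ] = {0};
    if (contact_on) {
      for (size_t i = 0; i < M.sph.size(); ++i) {
        const Sphere& s = M.sph[i];
        int body = s.leg == 0 ? 3 : 6;
        PointRes P; pointKin(M, K, q, qd, body, Vec2{s.x, s.y}, P);
        double depth = s.R - P.p.y;
        if (depth <= 0.0) continue;
        double ddot = -P.v.y;
        double fnorm = (4.0 / 3.0) * s.E * std::sqrt(s.R) * std::pow(depth, 1.5) *
                       (1.0 + s.c * ddot);
        if (fnorm < 0.0) fnorm = 0.0;
        double ftan = -s.mu * fnorm * std::tanh(P.v.x / s.vtrans);
        out.grf[s.leg].x += ftan; out.grf[s.leg].y += fnorm;
        for (int j = 0; j < NQ; ++j)
          Qc[j] += P.J[0][j] * ftan + P.J[1][j] * fnorm;
      }
    }

    // --- solve -------------------------------------------------------------
    double rhs[NQ];
    for (int i = 0; i < NQ; ++i) rhs[i] = tau[i] + Qg[i] + Qc[i] - bias[i];
    if (!cholSolve(Mm, rhs, active, out.qdd)) return false;
    for (int i = 0; i < NQ; ++i) {
      dy[i] = active[i] ? qd[i] : 0.0;   // locked dofs hold their position
      dy[NQ + i] = out.qdd[i];
    }

    // head-point acceleration
    PointRes H; pointKin(M, K, q, qd, 0, M.head, H);
    out.headacc.x = H.a0.x; out.headacc.y = H.a0.y;
    for (int j = 0; j < NQ; ++j) {
      out.headacc.x += H.J[0][j] * out.qdd[j];
      out.headacc.y += H.J[1][j] * out.qdd[j];
    }
    return true;
  }

  // state-machine transitions; at most one per leg per call
  void updatePhases(const double* y, const Vec2* grf) {
    Kin K; computeKin(y, y + NQ, K);
    double dist[2], grfmag[2];
    for (int leg = 0; leg < 2; ++leg) {
      // heel-sphere center to pelvis origin, signed along +x
      const Sphere& heel = M.sph[leg == 0 ? 0 : 3];
      PointRes P; pointKin(M, K, y, y + NQ, leg == 0 ? 3 : 6,
                           Vec2{heel.x, heel.y}, P);
      dist[leg] = P.p.x - y[0];
      grfmag[leg] = std::sqrt(grf[leg].x * grf[leg].x + grf[leg].y * grf[leg].y);
    }
    int newphase[2] = {phase[0], phase[1]};
    for (int leg = 0; leg < 2; ++leg) {
      switch (phase[leg]) {
      case PH_ES: if (dist[leg] < par[C.thr_es_ms]) newphase[leg] = PH_MS; break;
      case PH_PS: if (grfmag[leg] < par[C.thr_ps_s]) newphase[leg] = PH_S; break;
      case PH_S:  if (dist[leg] > par[C.thr_s_lp]) newphase[leg] = PH_LP; break;
      case PH_LP: if (grfmag[leg] > par[C.thr_lp_es]) newphase[leg] = PH_ES; break;
      default: break;
      }
    }
    // MS -> PS when the contralateral leg enters ES (no threshold)
    for (int leg = 0; leg < 2; ++leg) {
      int other = 1 - leg;
      if (phase[leg] == PH_MS && newphase[other] == PH_ES && phase[other] != PH_ES)
        newphase[leg] = PH_PS;
    }
    phase[0] = newphase[0]; phase[1] = newphase[1];
  }
};

// fiber/tendon equilibrium at given activation (isometric): damped Newton
// with a bisection fallback on the bracket [0.2, 2.2] l_opt
static bool equilibrate1(const Model& M, const Muscle& mu, double Lmtu,
                         double a, double& lmn_out, double& resid_out,
                         int maxit = 100, double tol = 1e-6) {
  const double lo = 0.2, hi = 2.2;
  if (Lmtu < mu.lslack * 0.5 + lo * mu.lopt) return false; // infeasible geometry
  auto resid = [&](double l) {
    double strain = (Lmtu - l * mu.lopt - mu.lslack) / mu.lslack;
    double f_m = a * act_fl(l, M.w_act) + mu.pscale * pas_fl(l, M.kpe, M.e0pe);
    return f_m - ten_fl(strain, mu.eref, M.kt);
  };
  double flo = resid(lo), fhi = resid(hi);
  double blo = lo, bhi = hi;
  bool bracket = (flo <= 0.0 && fhi >= 0.0);
  double lmn = std::min(std::max((Lmtu - mu.lslack) / mu.lopt, lo + 1e-3), hi - 1e-3);
  double f = resid(lmn);
  for (int it = 0; it < maxit; ++it) {
    if (std::fabs(f) < tol) { lmn_out = lmn; resid_out = f; return true; }
    if (bracket) {  // maintain the sign-change bracket
      if (f > 0.0) bhi = lmn; else blo = lmn;
    }
    double h = 1e-7;
    double df = (resid(lmn + h) - f) / h;
    double cand = (std::fabs(df) > 1e-14) ? lmn - f / df : NA_REAL;
    if (!std::isfinite(cand) || cand <= blo || cand >= bhi) {
      if (!bracket) break;               // Newton left the bracket; bisect
      cand = 0.5 * (blo + bhi);
    }
    double fc = resid(cand);
    if (!bracket && std::fabs(fc) >= std::fabs(f)) {
      // no sign change available and no progress: damp
      double damp = 0.5;
      for (int k = 0; k < 25 && std::fabs(fc) >= std::fabs(f); ++k) {
        cand = lmn + damp * (cand - lmn);
        fc = resid(cand);
        damp *= 0.5;
      }
      if (std::fabs(fc) >= std::fabs(f)) break;
    }
    lmn = cand; f = fc;
  }
  // last resort: pure bisection on the bracket
  if (bracket) {
    for (int it = 0; it < 200; ++it) {
      double mid = 0.5 * (blo + bhi);
      double fm = resid(mid);
      if (std::fabs(fm) < tol) { lmn_out = mid; resid_out = fm; return true; }
      if (fm > 0.0) bhi = mid; else blo = mid;
    }
    lmn = 0.5 * (blo + bhi);
    f = resid(lmn);
  }
  lmn_out = lmn; resid_out = f;
  return std::fabs(f) < tol;
}

// static vertical GRF at configuration (zero velocity)
static double staticVGRF(const Engine& E, const double* q) {
  double qd[NQ] = {0};
  Kin K; computeKin(q, qd, K);
  double total = 0.0;
  for (size_t i = 0; i < E.M.sph.size(); ++i) {
    const Sphere& s = E.M.sph[i];
    int body = s.leg == 0 ? 3 : 6;
    PointRes P; pointKin(E.M, K, q, qd, body, Vec2{s.x, s.y}, P);
    double depth = s.R - P.p.y;
    if (depth <= 0.0) continue;
    total += (4.0 / 3.0) * s.E * std::sqrt(s.R) * std::pow(depth, 1.5);
  }
  return total;
}

// Build the full initial state from the 16 free parameters.
// init16: tilt, hipL, kneeL, ankleL, hipR, kneeR, ankleR, then 9 velocities.
static int buildInitialState(Engine& E, const double* init16, double* y,
                             double& pelvis_y, double& grf0) {
  double q[NQ] = {0};
  q[0] = 0.0;
  q[2] = init16[0];
  for (int i = 0; i < 6; ++i) q[3 + i] = init16[1 + i];
  double target = 0.5 * E.M.total_mass * E.M.grav;
  // bracket: y_hi = all spheres airborne; descend until force exceeds target
  double yhi = -1e9;
  {
    double q0[NQ]; std::memcpy(q0, q, sizeof(q0)); q0[1] = 0.0;
    Kin K; double qd[NQ] = {0}; computeKin(q0, qd, K);
    for (size_t i = 0; i < E.M.sph.size(); ++i) {
      const Sphere& s = E.M.sph[i];
      int body = s.leg == 0 ? 3 : 6;
      PointRes P; pointKin(E.M, K, q0, qd, body, Vec2{s.x, s.y}, P);
      double need = s.R - P.p.y;     // extra height so this sphere just touches
      if (need > yhi) yhi = need;
    }
  }
  double ylo = yhi - 0.4;
  {
    double qq[NQ]; std::memcpy(qq, q, sizeof(qq));
    qq[1] = ylo;
    int guard = 0;
    while (staticVGRF(E, qq) < target && guard++ < 10) { ylo -= 0.2; qq[1] = ylo; }
    if (staticVGRF(E, qq) < target) return 1;  // cannot reach half body weight
  }
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (ylo + yhi);
    double qq[NQ]; std::memcpy(qq, q, sizeof(qq)); qq[1] = mid;
    if (staticVGRF(E, qq) > target) ylo = mid; else yhi = mid;
  }
  q[1] = 0.5 * (ylo + yhi);
  pelvis_y = q[1];
  {
    double qq[NQ]; std::memcpy(qq, q, sizeof(qq));
    grf0 = staticVGRF(E, qq);
  }
  std::memcpy(y, q, NQ * sizeof(double));
  for (int i = 0; i < NQ; ++i) y[NQ + i] = init16[7 + i];
  for (int m = 0; m < NM; ++m) { y[18 + m] = 0.05; y[36 + m] = 1.0; } // provisional

  // muscle states: equilibrate at provisional activation, compute the
  // controller's initial excitations, then re-equilibrate at the resulting
  // activations (paper: activation from the initial excitations)
  double qd0[NQ]; std::memcpy(qd0, y + NQ, sizeof(qd0));
  for (int pass = 0; pass < 2; ++pass) {
    for (int m = 0; m < NM; ++m) {
      const Muscle& mu = E.M.mus[m];
      double L = mu.L0;
      for (int s = 0; s < 2; ++s) {
        if (mu.j[s] < 0) continue;
        double th = q[mu.j[s]];
        L += mu.c1[s] * th + mu.c2[s] * th * th;
      }
      double a = (pass == 0) ? 0.05 : y[18 + m];
      double lmn, res;
      if (!equilibrate1(E.M, mu, L, a, lmn, res)) return 2;
      y[36 + m] = lmn;
    }
    if (pass == 0) {
      double ch[NCH]; E.channelsFromState(y, ch);
      double u0[NM];
      E.excitations(ch, E.phase, u0);
      for (int m = 0; m < NM; ++m)
        y[18 + m] = std::min(std::max(u0[m], E.C.u_floor), 1.0);
    }
  }
  return 0;
}

// Dormand-Prince 5(4) coefficients
static const double DP_C[7] = {0, 1.0/5, 3.0/10, 4.0/5, 8.0/9, 1.0, 1.0};
static const double DP_A[7][6] = {
  {0,0,0,0,0,0},
  {1.0/5,0,0,0,0,0},
  {3.0/40, 9.0/40,0,0,0,0},
  {44.0/45, -56.0/15, 32.0/9,0,0,0},
  {19372.0/6561, -25360.0/2187, 64448.0/6561, -212.0/729,0,0},
  {9017.0/3168, -355.0/33, 46732.0/5247, 49.0/176, -5103.0/18656,0},
  {35.0/384, 0, 500.0/1113, 125.0/192, -2187.0/6784, 11.0/84}
};
static const double DP_B5[7] = {35.0/384, 0, 500.0/1113, 125.0/192,
                                -2187.0/6784, 11.0/84, 0};
static const double DP_B4[7] = {5179.0/57600, 0, 7571.0/16695, 393.0/640,
                                -92097.0/339200, 187.0/2100, 1.0/40};

// [[Rcpp::export(name = ".gait_core_rollout")]]
List gait_core_rollout(List model, List controller, NumericVector params,
                       NumericVector init, List opts) {
  Engine E;
  E.M = parseModel(model);
  E.C = parseController(controller);
  if (params.size() != 74) stop("controller parameter vector must have length 74");
  E.par = REAL(params);
  double t_des   = as<double>(opts["t_des"]);
  double rtol    = as<double>(opts["rtol"]);
  double atol    = as<double>(opts["atol"]);
  double h_max   = as<double>(opts["h_max"]);
  E.muscles_on   = as<bool>(opts["muscles_on"]);
  E.contact_on   = as<bool>(opts["contact_on"]);
  IntegerVector locked = opts["locked_dofs"];  // 1-based dof indices
  for (int i = 0; i < NQ; ++i) E.active[i] = true;
  for (int i = 0; i < locked.size(); ++i) E.active[locked[i] - 1] = false;
  E.phase[0] = E.C.init_phase[0]; E.phase[1] = E.C.init_phase[1];

  double y[NY];
  double pelvis_y = NA_REAL, grf0 = NA_REAL;
  if (init.size() == 16) {
    int rc = buildInitialState(E, REAL(init), y, pelvis_y, grf0);
    if (rc == 1) stop("initialization error: static GRF of half body weight is unreachable for this pose");
    if (rc == 2) stop("initialization error: muscle fiber/tendon equilibrium infeasible at the initial pose");
  } else if (init.size() == NY) {
    std::memcpy(y, REAL(init), NY * sizeof(double));
  } else stop("init must have length 16 (free parameters) or 54 (full state)");

  // initial channel fill and first record
  double ch0[NCH]; E.channelsFromState(y, ch0);
  E.hist.push(0.0, ch0);

  std::vector<double> rec;     // row-major records
  const int NREC = 1 + NY + NM + NM + 6 + 6 + 4 + 2 + 1 + 2 + 2; // 114
  DerivOut O;
  double dy[NY];
  bool ok0 = E.deriv(0.0, y, dy, O);
  if (!ok0) stop("simulation error: singular mass matrix at the initial state");
  double com0 = O.com.y;

  auto record = [&](double t, const double* yy, const DerivOut& oo) {
    rec.push_back(t);
    for (int i = 0; i < NY; ++i) rec.push_back(yy[i]);
    for (int i = 0; i < NM; ++i) rec.push_back(oo.u[i]);
    for (int i = 0; i < NM; ++i) rec.push_back(oo.Fn[i]);
    for (int i = 0; i < 6; ++i) rec.push_back(oo.jointmom[i]);
    for (int i = 0; i < 6; ++i) rec.push_back(oo.ligt[i]);
    rec.push_back(oo.grf[0].x); rec.push_back(oo.grf[0].y);
    rec.push_back(oo.grf[1].x); rec.push_back(oo.grf[1].y);
    rec.push_back(oo.headacc.x); rec.push_back(oo.headacc.y);
    rec.push_back(oo.edot);
    rec.push_back(oo.com.x); rec.push_back(oo.com.y);
    rec.push_back((double) E.phase[0]); rec.push_back((double) E.phase[1]);
  };
  record(0.0, y, O);

  double t = 0.0, h = 1e-3;
  const double h_min = 1e-8;
  std::string status = "completed";
  double t_fall = NA_REAL;
  double k[7][NY], ytmp[NY], y5[NY], y4[NY];
  DerivOut Otmp;
  int max_steps = 4000000;
  int nsteps = 0;

  while (t < t_des && nsteps++ < max_steps) {
    if (h > h_max) h = h_max;
    if (t + h > t_des) h = t_des - t;
    bool stage_ok = true;
    std::memcpy(k[0], dy, sizeof(dy)); // FSAL-style reuse of last deriv at t
    for (int s = 1; s < 7 && stage_ok; ++s) {
      for (int i = 0; i < NY; ++i) {
        double acc = 0;
        for (int j = 0; j < s; ++j) acc += DP_A[s][j] * k[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      stage_ok = E.deriv(t + DP_C[s] * h, ytmp, k[s], Otmp);
    }
    if (!stage_ok) { h *= 0.5; if (h < h_min) { status = "integration_failure"; break; } continue; }
    double errn = 0.0;
    for (int i = 0; i < NY; ++i) {
      double acc5 = 0, acc4 = 0;
      for (int j = 0; j < 7; ++j) { acc5 += DP_B5[j] * k[j][i]; acc4 += DP_B4[j] * k[j][i]; }
      y5[i] = y[i] + h * acc5;
      y4[i] = y[i] + h * acc4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = (y5[i] - y4[i]) / sc;
      errn += e * e;
    }
    errn = std::sqrt(errn / NY);
    if (!std::isfinite(errn)) { h *= 0.5; if (h < h_min) { status = "integration_failure"; break; } continue; }
    if (errn > 1.0) {
      h *= std::max(0.2, 0.9 * std::pow(errn, -0.2));
      if (h < h_min) { status = "integration_failure"; break; }
      continue;
    }
    // accept
    t += h;
    std::memcpy(y, y5, sizeof(y5));
    // state safety projection (wild candidates during optimization)
    for (int m = 0; m < NM; ++m) {
      if (y[18 + m] < 0.0) y[18 + m] = 0.0;
      if (y[18 + m] > 1.0) y[18 + m] = 1.0;
      if (y[36 + m] < 0.2) y[36 + m] = 0.2;
      if (y[36 + m] > 2.2) y[36 + m] = 2.2;
    }
    double fac = (errn < 1e-12) ? 5.0 : std::min(5.0, std::max(0.2, 0.9 * std::pow(errn, -0.2)));
    h *= fac;
    // evaluate at the accepted state: channels, records, sensors, fall check
    if (!E.deriv(t, y, dy, O)) { status = "integration_failure"; break; }
    double chn[NCH]; E.channelsFromState(y, chn);
    E.hist.push(t, chn);
    E.updatePhases(y, O.grf);
    record(t, y, O);
    if (O.com.y < E.M.fall_frac * com0) { status = "fell"; t_fall = t; break; }
    if (!std::isfinite(O.com.y) || std::fabs(y[0]) > 1e4) { status = "integration_failure"; break; }
  }
  if (nsteps >= max_steps) status = "integration_failure";

  int nrow = (int) (rec.size() / NREC);
  NumericMatrix out(nrow, NREC);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < NREC; ++j) out(i, j) = rec[(size_t) i * NREC + j];
  return List::create(
    _["records"] = out,
    _["status"] = status,
    _["t_end"] = t,
    _["t_fall"] = t_fall,
    _["pelvis_y"] = pelvis_y,
    _["grf0"] = grf0,
    _["com0"] = com0);
}

// [[Rcpp::export(name = ".gait_core_initialize")]]
List gait_core_initialize(List model, List controller, NumericVector params,
                          NumericVector init16) {
  Engine E;
  E.M = parseModel(model);
  E.C = parseController(controller);
  E.par = REAL(params);
  E.muscles_on = true; E.contact_on = true;
  for (int i = 0; i < NQ; ++i) E.active[i] = true;
  E.phase[0] = E.C.init_phase[0]; E.phase[1] = E.C.init_phase[1];
  if (init16.size() != 16) stop("expected 16 initial-state free parameters, got %d", (int) init16.size());
  double y[NY], pelvis_y, grf0;
  int rc = buildInitialState(E, REAL(init16), y, pelvis_y, grf0);
  if (rc == 1) stop("initialization error: static GRF of half body weight is unreachable for this pose");
  if (rc == 2) stop("initialization error: muscle fiber/tendon equilibrium infeasible at the initial pose");
  return List::create(_["state"] = NumericVector(y, y + NY),
                      _["pelvis_y"] = pelvis_y,
                      _["static_vgrf"] = grf0);
}

// [[Rcpp::export(name = ".gait_core_geometry")]]
List gait_core_geometry(List model, NumericVector q, NumericVector qdot) {
  Model M = parseModel(model);
  NumericVector len(NM), vel(NM);
  NumericMatrix ma(NM, NQ);
  for (int m = 0; m < NM; ++m) {
    const Muscle& mu = M.mus[m];
    double L = mu.L0, Ld = 0.0;
    for (int s = 0; s < 2; ++s) {
      if (mu.j[s] < 0) continue;
      double th = q[mu.j[s]], thd = qdot[mu.j[s]];
      L += mu.c1[s] * th + mu.c2[s] * th * th;
      Ld += (mu.c1[s] + 2.0 * mu.c2[s] * th) * thd;
      ma(m, mu.j[s]) = -(mu.c1[s] + 2.0 * mu.c2[s] * th);
    }
    len[m] = L; vel[m] = Ld;
  }
  return List::create(_["length"] = len, _["velocity"] = vel,
                      _["moment_arm"] = ma);
}

// [[Rcpp::export(name = ".gait_core_mass_matrix")]]
NumericMatrix gait_core_mass_matrix(List model, NumericVector q) {
  Model M = parseModel(model);
  double qd[NQ] = {0};
  Kin K; computeKin(REAL(q), qd, K);
  double Mm[NQ][NQ] = {{0}};
  for (int b = 0; b < NBODY; ++b) {
    PointRes P; pointKin(M, K, REAL(q), qd, b, M.rcom[b], P);
    for (int i = 0; i < NQ; ++i)
      for (int j = i; j < NQ; ++j)
        Mm[i][j] += M.m[b] * (P.J[0][i] * P.J[0][j] + P.J[1][i] * P.J[1][j]);
    for (int i = 2; i < NQ; ++i) {
      if (!SGN[b][i - 2]) continue;
      for (int j = i; j < NQ; ++j)
        if (SGN[b][j - 2]) Mm[i][j] += M.I[b] * SGN[b][i - 2] * SGN[b][j - 2];
    }
  }
  NumericMatrix out(NQ, NQ);
  for (int i = 0; i < NQ; ++i)
    for (int j = 0; j < NQ; ++j) out(i, j) = (j >= i) ? Mm[i][j] : Mm[j][i];
  return out;
}

// [[Rcpp::export(name = ".gait_core_body_points")]]
List gait_core_body_points(List model, NumericVector q, NumericVector qdot) {
  Model M = parseModel(model);
  Kin K; computeKin(REAL(q), REAL(qdot), K);
  NumericMatrix pos(NBODY, 2), vel(NBODY, 2);
  double comx = 0, comy = 0;
  for (int b = 0; b < NBODY; ++b) {
    PointRes P; pointKin(M, K, REAL(q), REAL(qdot), b, M.rcom[b], P);
    pos(b,0) = P.p.x; pos(b,1) = P.p.y;
    vel(b,0) = P.v.x; vel(b,1) = P.v.y;
    comx += M.m[b] * P.p.x; comy += M.m[b] * P.p.y;
  }
  // sphere world positions
  NumericMatrix sp(M.sph.size(), 4);
  for (size_t i = 0; i < M.sph.size(); ++i) {
    const Sphere& s = M.sph[i];
    PointRes P; pointKin(M, K, REAL(q), REAL(qdot), s.leg == 0 ? 3 : 6,
                         Vec2{s.x, s.y}, P);
    sp(i,0) = P.p.x; sp(i,1) = P.p.y; sp(i,2) = P.v.x; sp(i,3) = P.v.y;
  }
  // head point
  PointRes H; pointKin(M, K, REAL(q), REAL(qdot), 0, M.head, H);
  return List::create(_["com"] = NumericVector::create(comx / M.total_mass,
                                                       comy / M.total_mass),
                      _["body_pos"] = pos, _["body_vel"] = vel,
                      _["spheres"] = sp,
                      _["head"] = NumericVector::create(H.p.x, H.p.y));
}

// [[Rcpp::export(name = ".gait_core_equilibrate")]]
List gait_core_equilibrate(List model, int muscle, double mtu_length,
                           double activation, double tol) {
  Model M = parseModel(model);
  if (muscle < 1 || muscle > (int) M.mus.size()) stop("muscle index out of range");
  const Muscle& mu = M.mus[muscle - 1];
  double lmn, res;
  bool ok = equilibrate1(M, mu, mtu_length, activation, lmn, res, 100, tol);
  return List::create(_["norm_fiber_length"] = lmn, _["residual"] = res,
                      _["converged"] = ok);
}

// [[Rcpp::export(name = ".gait_core_excitations")]]
NumericVector gait_core_excitations(List controller, NumericVector params,
                                    NumericVector channels, IntegerVector phases) {
  Controller C = parseController(controller);
  if (channels.size() != NCH) stop("expected %d channel values", NCH);
  Engine E; E.C = C; E.par = REAL(params);
  int ph[2] = {phases[0], phases[1]};
  double u[NM];
  E.excitations(REAL(channels), ph, u);
  return NumericVector(u, u + NM);
}

// [[Rcpp::export(name = ".gait_core_metabolic")]]
List gait_core_metabolic(double activation, double excitation,
                         double norm_fiber_length, double norm_fiber_velocity,
                         double fmax, double lopt, double vmax, double ftfrac,
                         double w_act, double sigma, double rho) {
  Muscle mu; mu.fmax = fmax; mu.lopt = lopt; mu.vmax = vmax; mu.ftfrac = ftfrac;
  double fl = act_fl(norm_fiber_length, w_act);
  // CE force consistent with the curves at this state (isometric fv handled
  // by caller via norm_fiber_velocity)
  double vbar = norm_fiber_velocity / vmax;
  double fce = fmax * activation * fl * fv_curve(vbar, 0.25, 1.5);
  double rate = metab_rate(activation, excitation, norm_fiber_length,
                           norm_fiber_velocity, mu, fl, fce, sigma, rho);
  return List::create(_["rate"] = rate,
                      _["muscle_mass"] = fmax / sigma * rho * lopt,
                      _["fce"] = fce);
}

// ---- curve primitives (vectorized) ----------------------------------------

// [[Rcpp::export(name = ".hill_active_fl")]]
NumericVector hill_active_fl(NumericVector lmn, double width) {
  NumericVector out(lmn.size());
  for (int i = 0; i < lmn.size(); ++i) out[i] = act_fl(lmn[i], width);
  return out;
}

// [[Rcpp::export(name = ".hill_passive_fl")]]
NumericVector hill_passive_fl(NumericVector lmn, double kpe, double e0) {
  NumericVector out(lmn.size());
  for (int i = 0; i < lmn.size(); ++i) out[i] = pas_fl(lmn[i], kpe, e0);
  return out;
}

// [[Rcpp::export(name = ".hill_fv")]]
NumericVector hill_fv(NumericVector v_lopt_s, double vmax, double K, double N) {
  NumericVector out(v_lopt_s.size());
  for (int i = 0; i < v_lopt_s.size(); ++i)
    out[i] = fv_curve(v_lopt_s[i] / vmax, K, N);
  return out;
}

// [[Rcpp::export(name = ".hill_fv_inverse")]]
NumericVector hill_fv_inverse(NumericVector fv, double vmax, double K, double N) {
  NumericVector out(fv.size());
  for (int i = 0; i < fv.size(); ++i) out[i] = fv_inverse(fv[i], K, N) * vmax;
  return out;
}

// [[Rcpp::export(name = ".tendon_force_norm")]]
NumericVector tendon_force_norm(NumericVector strain, double eref, double kt) {
  NumericVector out(strain.size());
  for (int i = 0; i < strain.size(); ++i) out[i] = ten_fl(strain[i], eref, kt);
  return out;
}

// [[Rcpp::export(name = ".contact_force_cpp")]]
NumericVector contact_force_cpp(double depth, double depth_rate,
                                double tangential_velocity, double radius,
                                double modulus, double dissipation,
                                double mu_dynamic, double transition_velocity) {
  if (depth <= 0.0) return NumericVector::create(0.0, 0.0);
  double fn = (4.0 / 3.0) * modulus * std::sqrt(radius) * std::pow(depth, 1.5) *
              (1.0 + dissipation * depth_rate);
  if (fn < 0.0) fn = 0.0;
  double ft = -mu_dynamic * fn * std::tanh(tangential_velocity / transition_velocity);
  return NumericVector::create(ft, fn);
}

// [[Rcpp::export(name = ".ligament_torque_cpp")]]
double ligament_torque_cpp(double angle, double lo, double hi, double K, double w) {
  if (angle > hi) return -K * (std::exp((angle - hi) / w) - 1.0);
  if (angle < lo) return  K * (std::exp((lo - angle) / w) - 1.0);
  return 0.0;
}
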