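// Compiled core: pair potentials, NVT propagation, alchemical trajectories
// and the hybrid MD/MC sampler loop.  All randomness comes from R's RNG so
// that set.seed() makes whole runs reproducible and the MC-MD / MDAS draw
// streams stay aligned (2 uniforms for pair selection, thermostat noise
// during MD, 1 uniform per acceptance decision).
//
// Force-evaluation bookkeeping: one evaluation per MD step (the end-of-step
// force computation).  Lambda increments use tagged-pair partial terms
// evaluated alongside the neighbouring plateau force calls and therefore
// cost one bookkept evaluation only when M == 0 (no plateau MD).  The
// initial force computation of a run is bookkept as the closing evaluation
// of the preceding run.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct Elec {
  bool on = false;
  double pref = 0.0;   // coulomb_prefactor / dielectric_screening
  double krf = 0.0, crf = 0.0, rc2 = 0.0;
};

struct FieldSpec {
  bool on = false;
  double k = 0.0;                 // stiffness when not lambda-coupled
  std::vector<double> center;
};

struct Alch {
  int kind = 0;                   // 0 none, 1 head-bead identity swap, 2 field stiffness ramp
  int h1 = -1, h2 = -1;           // tagged head particle indices (0-based)
  int t1 = 0, t2 = 0;             // lambda = 0 bead types of h1, h2
  double q1 = 0.0, q2 = 0.0;      // lambda = 0 charges
  bool softcore = false;
  double delta = 0.0;             // soft-core delta (reduced length^2)
  double k0 = 0.0, k1 = 0.0;      // field stiffness endpoints (kind 2)
};

struct Thermo {
  int scheme = 0;                 // 0 none, 1 langevin, 2 velocity rescaling
  double kT = 1.0, gamma = 1.0, tau = 1.0;
};

struct Frame {
  std::vector<double> x, q;
  std::vector<int> type;
  double nev;
  double step;
};

static Thermo parse_thermo(List th) {
  Thermo t;
  t.scheme = as<int>(th["scheme"]);
  t.kT = as<double>(th["kT"]);
  if (th.containsElementNamed("gamma") && !Rf_isNull(th["gamma"]))
    t.gamma = as<double>(th["gamma"]);
  if (th.containsElementNamed("tau") && !Rf_isNull(th["tau"]))
    t.tau = as<double>(th["tau"]);
  return t;
}

class Model {
public:
  int N = 0, d = 2, nt = 1, nmol = 0;
  std::vector<double> x, v, mass, q, boxlen;
  std::vector<int> type, molid, periodic;
  std::vector<double> eps, sig2, ushift;
  double rc2 = 0.0;
  bool shift = true;
  Elec el;
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak;
  std::vector<double> akth, acos0;
  FieldSpec field;
  bool excl = true;
  std::vector<int> mhead, mspec;  // per-molecule head particle, species code (0 A, 1 B, 2 other)
  Alch al;
  double lambda = 0.0;
  std::vector<double> f;
  bool fvalid = false;
  double Ev = 0.0, Ec = 0.0, Eb = 0.0;
  long long nev = 0;
  long long stepcount = 0;
  std::vector<Frame> frames;
  std::vector<double> elog;       // rows of 8 doubles

  Model(List sys, List mod) {
    NumericMatrix xm = sys["x"], vm = sys["v"];
    N = xm.nrow();
    d = xm.ncol();
    x.assign((size_t)N * d, 0.0);
    v.assign((size_t)N * d, 0.0);
    for (int i = 0; i < N; i++)
      for (int k = 0; k < d; k++) {
        x[(size_t)i * d + k] = xm(i, k);
        v[(size_t)i * d + k] = vm(i, k);
      }
    mass = as<std::vector<double> >(sys["mass"]);
    q = as<std::vector<double> >(sys["charge"]);
    IntegerVector tv = sys["type"];
    type.resize(N);
    for (int i = 0; i < N; i++) type[i] = tv[i] - 1;
    IntegerVector mv = sys["molecule_id"];
    molid.resize(N);
    for (int i = 0; i < N; i++) molid[i] = mv[i];
    List box = sys["box"];
    boxlen = as<std::vector<double> >(box["lengths"]);
    LogicalVector pv = box["periodic"];
    periodic.resize(d);
    for (int k = 0; k < d; k++) periodic[k] = pv[k] ? 1 : 0;

    NumericMatrix em = mod["eps"], sm = mod["sigma"];
    nt = em.nrow();
    eps.resize((size_t)nt * nt);
    sig2.resize((size_t)nt * nt);
    for (int a = 0; a < nt; a++)
      for (int b = 0; b < nt; b++) {
        eps[(size_t)a * nt + b] = em(a, b);
        double s = sm(a, b);
        sig2[(size_t)a * nt + b] = s * s;
      }
    double rc = as<double>(mod["cutoff"]);
    rc2 = rc * rc;
    shift = as<bool>(mod["shift"]);
    ushift.assign((size_t)nt * nt, 0.0);
    if (shift)
      for (size_t a = 0; a < (size_t)nt * nt; a++) {
        double s2 = sig2[a] / rc2, s6 = s2 * s2 * s2;
        ushift[a] = 4.0 * eps[a] * (s6 * s6 - s6);
      }
    if (!Rf_isNull(mod["elec"])) {
      List e = mod["elec"];
      el.on = true;
      el.pref = as<double>(e["pref"]);
      el.krf = as<double>(e["krf"]);
      el.crf = as<double>(e["crf"]);
      double rcc = as<double>(e["cutoff"]);
      el.rc2 = rcc * rcc;
    }
    if (!Rf_isNull(mod["bonds"])) {
      NumericMatrix bm = mod["bonds"];
      for (int r = 0; r < bm.nrow(); r++) {
        bi.push_back((int)bm(r, 0) - 1);
        bj.push_back((int)bm(r, 1) - 1);
        bk.push_back(bm(r, 2));
        br0.push_back(bm(r, 3));
      }
    }
    if (!Rf_isNull(mod["angles"])) {
      NumericMatrix am = mod["angles"];
      for (int r = 0; r < am.nrow(); r++) {
        ai.push_back((int)am(r, 0) - 1);
        aj.push_back((int)am(r, 1) - 1);
        ak.push_back((int)am(r, 2) - 1);
        akth.push_back(am(r, 3));
        acos0.push_back(std::cos(am(r, 4)));
      }
    }
    if (!Rf_isNull(mod["field"])) {
      List fl = mod["field"];
      field.on = true;
      field.k = as<double>(fl["k"]);
      field.center = as<std::vector<double> >(fl["center"]);
    }
    excl = as<bool>(mod["exclude_intramolecular"]);
    if (!Rf_isNull(mod["mol_head"])) {
      IntegerVector mh = mod["mol_head"], ms = mod["mol_species"];
      nmol = mh.size();
      mhead.resize(nmol);
      mspec.resize(nmol);
      for (int m = 0; m < nmol; m++) {
        mhead[m] = mh[m] - 1;
        mspec[m] = ms[m];
      }
    }
  }

  inline void mimg(double *dx) const {
    for (int k = 0; k < d; k++)
      if (periodic[k]) dx[k] -= boxlen[k] * std::nearbyint(dx[k] / boxlen[k]);
  }

  inline double ljs(int ti, int tj, double r2v) const {
    size_t a = (size_t)ti * nt + tj;
    double s2 = sig2[a] / r2v, s6 = s2 * s2 * s2;
    return 4.0 * eps[a] * (s6 * s6 - s6) - ushift[a];
  }
  inline double ljg(int ti, int tj, double r2v) const {
    size_t a = (size_t)ti * nt + tj;
    double s2 = sig2[a] / r2v, s6 = s2 * s2 * s2;
    return 24.0 * eps[a] * (2.0 * s6 * s6 - s6) / r2v;
  }
  // soft-core: U = 4 eps lam (A^6 - A^3), A = sigma^2 / (r^2 + delta (1 - lam))
  inline double sce(double ep, double s2v, double lam, double r2v, double dlt) const {
    if (lam <= 0.0 || ep == 0.0) return 0.0;
    double sden = r2v + dlt * (1.0 - lam);
    double A = s2v / sden, A3 = A * A * A;
    double u = 4.0 * ep * lam * (A3 * A3 - A3);
    if (shift) {
      double sc = rc2 + dlt * (1.0 - lam);
      double Acut = s2v / sc, Ac3 = Acut * Acut * Acut;
      u -= 4.0 * ep * lam * (Ac3 * Ac3 - Ac3);
    }
    return u;
  }
  inline double scg(double ep, double s2v, double lam, double r2v, double dlt) const {
    if (lam <= 0.0 || ep == 0.0) return 0.0;
    double sden = r2v + dlt * (1.0 - lam);
    double A = s2v / sden, A3 = A * A * A;
    return 8.0 * ep * lam * (6.0 * A3 * A3 - 3.0 * A3) / sden;
  }

  // swapped-endpoint bead type / charge of particle p
  inline int type1(int p) const {
    return (p == al.h1) ? al.t2 : ((p == al.h2) ? al.t1 : type[p]);
  }
  inline double charge1(int p) const {
    return (p == al.h1) ? al.q2 : ((p == al.h2) ? al.q1 : q[p]);
  }

  inline void vdw_pair(int i, int j, double r2v, bool tagged, double lam,
                       double &e, double *g) const {
    if (!tagged) {
      e = ljs(type[i], type[j], r2v);
      if (g) *g = ljg(type[i], type[j], r2v);
      return;
    }
    int ti0 = type[i], tj0 = type[j], ti1 = type1(i), tj1 = type1(j);
    if (al.softcore) {
      size_t a0 = (size_t)ti0 * nt + tj0, a1 = (size_t)ti1 * nt + tj1;
      e = sce(eps[a1], sig2[a1], lam, r2v, al.delta) +
          sce(eps[a0], sig2[a0], 1.0 - lam, r2v, al.delta);
      if (g)
        *g = scg(eps[a1], sig2[a1], lam, r2v, al.delta) +
             scg(eps[a0], sig2[a0], 1.0 - lam, r2v, al.delta);
    } else {
      e = (1.0 - lam) * ljs(ti0, tj0, r2v) + lam * ljs(ti1, tj1, r2v);
      if (g)
        *g = (1.0 - lam) * ljg(ti0, tj0, r2v) + lam * ljg(ti1, tj1, r2v);
    }
  }

  inline void coul_pair(int i, int j, double r2v, bool tagged, double lam,
                        double &e, double *g) const {
    double qp;
    if (tagged)
      qp = (1.0 - lam) * q[i] * q[j] + lam * charge1(i) * charge1(j);
    else
      qp = q[i] * q[j];
    if (qp == 0.0) { e = 0.0; if (g) *g = 0.0; return; }
    double r = std::sqrt(r2v);
    e = el.pref * qp * (1.0 / r + el.krf * r2v - el.crf);
    if (g) *g = el.pref * qp * (1.0 / (r2v * r) - 2.0 * el.krf);
  }

  void bonded_terms(bool wantf) {
    double dx[3], u[3], w[3];
    for (size_t b = 0; b < bi.size(); b++) {
      int i = bi[b], j = bj[b];
      double r2v = 0.0;
      for (int k = 0; k < d; k++) dx[k] = x[(size_t)i * d + k] - x[(size_t)j * d + k];
      mimg(dx);
      for (int k = 0; k < d; k++) r2v += dx[k] * dx[k];
      double r = std::sqrt(r2v), dr = r - br0[b];
      Eb += 0.5 * bk[b] * dr * dr;
      if (wantf && r > 0) {
        double gb = -bk[b] * dr / r;
        for (int k = 0; k < d; k++) {
          f[(size_t)i * d + k] += gb * dx[k];
          f[(size_t)j * d + k] -= gb * dx[k];
        }
      }
    }
    for (size_t a = 0; a < ai.size(); a++) {
      int i = ai[a], j = aj[a], kk = ak[a];
      double nu2 = 0.0, nw2 = 0.0, uw = 0.0;
      for (int k = 0; k < d; k++) {
        u[k] = x[(size_t)i * d + k] - x[(size_t)j * d + k];
        w[k] = x[(size_t)kk * d + k] - x[(size_t)j * d + k];
      }
      mimg(u);
      mimg(w);
      for (int k = 0; k < d; k++) {
        nu2 += u[k] * u[k];
        nw2 += w[k] * w[k];
        uw += u[k] * w[k];
      }
      double nu = std::sqrt(nu2), nw = std::sqrt(nw2);
      double c = uw / (nu * nw);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      double diff = c - acos0[a];
      Eb += 0.5 * akth[a] * diff * diff;
      if (wantf) {
        double pref = -akth[a] * diff;
        for (int k = 0; k < d; k++) {
          double dcdu = w[k] / (nu * nw) - c * u[k] / nu2;
          double dcdw = u[k] / (nu * nw) - c * w[k] / nw2;
          f[(size_t)i * d + k] += pref * dcdu;
          f[(size_t)kk * d + k] += pref * dcdw;
          f[(size_t)j * d + k] -= pref * (dcdu + dcdw);
        }
      }
    }
    if (field.on) {
      double keff = (al.kind == 2) ? ((1.0 - lambda) * al.k0 + lambda * al.k1)
                                   : field.k;
      if (keff != 0.0)
        for (int i = 0; i < N; i++)
          for (int k = 0; k < d; k++) {
            double dv = x[(size_t)i * d + k] - field.center[k];
            Eb += 0.5 * keff * dv * dv;
            if (wantf) f[(size_t)i * d + k] -= keff * dv;
          }
    }
  }

  // minimum image for wrapped coordinates (|dx| < L)
  inline double mi1(double dx, int k) const {
    if (!periodic[k]) return dx;
    double L = boxlen[k], h = 0.5 * L;
    if (dx > h) return dx - L;
    if (dx < -h) return dx + L;
    return dx;
  }

  void compute_all(bool wantf, bool count) {
    Ev = Ec = Eb = 0.0;
    if (wantf) f.assign((size_t)N * d, 0.0);
    double dx[3];
    const double rcmax2 = el.on ? (el.rc2 > rc2 ? el.rc2 : rc2) : rc2;
    const bool alch_on = (al.kind == 1);
    for (int i = 0; i < N - 1; i++) {
      const double *xi = &x[(size_t)i * d];
      const int mi_ = molid[i];
      const bool tag_i = alch_on && (i == al.h1 || i == al.h2);
      for (int j = i + 1; j < N; j++) {
        if (excl && mi_ == molid[j]) continue;
        const double *xj = &x[(size_t)j * d];
        double r2v = 0.0;
        for (int k = 0; k < d; k++) {
          dx[k] = mi1(xi[k] - xj[k], k);
          r2v += dx[k] * dx[k];
        }
        if (r2v >= rcmax2) continue;
        bool tag = tag_i || (alch_on && (j == al.h1 || j == al.h2));
        if (r2v < rc2) {
          double e, g;
          vdw_pair(i, j, r2v, tag, lambda, e, wantf ? &g : (double *)0);
          Ev += e;
          if (wantf)
            for (int k = 0; k < d; k++) {
              f[(size_t)i * d + k] += g * dx[k];
              f[(size_t)j * d + k] -= g * dx[k];
            }
        }
        if (el.on && r2v < el.rc2 && (tag || (q[i] != 0.0 && q[j] != 0.0))) {
          double e, g;
          coul_pair(i, j, r2v, tag, lambda, e, wantf ? &g : (double *)0);
          Ec += e;
          if (wantf)
            for (int k = 0; k < d; k++) {
              f[(size_t)i * d + k] += g * dx[k];
              f[(size_t)j * d + k] -= g * dx[k];
            }
        }
      }
    }
    bonded_terms(wantf);
    if (wantf) fvalid = true;
    if (count) nev++;
  }

  // lambda-dependent part of the potential (tagged-pair nonbonded terms for
  // kind 1, harmonic field for kind 2); e = {vdw, coulomb, bonded}
  void partial(double lam, double *e, double *fp) const {
    e[0] = e[1] = e[2] = 0.0;
    if (al.kind == 2) {
      double keff = (1.0 - lam) * al.k0 + lam * al.k1;
      for (int i = 0; i < N; i++)
        for (int k = 0; k < d; k++) {
          double dv = x[(size_t)i * d + k] - field.center[k];
          e[2] += 0.5 * keff * dv * dv;
          if (fp) fp[(size_t)i * d + k] -= keff * dv;
        }
      return;
    }
    if (al.kind != 1) return;
    double dx[3];
    int hs[2] = {al.h1, al.h2};
    for (int hi = 0; hi < 2; hi++) {
      int i = hs[hi];
      for (int j = 0; j < N; j++) {
        if (j == i) continue;
        if (hi == 1 && j == al.h1) continue;  // count (h1, h2) once
        if (excl && molid[i] == molid[j]) continue;
        double r2v = 0.0;
        for (int k = 0; k < d; k++) {
          dx[k] = mi1(x[(size_t)i * d + k] - x[(size_t)j * d + k], k);
          r2v += dx[k] * dx[k];
        }
        if (r2v < rc2) {
          double ev, g;
          vdw_pair(i, j, r2v, true, lam, ev, fp ? &g : (double *)0);
          e[0] += ev;
          if (fp)
            for (int k = 0; k < d; k++) {
              fp[(size_t)i * d + k] += g * dx[k];
              fp[(size_t)j * d + k] -= g * dx[k];
            }
        }
        if (el.on && r2v < el.rc2) {
          double ec, g;
          coul_pair(i, j, r2v, true, lam, ec, fp ? &g : (double *)0);
          e[1] += ec;
          if (fp)
            for (int k = 0; k < d; k++) {
              fp[(size_t)i * d + k] += g * dx[k];
              fp[(size_t)j * d + k] -= g * dx[k];
            }
        }
      }
    }
  }

  void ensure_forces() {
    if (!fvalid) compute_all(true, false);
  }

  double kinetic() const {
    double K = 0.0;
    for (int i = 0; i < N; i++)
      for (int k = 0; k < d; k++) {
        double vv = v[(size_t)i * d + k];
        K += 0.5 * mass[i] * vv * vv;
      }
    return K;
  }

  void wrap() {
    for (int k = 0; k < d; k++)
      if (periodic[k])
        for (int i = 0; i < N; i++) {
          double &xx = x[(size_t)i * d + k];
          xx -= boxlen[k] * std::floor(xx / boxlen[k]);
        }
  }

  void bussi(double dt, const Thermo &th) {
    int Nf = N * d;
    double K = kinetic();
    double Kbar = 0.5 * Nf * th.kT;
    double c = std::exp(-dt / th.tau);
    double r1 = norm_rand();
    double ssum = (Nf > 1) ? R::rchisq((double)(Nf - 1)) : 0.0;
    if (K <= 0.0) {  // degenerate start: draw Maxwell velocities
      for (int i = 0; i < N; i++)
        for (int k = 0; k < d; k++)
          v[(size_t)i * d + k] = std::sqrt(th.kT / mass[i]) * norm_rand();
      return;
    }
    double Knew = K * c + Kbar / Nf * (1.0 - c) * (r1 * r1 + ssum) +
                  2.0 * r1 * std::sqrt(K * Kbar / Nf * (1.0 - c) * c);
    if (Knew < 0.0) Knew = 0.0;
    double a = std::sqrt(Knew / K);
    for (size_t z = 0; z < v.size(); z++) v[z] *= a;
  }

  void md_steps(int n, double dt, const Thermo &th) {
    if (n <= 0) return;
    ensure_forces();
    double c1 = (th.scheme == 1) ? std::exp(-th.gamma * dt) : 0.0;
    double c2 = (th.scheme == 1) ? std::sqrt(1.0 - c1 * c1) : 0.0;
    for (int s = 0; s < n; s++) {
      for (int i = 0; i < N; i++)
        for (int k = 0; k < d; k++)
          v[(size_t)i * d + k] += 0.5 * dt * f[(size_t)i * d + k] / mass[i];
      for (size_t z = 0; z < x.size(); z++) x[z] += 0.5 * dt * v[z];
      if (th.scheme == 1)
        for (int i = 0; i < N; i++) {
          double sd = c2 * std::sqrt(th.kT / mass[i]);
          for (int k = 0; k < d; k++) {
            double &vv = v[(size_t)i * d + k];
            vv = c1 * vv + sd * norm_rand();
          }
        }
      for (size_t z = 0; z < x.size(); z++) x[z] += 0.5 * dt * v[z];
      wrap();
      compute_all(true, true);
      for (int i = 0; i < N; i++)
        for (int k = 0; k < d; k++)
          v[(size_t)i * d + k] += 0.5 * dt * f[(size_t)i * d + k] / mass[i];
      if (th.scheme == 2) bussi(dt, th);
      stepcount++;
      double mx = 0.0;
      bool bad = false;
      for (size_t z = 0; z < x.size(); z++) {
        if (!std::isfinite(x[z])) { bad = true; break; }
        double av = std::fabs(dt * v[z]);
        if (av > mx) mx = av;
      }
      if (bad)
        stop("dynamics blew up at step %d (non-finite coordinates; max step displacement %g)",
             (int)stepcount, mx);
    }
  }

  void capture_frame(double nev_offset) {
    Frame fr;
    fr.x = x;
    fr.q = q;
    fr.type = type;
    fr.nev = nev_offset + (double)nev;
    fr.step = (double)stepcount;
    frames.push_back(fr);
  }

  void elog_row(double nev_offset) {
    double K = kinetic();
    elog.push_back((double)stepcount);
    elog.push_back(nev_offset + (double)nev);
    elog.push_back(Ev + Ec + Eb);
    elog.push_back(Ev);
    elog.push_back(Ec);
    elog.push_back(Eb);
    elog.push_back(K);
    elog.push_back(N > 0 ? 2.0 * K / (double)(N * d) : 0.0);
  }

  // MD segment with frame / energy-log capture at fixed strides
  void run_segment(int n, double dt, const Thermo &th, int fs, int es,
                   double nev_offset) {
    if (n <= 0) return;
    ensure_forces();
    int done = 0;
    while (done < n) {
      int chunk = n - done;
      if (fs > 0) {
        int r = fs - (int)(stepcount % fs);
        if (r < chunk) chunk = r;
      }
      if (es > 0) {
        int r = es - (int)(stepcount % es);
        if (r < chunk) chunk = r;
      }
      md_steps(chunk, dt, th);
      done += chunk;
      if (fs > 0 && stepcount % fs == 0) capture_frame(nev_offset);
      if (es > 0 && stepcount % es == 0) elog_row(nev_offset);
    }
  }

  // alchemical trajectory: plateau MD then lambda increment, repeated until
  // lambda = 1; w accumulates per-term potential-energy jumps at increments
  void at_run(int M, double dlam, double dt, const Thermo &th, double *w) {
    int nlam = (int)std::lround(1.0 / dlam);
    w[0] = w[1] = w[2] = 0.0;
    ensure_forces();
    std::vector<double> fp0((size_t)N * d), fp1((size_t)N * d);
    double e0[3], e1[3];
    for (int il = 0; il < nlam; il++) {
      lambda = dlam * il;
      if (M > 0) md_steps(M, dt, th);
      double lnew = (il + 1 == nlam) ? 1.0 : dlam * (il + 1);
      std::fill(fp0.begin(), fp0.end(), 0.0);
      std::fill(fp1.begin(), fp1.end(), 0.0);
      partial(lambda, e0, fp0.data());
      partial(lnew, e1, fp1.data());
      for (int t = 0; t < 3; t++) w[t] += e1[t] - e0[t];
      for (size_t z = 0; z < f.size(); z++) f[z] += fp1[z] - fp0[z];
      lambda = lnew;
      if (M == 0) nev++;
      if (!std::isfinite(w[0] + w[1] + w[2]))
        stop("non-finite alchemical work at lambda = %g", lnew);
    }
  }

  List state_list() const {
    NumericMatrix xm(N, d), vm(N, d);
    for (int i = 0; i < N; i++)
      for (int k = 0; k < d; k++) {
        xm(i, k) = x[(size_t)i * d + k];
        vm(i, k) = v[(size_t)i * d + k];
      }
    IntegerVector tv(N);
    NumericVector qv(N);
    for (int i = 0; i < N; i++) {
      tv[i] = type[i] + 1;
      qv[i] = q[i];
    }
    return List::create(_["x"] = xm, _["v"] = vm, _["type"] = tv,
                        _["charge"] = qv);
  }

  List frames_list() const {
    List out(frames.size());
    for (size_t fi = 0; fi < frames.size(); fi++) {
      const Frame &fr = frames[fi];
      NumericMatrix xm(N, d);
      for (int i = 0; i < N; i++)
        for (int k = 0; k < d; k++) xm(i, k) = fr.x[(size_t)i * d + k];
      IntegerVector tv(N);
      NumericVector qv(N);
      for (int i = 0; i < N; i++) {
        tv[i] = fr.type[i] + 1;
        qv[i] = fr.q[i];
      }
      out[fi] = List::create(_["x"] = xm, _["type"] = tv, _["charge"] = qv,
                             _["force_evals"] = fr.nev, _["step"] = fr.step);
    }
    return out;
  }

  NumericMatrix elog_matrix() const {
    int nr = (int)(elog.size() / 8);
    NumericMatrix m(nr, 8);
    for (int r = 0; r < nr; r++)
      for (int c = 0; c < 8; c++) m(r, c) = elog[(size_t)r * 8 + c];
    colnames(m) = CharacterVector::create("step", "force_evals", "total",
                                          "vdw", "coulomb", "bonded",
                                          "kinetic", "temperature");
    return m;
  }

  void set_alch_pair(int molA, int molB, bool softcore, double delta) {
    al.kind = 1;
    al.h1 = mhead[molA];
    al.h2 = mhead[molB];
    al.t1 = type[al.h1];
    al.t2 = type[al.h2];
    al.q1 = q[al.h1];
    al.q2 = q[al.h2];
    al.softcore = softcore;
    al.delta = delta;
  }

  void bake_swap(int molA, int molB) {
    std::swap(type[al.h1], type[al.h2]);
    std::swap(q[al.h1], q[al.h2]);
    std::swap(mspec[molA], mspec[molB]);
  }
};

static Alch parse_alch(List a, const Model &m) {
  Alch al;
  al.kind = as<int>(a["kind"]);
  if (al.kind == 1) {
    al.h1 = as<int>(a["h1"]) - 1;
    al.h2 = as<int>(a["h2"]) - 1;
    al.t1 = m.type[al.h1];
    al.t2 = m.type[al.h2];
    al.q1 = m.q[al.h1];
    al.q2 = m.q[al.h2];
    al.softcore = as<bool>(a["softcore"]);
    al.delta = as<double>(a["delta"]);
  } else if (al.kind == 2) {
    al.k0 = as<double>(a["k0"]);
    al.k1 = as<double>(a["k1"]);
  }
  return al;
}

// [[Rcpp::export]]
List cpp_energy(List sys, List mod, Nullable<List> alch, double lambda) {
  Model m(sys, mod);
  if (alch.isNotNull()) m.al = parse_alch(alch.get(), m);
  m.lambda = lambda;
  m.compute_all(false, false);
  return List::create(_["total"] = m.Ev + m.Ec + m.Eb, _["vdw"] = m.Ev,
                      _["coulomb"] = m.Ec, _["bonded"] = m.Eb);
}

// [[Rcpp::export]]
List cpp_forces(List sys, List mod, Nullable<List> alch, double lambda) {
  Model m(sys, mod);
  if (alch.isNotNull()) m.al = parse_alch(alch.get(), m);
  m.lambda = lambda;
  m.compute_all(true, true);
  NumericMatrix fm(m.N, m.d);
  for (int i = 0; i < m.N; i++)
    for (int k = 0; k < m.d; k++) fm(i, k) = m.f[(size_t)i * m.d + k];
  return List::create(_["forces"] = fm,
                      _["energy"] = List::create(_["total"] = m.Ev + m.Ec + m.Eb,
                                                 _["vdw"] = m.Ev,
                                                 _["coulomb"] = m.Ec,
                                                 _["bonded"] = m.Eb));
}

// [[Rcpp::export]]
List cpp_partial_energy(List sys, List mod, List alch, double lambda) {
  Model m(sys, mod);
  m.al = parse_alch(alch, m);
  double e[3];
  m.partial(lambda, e, (double *)0);
  return List::create(_["total"] = e[0] + e[1] + e[2], _["vdw"] = e[0],
                      _["coulomb"] = e[1], _["bonded"] = e[2]);
}

// [[Rcpp::export]]
List cpp_md_run(List sys, List mod, Nullable<List> alch, double lambda,
                int n_steps, double dt, List thermo, int frame_stride,
                int elog_stride, double nev_offset) {
  Model m(sys, mod);
  if (alch.isNotNull()) m.al = parse_alch(alch.get(), m);
  m.lambda = lambda;
  Thermo th = parse_thermo(thermo);
  m.run_segment(n_steps, dt, th, frame_stride, elog_stride, nev_offset);
  return List::create(_["state"] = m.state_list(),
                      _["frames"] = m.frames_list(),
                      _["energy_log"] = m.elog_matrix(),
                      _["nevals"] = (double)m.nev,
                      _["energy"] = List::create(_["total"] = m.Ev + m.Ec + m.Eb,
                                                 _["vdw"] = m.Ev, _["coulomb"] = m.Ec,
                                                 _["bonded"] = m.Eb));
}

// [[Rcpp::export]]
NumericMatrix cpp_thermostat_step(NumericMatrix v, NumericVector mass,
                                  List thermo, double dt) {
  Thermo th = parse_thermo(thermo);
  int N = v.nrow(), d = v.ncol();
  NumericMatrix out = clone(v);
  if (th.scheme == 1) {
    double c1 = std::exp(-th.gamma * dt), c2 = std::sqrt(1.0 - c1 * c1);
    for (int i = 0; i < N; i++) {
      double sd = c2 * std::sqrt(th.kT / mass[i]);
      for (int k = 0; k < d; k++) out(i, k) = c1 * out(i, k) + sd * norm_rand();
    }
  } else if (th.scheme == 2) {
    int Nf = N * d;
    double K = 0.0;
    for (int i = 0; i < N; i++)
      for (int k = 0; k < d; k++) K += 0.5 * mass[i] * out(i, k) * out(i, k);
    double Kbar = 0.5 * Nf * th.kT;
    double c = std::exp(-dt / th.tau);
    double r1 = norm_rand();
    double ssum = (Nf > 1) ? R::rchisq((double)(Nf - 1)) : 0.0;
    if (K <= 0.0) {
      for (int i = 0; i < N; i++)
        for (int k = 0; k < d; k++)
          out(i, k) = std::sqrt(th.kT / mass[i]) * norm_rand();
      return out;
    }
    double Knew = K * c + Kbar / Nf * (1.0 - c) * (r1 * r1 + ssum) +
                  2.0 * r1 * std::sqrt(K * Kbar / Nf * (1.0 - c) * c);
    if (Knew < 0.0) Knew = 0.0;
    double a = std::sqrt(Knew / K);
    for (int i = 0; i < N; i++)
      for (int k = 0; k < d; k++) out(i, k) *= a;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_alch_traj(List sys, List mod, List alch, List thermo, double dt,
                   double dlam, int M) {
  Model m(sys, mod);
  m.al = parse_alch(alch, m);
  m.lambda = 0.0;
  Thermo th = parse_thermo(thermo);
  double w[3];
  m.at_run(M, dlam, dt, th, w);
  return List::create(_["w_total"] = w[0] + w[1] + w[2], _["w_vdw"] = w[0],
                      _["w_coulomb"] = w[1], _["w_bonded"] = w[2],
                      _["state"] = m.state_list(), _["nevals"] = (double)m.nev);
}

// [[Rcpp::export]]
List cpp_mc_delta(List sys, List mod, List alch) {
  Model m(sys, mod);
  m.al = parse_alch(alch, m);
  double e0[3], e1[3];
  m.partial(0.0, e0, (double *)0);
  m.partial(1.0, e1, (double *)0);
  return List::create(_["total"] = (e1[0] - e0[0]) + (e1[1] - e0[1]) + (e1[2] - e0[2]),
                      _["vdw"] = e1[0] - e0[0], _["coulomb"] = e1[1] - e0[1],
                      _["bonded"] = e1[2] - e0[2]);
}

// mode: 0 md, 1 mcmd, 2 mdas
// [[Rcpp::export]]
List cpp_run_sampler(List sys, List mod, List thermo, int mode, int seg_steps,
                     int n_attempts, double dt, double dlam, int M,
                     bool softcore, double delta, int frame_stride,
                     int elog_stride, double nev_offset) {
  Model m(sys, mod);
  Thermo th = parse_thermo(thermo);
  std::vector<int> Alist, Blist;
  for (int mm = 0; mm < m.nmol; mm++) {
    if (m.mspec[mm] == 0) Alist.push_back(mm);
    else if (m.mspec[mm] == 1) Blist.push_back(mm);
  }
  int nA = (int)Alist.size(), nB = (int)Blist.size();
  if (mode >= 1 && (nA == 0 || nB == 0))
    stop("no unlike molecule pair available for exchange (need both species)");
  int nlam = (dlam > 0) ? (int)std::lround(1.0 / dlam) : 1;
  NumericMatrix wlog(mode >= 1 ? n_attempts : 0, 10);
  std::vector<double> fp0, fp1;
  m.ensure_forces();
  for (int a = 0; a < n_attempts; a++) {
    m.run_segment(seg_steps, dt, th, frame_stride, elog_stride, nev_offset);
    if (mode == 0) continue;
    long long nev_before = m.nev;
    int iA = (int)(unif_rand() * nA);
    if (iA >= nA) iA = nA - 1;
    int iB = (int)(unif_rand() * nB);
    if (iB >= nB) iB = nB - 1;
    int molA = Alist[iA], molB = Blist[iB];
    m.set_alch_pair(molA, molB, softcore, delta);
    double w[3];
    bool acc;
    if (mode == 1) {
      double e0[3], e1[3];
      m.partial(0.0, e0, (double *)0);
      m.partial(1.0, e1, (double *)0);
      for (int t = 0; t < 3; t++) w[t] = e1[t] - e0[t];
      m.nev++;
      double wtot = w[0] + w[1] + w[2];
      double u = unif_rand();
      acc = std::log(u) < -wtot / th.kT;
      if (acc) {
        fp0.assign(m.f.size(), 0.0);
        fp1.assign(m.f.size(), 0.0);
        m.partial(0.0, e0, fp0.data());
        m.partial(1.0, e1, fp1.data());
        for (size_t z = 0; z < m.f.size(); z++) m.f[z] += fp1[z] - fp0[z];
        m.bake_swap(molA, molB);
        Alist[iA] = molB;
        Blist[iB] = molA;
      }
    } else {
      std::vector<double> xs = m.x, vs = m.v, fs = m.f;
      m.at_run(M, dlam, dt, th, w);
      double wtot = w[0] + w[1] + w[2];
      double u = unif_rand();
      acc = std::log(u) < -wtot / th.kT;
      if (acc) {
        // cached forces at lambda = 1 equal post-swap plain forces
        m.bake_swap(molA, molB);
        Alist[iA] = molB;
        Blist[iB] = molA;
      } else {
        m.x = xs;
        m.v = vs;
        m.f = fs;
      }
    }
    m.al = Alch();
    m.lambda = 0.0;
    wlog(a, 0) = a + 1;
    wlog(a, 1) = molA + 1;
    wlog(a, 2) = molB + 1;
    wlog(a, 3) = w[0] + w[1] + w[2];
    wlog(a, 4) = w[0];
    wlog(a, 5) = w[1];
    wlog(a, 6) = w[2];
    wlog(a, 7) = acc ? 1.0 : 0.0;
    wlog(a, 8) = (double)(m.nev - nev_before);
    wlog(a, 9) = nev_offset + (double)m.nev;
  }
  colnames(wlog) = CharacterVector::create(
      "attempt", "pair_a", "pair_b", "w_total", "w_vdw", "w_coulomb",
      "w_bonded", "accepted", "evals_attempt", "cumulative_force_evals");
  IntegerVector spec(m.nmol);
  for (int mm = 0; mm < m.nmol; mm++) spec[mm] = m.mspec[mm];
  return List::create(_["state"] = m.state_list(), _["work_log"] = wlog,
                      _["frames"] = m.frames_list(),
                      _["energy_log"] = m.elog_matrix(),
                      _["nevals"] = (double)m.nev,
                      _["mol_species"] = spec);
}

// pair-distance histogram for the RDF (counts per bin, minimum image)
// [[Rcpp::export]]
IntegerVector cpp_rdf_counts(NumericMatrix x, NumericVector boxlen,
                             LogicalVector periodic, IntegerVector sel,
                             double rmax, int nbins) {
  int d = x.ncol(), n = sel.size();
  IntegerVector counts(nbins);
  double dx[3], rmax2 = rmax * rmax, w = rmax / nbins;
  for (int a = 0; a < n - 1; a++) {
    int i = sel[a] - 1;
    for (int b = a + 1; b < n; b++) {
      int j = sel[b] - 1;
      double r2 = 0.0;
      for (int k = 0; k < d; k++) {
        dx[k] = x(i, k) - x(j, k);
        if (periodic[k]) dx[k] -= boxlen[k] * std::nearbyint(dx[k] / boxlen[k]);
        r2 += dx[k] * dx[k];
      }
      if (r2 < rmax2) {
        int bin = (int)(std::sqrt(r2) / w);
        if (bin >= 0 && bin < nbins) counts[bin]++;
      }
    }
  }
  return counts;
}
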