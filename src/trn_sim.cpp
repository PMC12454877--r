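// Compartmental conductance-based simulator core.
//
// One code path serves both the single-cell current-clamp integrator and the
// reduced thalamoreticular network: the system is a forest of compartment
// trees (parent index < child index), advanced with a staggered scheme --
// exponential-Euler gate updates followed by a backward-Euler solve of the
// voltage/axial system (Hines elimination per tree).  Voltage-dependent rates
// are tabulated once per run on a fixed grid and linearly interpolated.
//
// Units: mV, ms, mM, S/cm^2, mA/cm^2, uF/cm^2, Ohm*cm; injected currents nA;
// axial and gap-junction conductances in S.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- kinetic-constant vector layout (built by R from trn_mechanisms()) ----
enum Kin {
  K_VTRAUB = 0,
  K_NA_M = 1,   // a_rate, a_v, a_k, b_rate, b_v, b_k
  K_NA_H = 7,
  K_K_N = 13,
  K_IT_M = 19,  // vhalf, k, tau0, tauamp, v1, k1, v2, k2
  K_IT_H = 27,
  K_AHP = 35,   // cac, beta, taumin
  K_CAN = 38,   // cac, beta, taumin
  K_IA_M = 41,  // vhalf, k, tau0, tauamp, v1, k1, v2, k2
  K_IA_H = 49,
  K_CAD = 57,   // depth, tau, cainf, cao
  K_EPAS = 61,
  K_ECAN = 62,
  K_AHP_SHIFT = 63,
  K_TADJ_HH2 = 64,
  K_TADJ_IT = 65,
  K_TADJ_IA = 66,
  K_TADJ_AHP = 67,
  K_TADJ_CAN = 68,
  K_ENA = 69,
  K_EK = 70,
  K_TEMP = 71,  // degrees C (for the calcium Nernst potential)
  K_LEN = 72
};

static const double FARADAY = 96485.332;
static const double GASCONST = 8.314462;

static inline double vtrap(double x, double k) {
  // x / (exp(x/k) - 1) with the removable singularity handled
  if (std::fabs(x / k) < 1e-6) return k * (1.0 - x / k / 2.0);
  return x / (std::exp(x / k) - 1.0);
}

// generic bi-exponential time constant: t0 + amp/(exp((v+v1)/k1)+exp(-(v+v2)/k2))
static inline double tau_biexp(double v, const double* p) {
  return p[2] + p[3] / (std::exp((v + p[4]) / p[5]) + std::exp(-(v + p[6]) / p[7]));
}
static inline double boltz(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}

// ---------------- rate tables ----------------
struct RateTables {
  double vmin, vmax, dv;
  int n;
  // steady states and time constants on the grid
  std::vector<double> na_minf, na_mtau, na_hinf, na_htau, k_ninf, k_ntau;
  std::vector<double> it_minf, it_mtau, it_hinf, it_htau;
  std::vector<double> ia_minf, ia_mtau, ia_hinf, ia_htau;

  void build(const NumericVector& kin) {
    vmin = -150.0; vmax = 70.0; dv = 0.05;
    n = (int)std::floor((vmax - vmin) / dv) + 1;
    na_minf.resize(n); na_mtau.resize(n); na_hinf.resize(n); na_htau.resize(n);
    k_ninf.resize(n); k_ntau.resize(n);
    it_minf.resize(n); it_mtau.resize(n); it_hinf.resize(n); it_htau.resize(n);
    ia_minf.resize(n); ia_mtau.resize(n); ia_hinf.resize(n); ia_htau.resize(n);
    const double vt = kin[K_VTRAUB];
    for (int i = 0; i < n; i++) {
      double v = vmin + i * dv;
      double v2 = v - vt;
      // hh2 sodium m
      {
        const double* p = &kin[K_NA_M];
        double a = p[0] * vtrap(p[1] - v2, p[2]);
        double b = p[3] * vtrap(v2 - p[4], p[5]);
        na_minf[i] = a / (a + b); na_mtau[i] = 1.0 / (a + b);
      }
      // hh2 sodium h
      {
        const double* p = &kin[K_NA_H];
        double a = p[0] * std::exp((p[1] - v2) / p[2]);
        double b = p[3] / (1.0 + std::exp((p[4] - v2) / p[5]));
        na_hinf[i] = a / (a + b); na_htau[i] = 1.0 / (a + b);
      }
      // hh2 potassium n
      {
        const double* p = &kin[K_K_N];
        double a = p[0] * vtrap(p[1] - v2, p[2]);
        double b = p[3] * std::exp((p[4] - v2) / p[5]);
        k_ninf[i] = a / (a + b); k_ntau[i] = 1.0 / (a + b);
      }
      // T-type
      it_minf[i] = boltz(v, kin[K_IT_M], kin[K_IT_M + 1]);
      it_mtau[i] = tau_biexp(v, &kin[K_IT_M]);
      it_hinf[i] = 1.0 - boltz(v, kin[K_IT_H], kin[K_IT_H + 1]);
      it_htau[i] = tau_biexp(v, &kin[K_IT_H]);
      // A-type
      ia_minf[i] = boltz(v, kin[K_IA_M], kin[K_IA_M + 1]);
      ia_mtau[i] = tau_biexp(v, &kin[K_IA_M]);
      ia_hinf[i] = 1.0 - boltz(v, kin[K_IA_H], kin[K_IA_H + 1]);
      ia_htau[i] = tau_biexp(v, &kin[K_IA_H]);
    }
  }
  inline void lookup(const std::vector<double>& tinf, const std::vector<double>& ttau,
                     double v, double& inf, double& tau) const {
    double x = (v - vmin) / dv;
    if (x < 0) x = 0;
    if (x > n - 1.001) x = n - 1.001;
    int i = (int)x;
    double f = x - i;
    inf = tinf[i] + f * (tinf[i + 1] - tinf[i]);
    tau = ttau[i] + f * (ttau[i + 1] - ttau[i]);
  }

  // per-step relaxation factors exp(-dt * tadj / tau(v)), tabulated once per
  // (kinetics, dt) combination
  double built_dt = -1.0;
  std::vector<double> f_na_m, f_na_h, f_k_n, f_it_m, f_it_h, f_ia_m, f_ia_h;
  void build_exp(const NumericVector& kin, double dt) {
    auto mk = [&](const std::vector<double>& ttau, double tadj,
                  std::vector<double>& out) {
      out.resize(n);
      for (int i = 0; i < n; i++) out[i] = std::exp(-dt * tadj / ttau[i]);
    };
    mk(na_mtau, kin[K_TADJ_HH2], f_na_m);
    mk(na_htau, kin[K_TADJ_HH2], f_na_h);
    mk(k_ntau, kin[K_TADJ_HH2], f_k_n);
    mk(it_mtau, kin[K_TADJ_IT], f_it_m);
    mk(it_htau, kin[K_TADJ_IT], f_it_h);
    mk(ia_mtau, kin[K_TADJ_IA], f_ia_m);
    mk(ia_htau, kin[K_TADJ_IA], f_ia_h);
    built_dt = dt;
  }
  inline void lookup_f(const std::vector<double>& tinf,
                       const std::vector<double>& tf, double v,
                       double& inf, double& f) const {
    double x = (v - vmin) / dv;
    if (x < 0) x = 0;
    if (x > n - 1.001) x = n - 1.001;
    int i = (int)x;
    double w = x - i;
    inf = tinf[i] + w * (tinf[i + 1] - tinf[i]);
    f = tf[i] + w * (tf[i + 1] - tf[i]);
  }
};

// ---------------- system state ----------------
struct System {
  int ncomp;
  std::vector<int> parent;           // -1 for tree roots
  std::vector<double> area;          // cm^2
  std::vector<double> gax;           // S, conductance to parent (0 for roots)
  std::vector<double> cmf;           // cm * 1e-3 (mA*ms/(mV*cm^2))
  // mechanism densities, S/cm^2
  std::vector<double> gna, gk, git, git2, gahp, gican, gia, gpas;
  std::vector<double> vshift, vshift2;  // T-type window shifts per compartment
  // state
  std::vector<double> v, cai, eca_v;
  std::vector<double> m_na, h_na, n_k, m_it, h_it, m_it2, h_it2;
  std::vector<double> m_ahp, m_can, m_ia, h_ia;
  // scratch for the Hines solve
  std::vector<double> d, rhs, b_self;
  int eca_refresh = 5;  // steps between Nernst-potential refreshes
  int step_count = 0;

  NumericVector kin;
  RateTables* rt;

  void init_from(List sys) {
    parent = as<std::vector<int>>(sys["parent"]);
    ncomp = (int)parent.size();
    area = as<std::vector<double>>(sys["area"]);
    gax = as<std::vector<double>>(sys["gax"]);
    NumericVector cmv = sys["cm"];
    cmf.resize(ncomp);
    for (int i = 0; i < ncomp; i++) cmf[i] = cmv[i] * 1e-3;
    gna = as<std::vector<double>>(sys["gna"]);
    gk = as<std::vector<double>>(sys["gk"]);
    git = as<std::vector<double>>(sys["git"]);
    git2 = as<std::vector<double>>(sys["git2"]);
    gahp = as<std::vector<double>>(sys["gahp"]);
    gican = as<std::vector<double>>(sys["gican"]);
    gia = as<std::vector<double>>(sys["gia"]);
    gpas = as<std::vector<double>>(sys["gpas"]);
    vshift = as<std::vector<double>>(sys["vshift"]);
    vshift2 = as<std::vector<double>>(sys["vshift2"]);
    kin = sys["kin"];
    // rate tables depend only on the kinetic constants, which are identical
    // across calls within a sweep; keep the last build cached
    static std::vector<double> cached_kin;
    static RateTables cached_rt;
    std::vector<double> kv = as<std::vector<double>>(kin);
    if (kv != cached_kin) {
      cached_rt.build(kin);
      cached_rt.built_dt = -1.0;
      cached_kin = kv;
    }
    rt = &cached_rt;
    d.resize(ncomp); rhs.resize(ncomp); b_self.resize(ncomp);
  }

  void init_state(double v_init) {
    v.assign(ncomp, v_init);
    cai.assign(ncomp, kin[K_CAD + 2]);
    eca_v.assign(ncomp, 0.0);
    step_count = 0;
    for (int i = 0; i < ncomp; i++) eca_v[i] = eca(i);
    m_na.resize(ncomp); h_na.resize(ncomp); n_k.resize(ncomp);
    m_it.resize(ncomp); h_it.resize(ncomp); m_it2.resize(ncomp); h_it2.resize(ncomp);
    m_ahp.resize(ncomp); m_can.resize(ncomp); m_ia.resize(ncomp); h_ia.resize(ncomp);
    double inf, tau;
    for (int i = 0; i < ncomp; i++) {
      rt->lookup(rt->na_minf, rt->na_mtau, v_init, inf, tau); m_na[i] = inf;
      rt->lookup(rt->na_hinf, rt->na_htau, v_init, inf, tau); h_na[i] = inf;
      rt->lookup(rt->k_ninf, rt->k_ntau, v_init, inf, tau); n_k[i] = inf;
      rt->lookup(rt->it_minf, rt->it_mtau, v_init + vshift[i], inf, tau); m_it[i] = inf;
      rt->lookup(rt->it_hinf, rt->it_htau, v_init + vshift[i], inf, tau); h_it[i] = inf;
      rt->lookup(rt->it_minf, rt->it_mtau, v_init + vshift2[i], inf, tau); m_it2[i] = inf;
      rt->lookup(rt->it_hinf, rt->it_htau, v_init + vshift2[i], inf, tau); h_it2[i] = inf;
      rt->lookup(rt->ia_minf, rt->ia_mtau, v_init, inf, tau); m_ia[i] = inf;
      rt->lookup(rt->ia_hinf, rt->ia_htau, v_init, inf, tau); h_ia[i] = inf;
      m_ahp[i] = ca_gate_inf(cai[i], &kin[K_AHP]);
      m_can[i] = ca_gate_inf(cai[i], &kin[K_CAN]);
    }
  }

  static inline double ca_gate_inf(double ca, const double* p) {
    double car = (ca / p[0]) * (ca / p[0]);
    return car / (1.0 + car);
  }
  static inline double ca_gate_tau(double ca, const double* p) {
    double car = (ca / p[0]) * (ca / p[0]);
    double tau = 1.0 / (p[1] * (1.0 + car));
    return tau < p[2] ? p[2] : tau;
  }

  inline double eca(int i) const {
    double cao = kin[K_CAD + 3];
    double TK = kin[K_TEMP] + 273.15;
    double ca = cai[i] < 1e-9 ? 1e-9 : cai[i];
    return 1000.0 * GASCONST * TK / (2.0 * FARADAY) * std::log(cao / ca);
  }

  static inline void expeuler(double& g, double inf, double tau, double dt, double tadj) {
    double t = tau / tadj;
    g = inf + (g - inf) * std::exp(-dt / t);
    if (g < 0) g = 0;
    if (g > 1) g = 1;
  }

  static inline void relax(double& g, double inf, double f) {
    g = inf + (g - inf) * f;
    if (g < 0) g = 0;
    if (g > 1) g = 1;
  }

  void update_gates(double dt) {
    if (rt->built_dt != dt) rt->build_exp(kin, dt);
    const double tj_ahp = kin[K_TADJ_AHP], tj_can = kin[K_TADJ_CAN];
    double inf, f;
    for (int i = 0; i < ncomp; i++) {
      double vi = v[i];
      if (gna[i] > 0) {
          rt->lookup_f(rt->na_minf, rt->f_na_m, vi, inf, f); relax(m_na[i], inf, f);
          rt->lookup_f(rt->na_hinf, rt->f_na_h, vi, inf, f); relax(h_na[i], inf, f);
      }
      if (gk[i] > 0) {
          rt->lookup_f(rt->k_ninf, rt->f_k_n, vi, inf, f); relax(n_k[i], inf, f);
      }
      if (git[i] > 0) {
        double vs = vi + vshift[i];
          rt->lookup_f(rt->it_minf, rt->f_it_m, vs, inf, f); relax(m_it[i], inf, f);
          rt->lookup_f(rt->it_hinf, rt->f_it_h, vs, inf, f); relax(h_it[i], inf, f);
      }
      if (git2[i] > 0) {
        double vs = vi + vshift2[i];
          rt->lookup_f(rt->it_minf, rt->f_it_m, vs, inf, f); relax(m_it2[i], inf, f);
          rt->lookup_f(rt->it_hinf, rt->f_it_h, vs, inf, f); relax(h_it2[i], inf, f);
      }
      if (gia[i] > 0) {
          rt->lookup_f(rt->ia_minf, rt->f_ia_m, vi, inf, f); relax(m_ia[i], inf, f);
          rt->lookup_f(rt->ia_hinf, rt->f_ia_h, vi, inf, f); relax(h_ia[i], inf, f);
      }
      if (gahp[i] > 0) {
        expeuler(m_ahp[i], ca_gate_inf(cai[i], &kin[K_AHP]),
                 ca_gate_tau(cai[i], &kin[K_AHP]), dt, tj_ahp);
      }
      if (gican[i] > 0) {
        expeuler(m_can[i], ca_gate_inf(cai[i], &kin[K_CAN]),
                 ca_gate_tau(cai[i], &kin[K_CAN]), dt, tj_can);
      }
    }
  }

  // assemble and solve backward-Euler voltage system; i_extra_* are per-comp
  // additive conductance (S/cm^2, into diagonal) and current (mA/cm^2, into rhs)
  // used for synapses, gap junctions, and injected currents.
  bool solve_voltage(double dt, const std::vector<double>& g_extra,
                     const std::vector<double>& i_extra) {
    const double ena = kin[K_ENA], ek = kin[K_EK], epas = kin[K_EPAS],
                 ecan = kin[K_ECAN], eahp = kin[K_EK] + kin[K_AHP_SHIFT];
    for (int i = 0; i < ncomp; i++) {
      double gtot = gpas[i], gesum = gpas[i] * epas;
      if (gna[i] > 0) {
        double g = gna[i] * m_na[i] * m_na[i] * m_na[i] * h_na[i];
        gtot += g; gesum += g * ena;
      }
      if (gk[i] > 0) {
        double g = gk[i] * n_k[i] * n_k[i] * n_k[i] * n_k[i];
        gtot += g; gesum += g * ek;
      }
      double ecai = eca_v[i];
      if (git[i] > 0) {
        double g = git[i] * m_it[i] * m_it[i] * h_it[i];
        gtot += g; gesum += g * ecai;
      }
      if (git2[i] > 0) {
        double g = git2[i] * m_it2[i] * m_it2[i] * h_it2[i];
        gtot += g; gesum += g * ecai;
      }
      if (gahp[i] > 0) {
        double g = gahp[i] * m_ahp[i] * m_ahp[i];
        gtot += g; gesum += g * eahp;
      }
      if (gican[i] > 0) {
        double g = gican[i] * m_can[i] * m_can[i];
        gtot += g; gesum += g * ecan;
      }
      if (gia[i] > 0) {
        double g = gia[i] * m_ia[i] * m_ia[i] * m_ia[i] * m_ia[i] * h_ia[i];
        gtot += g; gesum += g * ek;
      }
      d[i] = cmf[i] / dt + gtot + g_extra[i];
      rhs[i] = cmf[i] / dt * v[i] + gesum + i_extra[i];
    }
    // axial terms; children have larger indices than parents
    for (int i = 0; i < ncomp; i++) {
      int p = parent[i];
      if (p >= 0) {
        d[i] += gax[i] / area[i];
        d[p] += gax[i] / area[p];
        b_self[i] = -gax[i] / area[i];  // coefficient of v_p in eq i
      } else {
        b_self[i] = 0.0;
      }
    }
    // Hines elimination: fold each child into its parent
    for (int i = ncomp - 1; i >= 0; i--) {
      int p = parent[i];
      if (p < 0) continue;
      double b_parent = -gax[i] / area[p];  // coefficient of v_i in eq p
      double f = b_parent / d[i];
      d[p] -= f * b_self[i];
      rhs[p] -= f * rhs[i];
    }
    for (int i = 0; i < ncomp; i++) {
      int p = parent[i];
      double vi = (p < 0) ? rhs[i] / d[i] : (rhs[i] - b_self[i] * v[p]) / d[i];
      if (!std::isfinite(vi)) return false;
      v[i] = vi;
    }
    return true;
  }

  void update_calcium(double dt) {
    const double depth = kin[K_CAD], taucad = kin[K_CAD + 1], cainf = kin[K_CAD + 2];
    step_count++;
    bool refresh = (step_count % eca_refresh) == 0;
    for (int i = 0; i < ncomp; i++) {
      if (git[i] <= 0 && git2[i] <= 0) continue;
      double ecai = eca_v[i];
      double ica = 0.0;
      if (git[i] > 0) ica += git[i] * m_it[i] * m_it[i] * h_it[i] * (v[i] - ecai);
      if (git2[i] > 0) ica += git2[i] * m_it2[i] * m_it2[i] * h_it2[i] * (v[i] - ecai);
      double drive = -1e4 * ica / (2.0 * FARADAY * depth);  // mM/ms
      if (drive < 0) drive = 0;
      double steady = cainf + drive * taucad;
      cai[i] = steady + (cai[i] - steady) * std::exp(-dt / taucad);
      if (refresh) eca_v[i] = eca(i);
    }
  }
};

// ---------------- single-cell current clamp ----------------
// [[Rcpp::export]]
List cpp_integrate_cell(List sys, NumericVector stim_start, NumericVector stim_end,
                        NumericVector stim_amp, int stim_comp, double dt,
                        double t_stop, double v_init, int record_comp,
                        int record_every) {
  System S;
  S.init_from(sys);
  S.init_state(v_init);
  int nstep = (int)std::round(t_stop / dt);
  int nrec = nstep / record_every + 1;
  NumericVector out_t(nrec), out_v(nrec), out_i(nrec);
  std::vector<double> g_extra(S.ncomp, 0.0), i_extra(S.ncomp, 0.0);
  int nseg = stim_start.size();
  out_t[0] = 0.0; out_v[0] = S.v[record_comp]; out_i[0] = 0.0;
  int irec = 1;
  int fail_step = -1;
  for (int step = 0; step < nstep; step++) {
    double t_mid = (step + 0.5) * dt;
    double amp = 0.0;
    for (int s = 0; s < nseg; s++) {
      if (t_mid >= stim_start[s] && t_mid < stim_end[s]) { amp += stim_amp[s]; }
    }
    i_extra[stim_comp] = amp * 1e-6 / S.area[stim_comp];
    S.update_gates(dt);
    if (!S.solve_voltage(dt, g_extra, i_extra)) { fail_step = step; break; }
    S.update_calcium(dt);
    if ((step + 1) % record_every == 0) {
      out_t[irec] = (step + 1) * dt;
      out_v[irec] = S.v[record_comp];
      out_i[irec] = amp;
      irec++;
    }
  }
  return List::create(_["t"] = out_t, _["v"] = out_v, _["i_inj"] = out_i,
                      _["fail_step"] = fail_step);
}

// ---------------- network ----------------
// Chemical synapses: Tsodyks-Markram release on presynaptic somatic spikes
// (upward crossing of 0 mV, 2 ms refractory), single-exponential conductance.
// External (corticothalamic) afferent spikes are supplied pre-generated.
// Gap junctions: ohmic coupling, semi-implicit (own voltage implicit,
// partner voltage from the previous step).
// [[Rcpp::export]]
List cpp_simulate_network(List sys, List net, double dt, double t_stop,
                          double v_init, IntegerVector record_comps,
                          int record_every) {
  System S;
  S.init_from(sys);
  S.init_state(v_init);

  IntegerVector cell_of = sys["cell_of"];        // compartment -> cell id (0-based)
  IntegerVector soma_comp = sys["soma_comp"];    // cell -> soma compartment
  int ncell = soma_comp.size();

  // synapses
  IntegerVector syn_pre = net["syn_pre"];        // cell id, or -1 for external
  IntegerVector syn_ext = net["syn_ext"];        // external afferent id (-1 if internal)
  IntegerVector syn_post = net["syn_post"];      // postsynaptic compartment
  NumericVector syn_e = net["syn_e"], syn_tau = net["syn_tau"],
                syn_gmax = net["syn_gmax"], syn_U = net["syn_U"],
                syn_trec = net["syn_trec"], syn_tfac = net["syn_tfac"],
                syn_delay = net["syn_delay"];
  int nsyn = syn_pre.size();
  std::vector<double> syn_g(nsyn, 0.0), syn_u(nsyn), syn_r(nsyn, 1.0),
      syn_last(nsyn, -1e9);
  for (int s = 0; s < nsyn; s++) syn_u[s] = syn_U[s];

  // presynaptic index: list of synapses per source
  std::vector<std::vector<int>> syn_of_cell(ncell);
  int next_id = 0;
  IntegerVector ext_src = net["ext_id"];         // sorted external events
  NumericVector ext_t = net["ext_t"];
  for (int s = 0; s < nsyn; s++) {
    if (syn_pre[s] >= 0) syn_of_cell[syn_pre[s]].push_back(s);
    if (syn_ext[s] >= 0 && syn_ext[s] + 1 > next_id) next_id = syn_ext[s] + 1;
  }
  std::vector<std::vector<int>> syn_of_ext(next_id);
  for (int s = 0; s < nsyn; s++)
    if (syn_ext[s] >= 0) syn_of_ext[syn_ext[s]].push_back(s);

  // gap junctions
  IntegerVector gj_a = net["gj_a"], gj_b = net["gj_b"];
  NumericVector gj_g = net["gj_g"];  // S
  int ngj = gj_a.size();

  // delayed release events: simple ring-buffered queue by step
  int nstep = (int)std::round(t_stop / dt);
  std::vector<std::vector<int>> pending((size_t)nstep + 2);  // synapse ids to trigger

  auto schedule = [&](int s, double t_now) {
    int at = (int)std::round((t_now + syn_delay[s]) / dt);
    if (at <= nstep + 1 && at >= 0) pending[at].push_back(s);
  };

  // spike detection state
  std::vector<double> last_spike(ncell, -1e9);
  std::vector<double> v_prev_soma(ncell, v_init);
  std::vector<int> raster_cell;
  std::vector<double> raster_t;

  std::vector<double> g_extra(S.ncomp), i_extra(S.ncomp);
  int nrecc = record_comps.size();
  int nrec = nstep / record_every + 1;
  NumericMatrix vrec(nrec, nrecc);
  NumericVector trec(nrec);
  for (int j = 0; j < nrecc; j++) vrec(0, j) = S.v[record_comps[j]];
  trec[0] = 0.0;
  int irec = 1;
  int iext = 0;
  int next_ext = ext_t.size();
  int fail_step = -1;

  for (int step = 0; step < nstep; step++) {
    double t = step * dt;
    // external afferent events
    while (iext < next_ext && ext_t[iext] < t + dt) {
      int id = ext_src[iext];
      if (id >= 0 && id < (int)syn_of_ext.size())
        for (int s : syn_of_ext[id]) schedule(s, ext_t[iext]);
      iext++;
    }
    // due releases: TM update then conductance increment
    for (int s : pending[step]) {
      double dtl = t - syn_last[s];
      if (syn_last[s] < -1e8) dtl = 1e9;
      double u = syn_U[s], r = syn_r[s];
      if (syn_tfac[s] > 0)
        u = syn_U[s] + syn_u[s] * (1.0 - syn_U[s]) * std::exp(-dtl / syn_tfac[s]);
      r = 1.0 - (1.0 - syn_r[s] * (1.0 - syn_u[s])) * std::exp(-dtl / syn_trec[s]);
      syn_u[s] = u; syn_r[s] = r;
      syn_g[s] += u * r * syn_gmax[s];
      syn_last[s] = t;
    }
    pending[step].clear();

    // accumulate synapse + gap-junction terms
    std::fill(g_extra.begin(), g_extra.end(), 0.0);
    std::fill(i_extra.begin(), i_extra.end(), 0.0);
    for (int s = 0; s < nsyn; s++) {
      if (syn_g[s] <= 1e-12) { syn_g[s] = 0.0; continue; }
      int pc = syn_post[s];
      double g = syn_g[s] / S.area[pc];  // S -> S/cm^2
      g_extra[pc] += g;
      i_extra[pc] += g * syn_e[s];
      syn_g[s] *= std::exp(-dt / syn_tau[s]);
    }
    for (int s = 0; s < ngj; s++) {
      int a = gj_a[s], b = gj_b[s];
      double g = gj_g[s];
      g_extra[a] += g / S.area[a];
      i_extra[a] += g * S.v[b] / S.area[a];
      g_extra[b] += g / S.area[b];
      i_extra[b] += g * S.v[a] / S.area[b];
    }

    S.update_gates(dt);
    if (!S.solve_voltage(dt, g_extra, i_extra)) { fail_step = step; break; }
    S.update_calcium(dt);

    // somatic spike detection (0 mV upward crossing)
    for (int c = 0; c < ncell; c++) {
      double vs = S.v[soma_comp[c]];
      if (v_prev_soma[c] < 0.0 && vs >= 0.0 && (t - last_spike[c]) > 2.0) {
        last_spike[c] = t + dt;
        raster_cell.push_back(c);
        raster_t.push_back(t + dt);
        for (int s : syn_of_cell[c]) schedule(s, t + dt);
      }
      v_prev_soma[c] = vs;
    }

    if ((step + 1) % record_every == 0) {
      trec[irec] = (step + 1) * dt;
      for (int j = 0; j < nrecc; j++) vrec(irec, j) = S.v[record_comps[j]];
      irec++;
    }
  }

  return List::create(_["raster_cell"] = wrap(raster_cell),
                      _["raster_t"] = wrap(raster_t),
                      _["t"] = trec, _["v"] = vrec, _["fail_step"] = fail_step);
}
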