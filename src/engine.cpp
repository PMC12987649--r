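// Branched-cable conductance-based neuron engine.
//
// Semi-implicit backward-Euler scheme: gating variables advance by
// Rush-Larsen exact exponential steps (voltage-rate functions tabulated on a
// 0.05 mV grid), then the voltage system -- tridiagonal on the Hines-ordered
// tree -- is solved implicitly with channel conductances frozen over the
// step. Synapses use the two-state transmitter-pulse scheme; contributions
// of synapses whose pulse has ended decay by a common per-step factor and
// are therefore aggregated per compartment, while synapses inside their ON
// pulse are integrated individually.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double F_CONST = 96485.3329; // C/mol

// ---------------------------------------------------------------------------
// voltage-rate tables

struct GateTab {
  std::vector<double> inf, mul; // steady state and exp(-dt/tau) per grid point
};

static const double VMIN = -120.0, VMAX = 60.0, VSTEP = 0.05;
static const int NTAB = (int)((VMAX - VMIN) / VSTEP) + 1;

static inline double guard_div(double num, double den, double lim) {
  // num/den with a l'Hopital fallback as den -> 0
  if (std::fabs(den) < 1e-7) return lim;
  return num / den;
}

typedef void (*RateFn)(double v, double &inf, double &tau);

static const double QT = std::pow(2.3, 1.3); // 2.3^((34-21)/10)

static void rate_nat_m(double v, double &inf, double &tau) {
  double a = guard_div(0.182 * (v + 38.0), 1.0 - std::exp(-(v + 38.0) / 6.0), 0.182 * 6.0);
  double b = guard_div(-0.124 * (v + 38.0), 1.0 - std::exp((v + 38.0) / 6.0), 0.124 * 6.0);
  inf = a / (a + b);
  tau = 1.0 / (QT * (a + b));
}
static void rate_nat_h(double v, double &inf, double &tau) {
  double a = guard_div(-0.015 * (v + 66.0), 1.0 - std::exp((v + 66.0) / 6.0), 0.015 * 6.0);
  double b = guard_div(0.015 * (v + 66.0), 1.0 - std::exp(-(v + 66.0) / 6.0), 0.015 * 6.0);
  inf = a / (a + b);
  tau = 1.0 / (QT * (a + b));
}
static void rate_nap_m(double v, double &inf, double &tau) {
  double a = guard_div(0.182 * (v + 38.0), 1.0 - std::exp(-(v + 38.0) / 6.0), 0.182 * 6.0);
  double b = guard_div(-0.124 * (v + 38.0), 1.0 - std::exp((v + 38.0) / 6.0), 0.124 * 6.0);
  inf = 1.0 / (1.0 + std::exp(-(v + 52.6) / 4.6));
  tau = 6.0 / (QT * (a + b));
}
static void rate_nap_h(double v, double &inf, double &tau) {
  double a = guard_div(-2.88e-6 * (v + 17.0), 1.0 - std::exp((v + 17.0) / 4.63), 2.88e-6 * 4.63);
  double b = guard_div(6.94e-6 * (v + 64.4), 1.0 - std::exp(-(v + 64.4) / 2.63), 6.94e-6 * 2.63);
  inf = 1.0 / (1.0 + std::exp((v + 48.8) / 10.0));
  tau = 1.0 / (QT * (a + b));
}
static void rate_ih_m(double v, double &inf, double &tau) {
  double a = guard_div(0.001 * 6.43 * (v + 154.9), std::exp((v + 154.9) / 11.9) - 1.0, 0.001 * 6.43 * 11.9);
  double b = 0.001 * 193.0 * std::exp(v / 33.1);
  inf = a / (a + b);
  tau = 1.0 / (a + b);
}
static void rate_im_m(double v, double &inf, double &tau) {
  double a = 3.3e-3 * std::exp(0.1 * (v + 35.0));
  double b = 3.3e-3 * std::exp(-0.1 * (v + 35.0));
  inf = a / (a + b);
  tau = 1.0 / (QT * (a + b));
}
static void rate_kp_m(double v, double &inf, double &tau) {
  double vs = v + 10.0;
  inf = 1.0 / (1.0 + std::exp(-(vs + 1.0) / 12.0));
  if (vs < -50.0)
    tau = (1.25 + 175.03 * std::exp(vs * 0.026)) / QT;
  else
    tau = (1.25 + 13.0 * std::exp(-vs * 0.026)) / QT;
}
static void rate_kp_h(double v, double &inf, double &tau) {
  double vs = v + 10.0;
  inf = 1.0 / (1.0 + std::exp((vs + 54.0) / 11.0));
  double z = (vs + 75.0) / 48.0;
  tau = (360.0 + (1010.0 + 24.0 * (vs + 55.0)) * std::exp(-z * z)) / QT;
}
static void rate_kt_m(double v, double &inf, double &tau) {
  double vs = v + 10.0;
  inf = 1.0 / (1.0 + std::exp(-vs / 19.0));
  double z = (vs + 71.0) / 59.0;
  tau = (0.34 + 0.92 * std::exp(-z * z)) / QT;
}
static void rate_kt_h(double v, double &inf, double &tau) {
  double vs = v + 10.0;
  inf = 1.0 / (1.0 + std::exp((vs + 66.0) / 10.0));
  double z = (vs + 83.0) / 23.0;
  tau = (8.0 + 49.0 * std::exp(-z * z)) / QT;
}
static void rate_kv_m(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp((18.7 - v) / 9.7));
  tau = 4.0 / (1.0 + std::exp(-(v + 46.56) / 44.14));
}
static void rate_hva_m(double v, double &inf, double &tau) {
  double a = guard_div(0.055 * (-27.0 - v), std::exp((-27.0 - v) / 3.8) - 1.0, 0.055 * 3.8);
  double b = 0.94 * std::exp((-75.0 - v) / 17.0);
  inf = a / (a + b);
  tau = 1.0 / (a + b);
}
static void rate_hva_h(double v, double &inf, double &tau) {
  double a = 0.000457 * std::exp((-13.0 - v) / 50.0);
  double b = 0.0065 / (std::exp((-v - 15.0) / 28.0) + 1.0);
  inf = a / (a + b);
  tau = 1.0 / (a + b);
}
static void rate_lva_m(double v, double &inf, double &tau) {
  double vs = v + 10.0;
  inf = 1.0 / (1.0 + std::exp(-(vs + 30.0) / 6.0));
  tau = (5.0 + 20.0 / (1.0 + std::exp((vs + 25.0) / 5.0))) / QT;
}
static void rate_lva_h(double v, double &inf, double &tau) {
  double vs = v + 10.0;
  inf = 1.0 / (1.0 + std::exp((vs + 80.0) / 6.4));
  tau = (20.0 + 50.0 / (1.0 + std::exp((vs + 40.0) / 7.0))) / QT;
}

enum GateId { G_NAT_M, G_NAT_H, G_NAP_M, G_NAP_H, G_IH_M, G_IM_M,
              G_KP_M, G_KP_H, G_KT_M, G_KT_H, G_KV_M,
              G_HVA_M, G_HVA_H, G_LVA_M, G_LVA_H, N_GATES };

static void build_tables(std::vector<GateTab> &tabs, double dt) {
  RateFn fns[N_GATES] = { rate_nat_m, rate_nat_h, rate_nap_m, rate_nap_h,
                          rate_ih_m, rate_im_m, rate_kp_m, rate_kp_h,
                          rate_kt_m, rate_kt_h, rate_kv_m,
                          rate_hva_m, rate_hva_h, rate_lva_m, rate_lva_h };
  tabs.assign(N_GATES, GateTab());
  for (int g = 0; g < N_GATES; ++g) {
    tabs[g].inf.resize(NTAB);
    tabs[g].mul.resize(NTAB);
    for (int i = 0; i < NTAB; ++i) {
      double v = VMIN + i * VSTEP, inf, tau;
      fns[g](v, inf, tau);
      if (tau < 1e-4) tau = 1e-4;
      tabs[g].inf[i] = inf;
      tabs[g].mul[i] = std::exp(-dt / tau);
    }
  }
}

static inline void tab_lookup(const GateTab &t, double v, double &inf, double &mul) {
  double x = (v - VMIN) / VSTEP;
  if (x <= 0.0) { inf = t.inf[0]; mul = t.mul[0]; return; }
  if (x >= NTAB - 1) { inf = t.inf[NTAB - 1]; mul = t.mul[NTAB - 1]; return; }
  int i = (int)x;
  double f = x - i;
  inf = t.inf[i] * (1.0 - f) + t.inf[i + 1] * f;
  mul = t.mul[i] * (1.0 - f) + t.mul[i + 1] * f;
}

// channel density matrix columns (S/cm^2)
enum ChanId { C_NAT, C_NAP, C_IH, C_IM, C_KP, C_KT, C_KV,
              C_HVA, C_LVA, C_SK, N_CHAN };

// synapse kinds
enum SynKind { SYN_AMPA = 0, SYN_NMDA = 1, SYN_GABA = 2, N_KIND = 3 };

struct ActivePulse {
  int syn;       // synapse index
  double r;      // gating variable
  double c;      // conductance scale, uS (weight * gmax * D)
  int end_step;  // step at which the transmitter pulse ends
};

// [[Rcpp::export]]
List simulate_cpp(IntegerVector parent, NumericVector len_um,
                  NumericVector diam_um, NumericVector cm_uFcm2,
                  double ra_ohmcm, NumericVector gl_Scm2, double e_leak,
                  NumericMatrix chan_Scm2,
                  double e_na, double e_k, double e_h, double cao_mM,
                  NumericVector ca_gamma, NumericVector ca_decay_ms,
                  double ca_depth_um, double ca_min_mM,
                  IntegerVector syn_comp, IntegerVector syn_kind,
                  NumericVector kin_alpha, NumericVector kin_beta,
                  NumericVector kin_ton_ms, NumericVector kin_erev,
                  IntegerVector del_step, IntegerVector del_syn,
                  NumericVector del_c,
                  IntegerVector inj_comp, NumericVector inj_amp,
                  IntegerVector inj_on, IntegerVector inj_off,
                  NumericVector sine_amp, NumericVector sine_freq,
                  double dt, int n_steps, double v_init,
                  IntegerVector rec_comp, int rec_every,
                  bool rec_v, bool rec_gna, bool rec_inmda, bool rec_ica,
                  bool rec_cai) {
  const int n = parent.size();
  const int nsyn = syn_comp.size();
  const int nrec = rec_comp.size();

  // geometry-derived scalars
  std::vector<double> area(n), cap(n), gl(n), gax(n);
  for (int i = 0; i < n; ++i) {
    area[i] = M_PI * diam_um[i] * len_um[i];        // um^2
    cap[i] = cm_uFcm2[i] * area[i] * 1e-5;          // nF
    gl[i] = gl_Scm2[i] * area[i] * 1e-2;            // uS
  }
  // axial conductance to parent (uS): series of the two half-cylinders
  for (int i = 0; i < n; ++i) {
    int p = parent[i];
    if (p < 0) { gax[i] = 0.0; continue; }
    if (p >= i) stop("compartments must be ordered parent-before-child");
    double r_half_i = (ra_ohmcm / 100.0) * (len_um[i] / 2.0) /
                      (M_PI * diam_um[i] * diam_um[i] / 4.0); // MOhm
    double r_half_p = (ra_ohmcm / 100.0) * (len_um[p] / 2.0) /
                      (M_PI * diam_um[p] * diam_um[p] / 4.0);
    gax[i] = 1.0 / (r_half_i + r_half_p); // uS
  }

  std::vector<GateTab> tabs;
  build_tables(tabs, dt);

  // state
  std::vector<double> v(n, v_init);
  std::vector<std::vector<double> > gate(N_GATES, std::vector<double>(n));
  for (int g = 0; g < N_GATES; ++g)
    for (int i = 0; i < n; ++i) {
      double inf, mul;
      tab_lookup(tabs[g], v_init, inf, mul);
      gate[g][i] = inf;
    }
  std::vector<double> cai(n, ca_min_mM), zsk(n);
  for (int i = 0; i < n; ++i) {
    double ratio = std::pow(0.00043 / cai[i], 4.8);
    zsk[i] = 1.0 / (1.0 + ratio);
  }

  // synapse bookkeeping
  double e_decay[N_KIND], g_on[N_KIND], r_inf[N_KIND];
  int ton_steps[N_KIND];
  for (int k = 0; k < N_KIND; ++k) {
    e_decay[k] = std::exp(-kin_beta[k] * dt);
    g_on[k] = std::exp(-(kin_alpha[k] + kin_beta[k]) * dt);
    r_inf[k] = kin_alpha[k] / (kin_alpha[k] + kin_beta[k]);
    ton_steps[k] = std::max(1, (int)std::lround(kin_ton_ms[k] / dt));
  }
  // per-compartment aggregated OFF-phase conductance scale (sum c_i r_i)
  std::vector<std::vector<double> > agg(N_KIND, std::vector<double>(n, 0.0));
  // per-synapse lazy state: value and step of last fold into the aggregate
  std::vector<double> syn_r(nsyn, 0.0), syn_c(nsyn, 0.0);
  std::vector<int> syn_step(nsyn, 0), syn_active(nsyn, -1);
  std::vector<ActivePulse> active;
  active.reserve(1024);
  int del_ptr = 0;
  const int ndel = del_step.size();

  // recording buffers
  int n_samp = n_steps / rec_every;
  NumericMatrix out_v(rec_v ? n_samp : 0, rec_v ? nrec : 0);
  NumericMatrix out_gna(rec_gna ? n_samp : 0, rec_gna ? nrec : 0);
  NumericMatrix out_inmda(rec_inmda ? n_samp : 0, rec_inmda ? nrec : 0);
  NumericMatrix out_ica(rec_ica ? n_samp : 0, rec_ica ? nrec : 0);
  NumericMatrix out_cai(rec_cai ? n_samp : 0, rec_cai ? nrec : 0);
  std::vector<double> gna_hold(nrec, 0.0);
  std::vector<int> rec_of_comp(n, -1);
  for (int j = 0; j < nrec; ++j) rec_of_comp[rec_comp[j]] = j;

  // workspaces
  std::vector<double> diag(n), rhs(n);
  std::vector<double> gsyn_tot(N_KIND * n, 0.0);
  std::vector<double> ica_dens(n, 0.0);

  const double eca_fac = 1000.0 * 8.31446 * 307.15 / (2.0 * F_CONST); // mV
  const double sk_mul = std::exp(-dt); // SK gate, tau = 1 ms

  for (int s = 0; s < n_steps; ++s) {
    // --- synaptic deliveries arriving at this step
    while (del_ptr < ndel && del_step[del_ptr] <= s) {
      int j = del_syn[del_ptr];
      int k = syn_kind[j];
      double cnew = del_c[del_ptr];
      if (syn_active[j] >= 0) {
        ActivePulse &ap = active[syn_active[j]];
        ap.c = cnew;
        ap.end_step = s + ton_steps[k];
      } else {
        // extract this synapse's residual contribution from the aggregate
        double r_now = syn_r[j] * std::pow(e_decay[k], (double)(s - syn_step[j]));
        if (r_now > 1e-12) agg[k][syn_comp[j]] -= syn_c[j] * r_now;
        if (agg[k][syn_comp[j]] < 0.0) agg[k][syn_comp[j]] = 0.0;
        ActivePulse ap;
        ap.syn = j; ap.r = r_now; ap.c = cnew; ap.end_step = s + ton_steps[k];
        syn_active[j] = (int)active.size();
        active.push_back(ap);
      }
      ++del_ptr;
    }

    // --- synaptic conductances for this step
    for (int k = 0; k < N_KIND; ++k) {
      double ed = e_decay[k];
      double *a = &agg[k][0];
      double *gt = &gsyn_tot[k * n];
      for (int i = 0; i < n; ++i) {
        a[i] *= ed;
        gt[i] = a[i];
      }
    }
    for (size_t ai = 0; ai < active.size();) {
      ActivePulse &ap = active[ai];
      int k = syn_kind[ap.syn];
      ap.r = r_inf[k] + (ap.r - r_inf[k]) * g_on[k];
      gsyn_tot[k * n + syn_comp[ap.syn]] += ap.c * ap.r;
      if (s + 1 >= ap.end_step) {
        // pulse over: fold back into the aggregate
        agg[k][syn_comp[ap.syn]] += ap.c * ap.r;
        syn_r[ap.syn] = ap.r;
        syn_c[ap.syn] = ap.c;
        syn_step[ap.syn] = s + 1;
        syn_active[ap.syn] = -1;
        if (ai != active.size() - 1) {
          active[ai] = active.back();
          syn_active[active[ai].syn] = (int)ai;
        }
        active.pop_back();
      } else {
        ++ai;
      }
    }

    // --- gating update (Rush-Larsen) and membrane assembly
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double inf, mul;
      double gsum = gl[i], gesum = gl[i] * e_leak;
      double a_um2 = area[i] * 1e-2; // converts S/cm^2 to uS for this comp

      double g;
      // NaT
      if ((g = chan_Scm2(i, C_NAT)) > 0.0) {
        tab_lookup(tabs[G_NAT_M], vi, inf, mul);
        gate[G_NAT_M][i] = inf + (gate[G_NAT_M][i] - inf) * mul;
        tab_lookup(tabs[G_NAT_H], vi, inf, mul);
        gate[G_NAT_H][i] = inf + (gate[G_NAT_H][i] - inf) * mul;
        double m = gate[G_NAT_M][i], h = gate[G_NAT_H][i];
        double gc = g * m * m * m * h * a_um2;
        gsum += gc; gesum += gc * e_na;
      }
      // NaP
      if ((g = chan_Scm2(i, C_NAP)) > 0.0) {
        tab_lookup(tabs[G_NAP_M], vi, inf, mul);
        gate[G_NAP_M][i] = inf + (gate[G_NAP_M][i] - inf) * mul;
        tab_lookup(tabs[G_NAP_H], vi, inf, mul);
        gate[G_NAP_H][i] = inf + (gate[G_NAP_H][i] - inf) * mul;
        double m = gate[G_NAP_M][i], h = gate[G_NAP_H][i];
        double gc = g * m * m * m * h * a_um2;
        gsum += gc; gesum += gc * e_na;
      }
      // Ih
      if ((g = chan_Scm2(i, C_IH)) > 0.0) {
        tab_lookup(tabs[G_IH_M], vi, inf, mul);
        gate[G_IH_M][i] = inf + (gate[G_IH_M][i] - inf) * mul;
        double gc = g * gate[G_IH_M][i] * a_um2;
        gsum += gc; gesum += gc * e_h;
      }
      // Im
      if ((g = chan_Scm2(i, C_IM)) > 0.0) {
        tab_lookup(tabs[G_IM_M], vi, inf, mul);
        gate[G_IM_M][i] = inf + (gate[G_IM_M][i] - inf) * mul;
        double gc = g * gate[G_IM_M][i] * a_um2;
        gsum += gc; gesum += gc * e_k;
      }
      // K_Pst
      if ((g = chan_Scm2(i, C_KP)) > 0.0) {
        tab_lookup(tabs[G_KP_M], vi, inf, mul);
        gate[G_KP_M][i] = inf + (gate[G_KP_M][i] - inf) * mul;
        tab_lookup(tabs[G_KP_H], vi, inf, mul);
        gate[G_KP_H][i] = inf + (gate[G_KP_H][i] - inf) * mul;
        double m = gate[G_KP_M][i];
        double gc = g * m * m * gate[G_KP_H][i] * a_um2;
        gsum += gc; gesum += gc * e_k;
      }
      // K_Tst
      if ((g = chan_Scm2(i, C_KT)) > 0.0) {
        tab_lookup(tabs[G_KT_M], vi, inf, mul);
        gate[G_KT_M][i] = inf + (gate[G_KT_M][i] - inf) * mul;
        tab_lookup(tabs[G_KT_H], vi, inf, mul);
        gate[G_KT_H][i] = inf + (gate[G_KT_H][i] - inf) * mul;
        double m = gate[G_KT_M][i];
        double gc = g * m * m * m * m * gate[G_KT_H][i] * a_um2;
        gsum += gc; gesum += gc * e_k;
      }
      // SKv3.1
      if ((g = chan_Scm2(i, C_KV)) > 0.0) {
        tab_lookup(tabs[G_KV_M], vi, inf, mul);
        gate[G_KV_M][i] = inf + (gate[G_KV_M][i] - inf) * mul;
        double gc = g * gate[G_KV_M][i] * a_um2;
        gsum += gc; gesum += gc * e_k;
      }
      // Ca channels: explicit current (for the pool) + linearised membrane term
      double g_hva = chan_Scm2(i, C_HVA), g_lva = chan_Scm2(i, C_LVA);
      double ica_d = 0.0;
      if (g_hva > 0.0 || g_lva > 0.0) {
        double eca = eca_fac * std::log(cao_mM / cai[i]);
        double gca_dens = 0.0;
        if (g_hva > 0.0) {
          tab_lookup(tabs[G_HVA_M], vi, inf, mul);
          gate[G_HVA_M][i] = inf + (gate[G_HVA_M][i] - inf) * mul;
          tab_lookup(tabs[G_HVA_H], vi, inf, mul);
          gate[G_HVA_H][i] = inf + (gate[G_HVA_H][i] - inf) * mul;
          double m = gate[G_HVA_M][i];
          gca_dens += g_hva * m * m * gate[G_HVA_H][i];
        }
        if (g_lva > 0.0) {
          tab_lookup(tabs[G_LVA_M], vi, inf, mul);
          gate[G_LVA_M][i] = inf + (gate[G_LVA_M][i] - inf) * mul;
          tab_lookup(tabs[G_LVA_H], vi, inf, mul);
          gate[G_LVA_H][i] = inf + (gate[G_LVA_H][i] - inf) * mul;
          double m = gate[G_LVA_M][i];
          gca_dens += g_lva * m * m * gate[G_LVA_H][i];
        }
        double gc = gca_dens * a_um2;
        gsum += gc; gesum += gc * eca;
        ica_d = gca_dens * (vi - eca); // mA/cm^2 (pre-step voltage)
      }
      ica_dens[i] = ica_d;
      // SK (calcium gated)
      if ((g = chan_Scm2(i, C_SK)) > 0.0) {
        double zi = 1.0 / (1.0 + std::pow(0.00043 / cai[i], 4.8));
        zsk[i] = zi + (zsk[i] - zi) * sk_mul; // tau = 1 ms
        double gc = g * zsk[i] * a_um2;
        gsum += gc; gesum += gc * e_k;
      }
      // synaptic conductances
      double g_ampa = gsyn_tot[SYN_AMPA * n + i];
      double g_gaba = gsyn_tot[SYN_GABA * n + i];
      double g_nmda = gsyn_tot[SYN_NMDA * n + i];
      if (g_nmda > 0.0) g_nmda /= 1.0 + 0.33 * std::exp(-0.06 * vi);
      gsum += g_ampa + g_gaba + g_nmda;
      gesum += g_ampa * kin_erev[SYN_AMPA] + g_nmda * kin_erev[SYN_NMDA] +
               g_gaba * kin_erev[SYN_GABA];
      gsyn_tot[SYN_NMDA * n + i] = g_nmda; // store blocked value for recording

      diag[i] = cap[i] / dt + gsum;
      rhs[i] = cap[i] / dt * vi + gesum;
    }

    // current injections (square steps and sinusoids)
    for (int q = 0; q < inj_comp.size(); ++q) {
      if (s >= inj_on[q] && s < inj_off[q]) {
        double amp = inj_amp[q];
        if (sine_freq[q] > 0.0)
          amp += sine_amp[q] *
                 std::sin(2.0 * M_PI * sine_freq[q] * ((s - inj_on[q]) * dt) / 1000.0);
        rhs[inj_comp[q]] += amp;
      }
    }

    // axial terms
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      diag[i] += gax[i];
      diag[p] += gax[i];
    }
    // Hines elimination (children come after parents)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      diag[p] -= gax[i] * gax[i] / diag[i];
      rhs[p] += gax[i] * rhs[i] / diag[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + gax[i] * v[parent[i]]) / diag[i];

    // calcium pool
    for (int i = 0; i < n; ++i) {
      if (chan_Scm2(i, C_HVA) > 0.0 || chan_Scm2(i, C_LVA) > 0.0) {
        double drive = -10000.0 * ica_dens[i] * ca_gamma[i] /
                       (2.0 * F_CONST * ca_depth_um);
        cai[i] += dt * (drive - (cai[i] - ca_min_mM) / ca_decay_ms[i]);
        if (cai[i] < 1e-8) cai[i] = 1e-8;
      }
    }

    // peak-hold sodium conductance density between samples (mS/cm^2)
    if (rec_gna) {
      for (int j = 0; j < nrec; ++j) {
        int i = rec_comp[j];
        double m = gate[G_NAT_M][i];
        double gna = chan_Scm2(i, C_NAT) * m * m * m * gate[G_NAT_H][i] * 1000.0;
        if (gna > gna_hold[j]) gna_hold[j] = gna;
      }
    }

    if ((s + 1) % rec_every == 0) {
      int row = (s + 1) / rec_every - 1;
      for (int j = 0; j < nrec; ++j) {
        int i = rec_comp[j];
        if (rec_v) out_v(row, j) = v[i];
        if (rec_gna) { out_gna(row, j) = gna_hold[j]; gna_hold[j] = 0.0; }
        if (rec_inmda)
          out_inmda(row, j) = gsyn_tot[SYN_NMDA * n + i] *
                              (v[i] - kin_erev[SYN_NMDA]);
        if (rec_ica) out_ica(row, j) = ica_dens[i] * area[i] * 1e-2; // nA
        if (rec_cai) out_cai(row, j) = cai[i];
      }
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(v[i])) {
          stop("numerical failure at t = %f ms, compartment %d",
               s * dt, i + 1);
        }
      }
    }
  }

  return List::create(
    _["v"] = out_v, _["gna"] = out_gna, _["inmda"] = out_inmda,
    _["ica"] = out_ica, _["cai"] = out_cai,
    _["v_final"] = NumericVector(v.begin(), v.end()));
}

// [[Rcpp::export]]
NumericVector stp_train_cpp(NumericVector times, double tau1, double d1,
                            double tau2, double d2) {
  int n = times.size();
  NumericVector out(n);
  double D1 = 1.0, D2 = 1.0, tlast = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double dt = times[i] - tlast;
    double r1 = 1.0 - (1.0 - D1) * std::exp(-dt / tau1);
    double r2 = 1.0 - (1.0 - D2) * std::exp(-dt / tau2);
    double D = r1 * r2;
    out[i] = D > 1.0 ? 1.0 : D;
    D1 = r1 * d1;
    D2 = r2 * d2;
    tlast = times[i];
  }
  return out;
}
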