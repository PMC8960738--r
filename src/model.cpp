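// Pig atrial cardiomyocyte: 12-current Hodgkin-Huxley membrane model with
// Luo-Rudy/CRN sarcoplasmic-reticulum Ca2+ handling, plus a monodomain
// FTCS tissue stepper (1D cable / 2D sheet, no-flux boundaries).
//
// State vector layout (NVAR = 21):
//   0  V      mV
//   1  m      I_Na activation
//   2  h      I_Na fast inactivation
//   3  j      I_Na slow inactivation
//   4  d      I_CaL activation
//   5  f      I_CaL voltage inactivation
//   6  fca    I_CaL Ca-dependent inactivation
//   7  ua     I_Kur activation
//   8  uif    I_Kur fast inactivation
//   9  uis    I_Kur slow inactivation
//   10 xr     I_Kr activation
//   11 xs     I_Ks activation
//   12 qca    I_ClCa gate (driven by F_n)
//   13 u      I_rel activation
//   14 v      I_rel Fn-inactivation
//   15 w      I_rel voltage inactivation (pig: +40 mV shift, steeper)
//   16 nai    mM
//   17 ki     mM
//   18 cai    mM
//   19 caup   mM (network SR)
//   20 carel  mM (junctional SR)

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int NVAR = 21;

// physical constants (CRN conventions)
static const double RGAS = 8.3143;    // J mol^-1 K^-1
static const double FDAY = 96.4867;   // C mmol^-1
// cell geometry (CRN), volumes in um^3
static const double V_I   = 13668.0;
static const double V_UP  = 1109.52;
static const double V_REL = 96.48;
// buffers (CRN)
static const double CMDN_MAX = 0.05, TRPN_MAX = 0.07, CSQN_MAX = 10.0;
static const double KM_CMDN = 0.00238, KM_TRPN = 0.0005, KM_CSQN = 0.8;
// pumps / exchangers (CRN Michaelis constants)
static const double KM_NAI = 10.0, KM_KO = 1.5;
static const double KM_NA_NCX = 87.5, KM_CA_NCX = 1.38, KSAT_NCX = 0.1, GAMMA_NCX = 0.35;
static const double KM_PCA = 0.0005;

struct Params {
  // conductances nS/pF and maximal currents pA/pF
  double g_na, g_k1, g_kur_amp, g_clca, g_kr, g_ks, g_cal, g_bna, g_bca;
  double i_nak_max, i_pca_max, i_naca_max;
  // SR
  double i_up_max, k_up, ca_up_max, k_rel, tau_tr;
  // membrane / environment
  double cm, temp, na_o, k_o, ca_o, e_cl;
  // pig-specific kinetic parameters
  double tau_m_scale, tau_h_scale, tau_j_scale;
  double a_kur, b_kur, kur_slow_tau_factor;
  double xr_half, xr_slope, ikr_rect_half, ikr_rect_slope;
  double ik1_shift, ik1_slope, ik1_vhalf;
  double p1, p2;
  double d_shift;
  double w_half, w_slope;
  double fca_half, qca_half, tau_fca, tau_qca;
  bool dynamic_concentrations;
};

static double getp(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop("missing model parameter '%s'", nm);
  return as<double>(l[nm]);
}

static Params params_from_list(const List& l) {
  Params p;
  p.g_na = getp(l, "g_na"); p.g_k1 = getp(l, "g_k1");
  p.g_kur_amp = getp(l, "g_kur_amp"); p.g_clca = getp(l, "g_clca");
  p.g_kr = getp(l, "g_kr"); p.g_ks = getp(l, "g_ks"); p.g_cal = getp(l, "g_cal");
  p.g_bna = getp(l, "g_bna"); p.g_bca = getp(l, "g_bca");
  p.i_nak_max = getp(l, "i_nak_max"); p.i_pca_max = getp(l, "i_pca_max");
  p.i_naca_max = getp(l, "i_naca_max");
  p.i_up_max = getp(l, "i_up_max"); p.k_up = getp(l, "k_up");
  p.ca_up_max = getp(l, "ca_up_max"); p.k_rel = getp(l, "k_rel");
  p.tau_tr = getp(l, "tau_tr");
  p.cm = getp(l, "cm"); p.temp = getp(l, "temperature");
  p.na_o = getp(l, "na_o"); p.k_o = getp(l, "k_o"); p.ca_o = getp(l, "ca_o");
  p.e_cl = getp(l, "e_cl");
  p.tau_m_scale = getp(l, "tau_m_scale"); p.tau_h_scale = getp(l, "tau_h_scale");
  p.tau_j_scale = getp(l, "tau_j_scale");
  p.a_kur = getp(l, "a_kur"); p.b_kur = getp(l, "b_kur");
  p.kur_slow_tau_factor = getp(l, "kur_slow_tau_factor");
  p.xr_half = getp(l, "xr_half"); p.xr_slope = getp(l, "xr_slope");
  p.ikr_rect_half = getp(l, "ikr_rect_half"); p.ikr_rect_slope = getp(l, "ikr_rect_slope");
  p.ik1_shift = getp(l, "ik1_shift"); p.ik1_slope = getp(l, "ik1_slope");
  p.ik1_vhalf = getp(l, "ik1_vhalf");
  p.p1 = getp(l, "p1"); p.p2 = getp(l, "p2");
  p.d_shift = getp(l, "d_shift");
  p.w_half = getp(l, "w_half"); p.w_slope = getp(l, "w_slope");
  p.fca_half = getp(l, "fca_half"); p.qca_half = getp(l, "qca_half");
  p.tau_fca = getp(l, "tau_fca"); p.tau_qca = getp(l, "tau_qca");
  p.dynamic_concentrations = as<bool>(l["dynamic_concentrations"]);
  return p;
}

// guard for x/(1-exp(-x/s)) style removable singularities
static inline double safediv(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// voltage-dependent quantities, tabulated for the inner loops
enum {
  R_MINF, R_TAUM, R_HINF, R_TAUH, R_JINF, R_TAUJ,
  R_DINF, R_TAUD, R_FINF, R_TAUF,
  R_UAINF, R_TAUUA, R_UIINF, R_TAUUIF,
  R_XRINF, R_TAUXR, R_XSINF, R_TAUXS,
  R_WINF, R_TAUW,
  R_GKURV, R_IK1F, R_IKRF, R_FNAK, R_EXPG, R_EXPG1,
  NRATE
};

static void eval_vrates(double V, const Params& p, double* r) {
  // --- I_Na gates (Luo-Rudy rates via CRN), taus scaled for pig ---
  double am = safediv(0.32 * (V + 47.13), 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  r[R_MINF] = am / (am + bm);
  r[R_TAUM] = p.tau_m_scale / (am + bm);
  r[R_HINF] = ah / (ah + bh);
  r[R_TAUH] = p.tau_h_scale / (ah + bh);
  r[R_JINF] = aj / (aj + bj);
  r[R_TAUJ] = p.tau_j_scale / (aj + bj);

  // --- I_CaL: activation shifted +d_shift mV (pig), inactivation as CRN ---
  double Vd = V - p.d_shift;
  r[R_DINF] = 1.0 / (1.0 + std::exp(-(Vd + 10.0) / 8.0));
  {
    double x = Vd + 10.0;
    double e = std::exp(-x / 6.24);
    r[R_TAUD] = std::fabs(x) < 1e-6 ? 1.0 / (0.035 * 6.24 * 2.0)
                                    : (1.0 - e) / (0.035 * x * (1.0 + e));
  }
  r[R_FINF] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  r[R_TAUF] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);

  // --- I_Kur (CRN rates; Q10 factor 3) ---
  double aua = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double bua = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r[R_UAINF] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  r[R_TAUUA] = 1.0 / (3.0 * (aua + bua));
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  r[R_UIINF] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  r[R_TAUUIF] = 1.0 / (3.0 * (aui + bui));

  // --- I_Kr activation (pig steady state, CRN tau) ---
  r[R_XRINF] = 1.0 / (1.0 + std::exp(-(V - p.xr_half) / p.xr_slope));
  {
    double axr = safediv(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
    double bxr = safediv(7.3898e-5 * (V - 3.3328),
                         std::exp((V - 3.3328) / 5.1237) - 1.0, 7.3898e-5 * 5.1237);
    r[R_TAUXR] = 1.0 / (axr + bxr);
  }

  // --- I_Ks (CRN form with pig p1, p2) ---
  r[R_XSINF] = std::pow(1.0 / (1.0 + std::exp(-(V - p.p1) / p.p2)), 0.5);
  {
    double x = V - p.p1;
    double axs = safediv(4e-5 * x, 1.0 - std::exp(-x / 17.0), 4e-5 * 17.0);
    double bxs = safediv(3.5e-5 * x, std::exp(x / 9.0) - 1.0, 3.5e-5 * 9.0);
    r[R_TAUXS] = 0.5 / (axs + bxs);
  }

  // --- I_rel voltage inactivation w: pig +40 mV shift, steeper slope ---
  r[R_WINF] = 1.0 - 1.0 / (1.0 + std::exp(-(V - p.w_half) / p.w_slope));
  {
    double x = V - 7.9;
    double e = std::exp(-x / 5.0);
    r[R_TAUW] = std::fabs(x) < 1e-6 ? 6.0 / (5.0 * 1.3)
                                    : 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * x);
  }

  // --- voltage-dependent current factors ---
  r[R_GKURV] = p.g_kur_amp * (0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0)));
  r[R_IK1F]  = 1.0 / (1.0 + std::exp(p.ik1_slope * (V + p.ik1_vhalf)));
  r[R_IKRF]  = 1.0 / (1.0 + std::exp((V - p.ikr_rect_half) / p.ikr_rect_slope));
  // F in C/mmol equals J/(mV*mmol), so with V in mV, V*F/(R*T) is dimensionless
  double vfrt = V * FDAY / (RGAS * p.temp);
  double sigma = (std::exp(p.na_o / 67.3) - 1.0) / 7.0;
  r[R_FNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) + 0.0365 * sigma * std::exp(-vfrt));
  r[R_EXPG]  = std::exp(GAMMA_NCX * vfrt);
  r[R_EXPG1] = std::exp((GAMMA_NCX - 1.0) * vfrt);
}

// lookup table over V in [VT_MIN, VT_MAX]; the upper margin beyond the
// physiological band absorbs transient stimulus artifacts at electrodes
static const double VT_MIN = -150.0, VT_MAX = 400.0, VT_DV = 0.01;

struct RateTable {
  std::vector<double> tab; // n x NRATE, row-major per voltage index
  int n;
  void build(const Params& p) {
    n = (int)std::floor((VT_MAX - VT_MIN) / VT_DV) + 1;
    tab.resize((size_t)n * NRATE);
    double r[NRATE];
    for (int i = 0; i < n; i++) {
      eval_vrates(VT_MIN + i * VT_DV, p, r);
      std::memcpy(&tab[(size_t)i * NRATE], r, sizeof(r));
    }
  }
  inline void lookup(double V, double* r) const {
    double u = (V - VT_MIN) / VT_DV;
    int i = (int)u;
    if (i < 0 || i >= n - 1) stop("membrane potential %f mV outside [-150, 400]: numerical instability", V);
    double w = u - i;
    const double* a = &tab[(size_t)i * NRATE];
    const double* b = a + NRATE;
    for (int k = 0; k < NRATE; k++) r[k] = a[k] + w * (b[k] - a[k]);
  }
};

// currents + fluxes evaluated at one state
struct Currents {
  double ina, ik1, iclca, ikur, ikr, iks, ical, ipca, inak, inaca, ibna, ibca;
  double iion;
  double iup, irel, itr, iupleak;
  double fn;
  double e_na, e_k, e_ca;
};

static inline void compute_currents_r(const double* s, const Params& p,
                                      const double* r, Currents& c) {
  double V = s[0];
  double rt_f = RGAS * p.temp / FDAY; // mV
  c.e_na = rt_f * std::log(p.na_o / s[16]);
  c.e_k  = rt_f * std::log(p.k_o / s[17]);
  c.e_ca = rt_f / 2.0 * std::log(p.ca_o / s[18]);

  c.ina   = p.g_na * s[1] * s[1] * s[1] * s[2] * s[3] * (V - c.e_na);
  c.ik1   = p.g_k1 * (V - c.e_k - p.ik1_shift) * r[R_IK1F];
  c.iclca = p.g_clca * s[12] * (V - p.e_cl);
  c.ikur  = r[R_GKURV] * s[7] * s[7] * s[7] *
            (p.a_kur * s[8] + p.b_kur * s[9]) * (V - c.e_k);
  c.ikr   = p.g_kr * s[10] * (V - c.e_k) * r[R_IKRF];
  c.iks   = p.g_ks * s[11] * s[11] * (V - c.e_k);
  c.ical  = p.g_cal * s[4] * s[5] * s[6] * (V - 65.0);
  c.ipca  = p.i_pca_max * s[18] / (KM_PCA + s[18]);
  c.inak  = p.i_nak_max * r[R_FNAK] *
            (1.0 / (1.0 + std::pow(KM_NAI / s[16], 1.5))) *
            (p.k_o / (p.k_o + KM_KO));
  {
    double na_o3 = p.na_o * p.na_o * p.na_o;
    double nai3 = s[16] * s[16] * s[16];
    c.inaca = p.i_naca_max *
      (r[R_EXPG] * nai3 * p.ca_o - r[R_EXPG1] * na_o3 * s[18]) /
      ((KM_NA_NCX * KM_NA_NCX * KM_NA_NCX + na_o3) * (KM_CA_NCX + p.ca_o) *
       (1.0 + KSAT_NCX * r[R_EXPG1]));
  }
  c.ibna = p.g_bna * (V - c.e_na);
  c.ibca = p.g_bca * (V - c.e_ca);

  c.iion = c.ina + c.ik1 + c.iclca + c.ikur + c.ikr + c.iks +
           c.ical + c.ipca + c.inak + c.inaca + c.ibna + c.ibca;

  // SR fluxes (mM/ms)
  c.irel = p.k_rel * s[13] * s[13] * s[14] * s[15] * (s[20] - s[18]);
  c.iup  = p.i_up_max / (1.0 + p.k_up / s[18]);
  c.iupleak = p.i_up_max * s[19] / p.ca_up_max;
  c.itr  = (s[19] - s[20]) / p.tau_tr;

  // net Ca2+ flux into the myoplasm (CRN convention)
  c.fn = 1e-12 * V_REL * c.irel -
         (5e-13 / FDAY) * (0.5 * c.ical - 0.2 * c.inaca) * p.cm;
}

static inline void gate_step(double& g, double inf, double tau, double dt, bool rl) {
  if (rl) g = inf - (inf - g) * std::exp(-dt / tau);
  else {
    g += dt * (inf - g) / tau;
    // gates are probabilities; the projection also guards the Euler update
    // where tau < dt (only reachable at electrode-artifact voltages)
    if (g < 0.0) g = 0.0; else if (g > 1.0) g = 1.0;
  }
}

// advance the non-voltage state by dt and return dV/dt contribution -Iion/Cm.
// istim: stimulus density in pA/pF, positive = depolarizing.
static inline double step_cell_core(double* s, const Params& p, const double* r,
                                    double istim, double dt, bool rl,
                                    Currents* cout_) {
  Currents c;
  compute_currents_r(s, p, r, c);
  if (cout_) *cout_ = c;

  // HH gates from the voltage table
  gate_step(s[1], r[R_MINF], r[R_TAUM], dt, rl);
  gate_step(s[2], r[R_HINF], r[R_TAUH], dt, rl);
  gate_step(s[3], r[R_JINF], r[R_TAUJ], dt, rl);
  gate_step(s[4], r[R_DINF], r[R_TAUD], dt, rl);
  gate_step(s[5], r[R_FINF], r[R_TAUF], dt, rl);
  gate_step(s[7], r[R_UAINF], r[R_TAUUA], dt, rl);
  gate_step(s[8], r[R_UIINF], r[R_TAUUIF], dt, rl);
  gate_step(s[9], r[R_UIINF], r[R_TAUUIF] * p.kur_slow_tau_factor, dt, rl);
  gate_step(s[10], r[R_XRINF], r[R_TAUXR], dt, rl);
  gate_step(s[11], r[R_XSINF], r[R_TAUXS], dt, rl);
  gate_step(s[15], r[R_WINF], r[R_TAUW], dt, rl);

  // Ca-dependent gates
  double fca_inf = 1.0 / (1.0 + s[18] / p.fca_half);
  gate_step(s[6], fca_inf, p.tau_fca, dt, rl);
  double fq = c.fn / p.qca_half;
  double qca_inf = 1.0 - 1.0 / (1.0 + fq * fq * fq);
  if (c.fn <= 0) qca_inf = 0.0;
  gate_step(s[12], qca_inf, p.tau_qca, dt, rl);

  // SR release gates (Fn-dependent)
  double uinf = 1.0 / (1.0 + std::exp(-(c.fn - 3.4175e-13) / 13.67e-16));
  double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(c.fn - 6.835e-14) / 13.67e-16));
  double tauv = 1.91 + 2.09 / (1.0 + std::exp(-(c.fn - 3.4175e-13) / 13.67e-16));
  gate_step(s[13], uinf, 8.0, dt, rl);
  gate_step(s[14], vinf, tauv, dt, rl);

  if (p.dynamic_concentrations) {
    double cmf = p.cm / (FDAY * V_I);
    double dnai = (-3.0 * c.inak - 3.0 * c.inaca - c.ibna - c.ina) * cmf;
    // I_to is a Cl- current in the pig, so it does not enter the K+ balance
    double dki = (2.0 * c.inak - c.ik1 - c.ikur - c.ikr - c.iks) * cmf;
    double b1 = (2.0 * c.inaca - c.ipca - c.ical - c.ibca) * p.cm / (2.0 * FDAY * V_I) +
                (V_UP * (c.iupleak - c.iup) + c.irel * V_REL) / V_I;
    double kt = KM_TRPN + s[18], kc = KM_CMDN + s[18];
    double b2 = 1.0 + TRPN_MAX * KM_TRPN / (kt * kt) + CMDN_MAX * KM_CMDN / (kc * kc);
    double dcaup = c.iup - c.iupleak - c.itr * V_REL / V_UP;
    double kq = KM_CSQN + s[20];
    double dcarel = (c.itr - c.irel) / (1.0 + CSQN_MAX * KM_CSQN / (kq * kq));
    s[16] += dt * dnai;
    s[17] += dt * dki;
    s[18] += dt * b1 / b2;
    s[19] += dt * dcaup;
    s[20] += dt * dcarel;
    if (s[18] <= 0 || s[19] <= 0 || s[20] <= 0)
      stop("Ca2+ concentration became non-positive: numerical instability");
  }

  return istim - c.iion; // dV/dt in mV/ms; densities are already per pF
}

static void check_state(const double* s) {
  for (int k = 0; k < NVAR; k++)
    if (!std::isfinite(s[k])) stop("state variable %d became non-finite: numerical instability", k + 1);
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
NumericVector cpp_vrates(double V, List params) {
  Params p = params_from_list(params);
  double r[NRATE];
  eval_vrates(V, p, r);
  NumericVector out(NRATE);
  for (int k = 0; k < NRATE; k++) out[k] = r[k];
  out.attr("names") = CharacterVector::create(
    "m_inf", "tau_m", "h_inf", "tau_h", "j_inf", "tau_j",
    "d_inf", "tau_d", "f_inf", "tau_f",
    "ua_inf", "tau_ua", "ui_inf", "tau_uif",
    "xr_inf", "tau_xr", "xs_inf", "tau_xs",
    "w_inf", "tau_w",
    "g_kur_v", "ik1_factor", "ikr_rect", "f_nak", "exp_g", "exp_g1");
  return out;
}

static NumericVector currents_to_vec(const Currents& c) {
  NumericVector out = NumericVector::create(
    _["i_na"] = c.ina, _["i_k1"] = c.ik1, _["i_clca"] = c.iclca,
    _["i_kur"] = c.ikur, _["i_kr"] = c.ikr, _["i_ks"] = c.iks,
    _["i_cal"] = c.ical, _["i_pca"] = c.ipca, _["i_nak"] = c.inak,
    _["i_naca"] = c.inaca, _["i_bna"] = c.ibna, _["i_bca"] = c.ibca,
    _["i_ion"] = c.iion, _["i_up"] = c.iup, _["i_rel"] = c.irel,
    _["i_tr"] = c.itr, _["i_up_leak"] = c.iupleak, _["f_n"] = c.fn,
    _["e_na"] = c.e_na, _["e_k"] = c.e_k);
  out.push_back(c.e_ca, "e_ca");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_compute_currents(NumericVector state, List params) {
  if (state.size() != NVAR) stop("state must have %d elements", NVAR);
  Params p = params_from_list(params);
  double r[NRATE];
  eval_vrates(state[0], p, r);
  Currents c;
  compute_currents_r(REAL(state), p, r, c);
  return currents_to_vec(c);
}

// number of trace columns when currents are recorded
static const int NCUR = 18; // 12 currents + iion + iup + irel + itr + iupleak + fn

static void record_row(double* row, double t, const double* s, const Currents* c,
                       bool rec_cur) {
  row[0] = t; row[1] = s[0];
  int k = 2;
  if (rec_cur && c) {
    row[k++] = c->ina; row[k++] = c->ik1; row[k++] = c->iclca; row[k++] = c->ikur;
    row[k++] = c->ikr; row[k++] = c->iks; row[k++] = c->ical; row[k++] = c->ipca;
    row[k++] = c->inak; row[k++] = c->inaca; row[k++] = c->ibna; row[k++] = c->ibca;
    row[k++] = c->iion; row[k++] = c->iup; row[k++] = c->irel; row[k++] = c->itr;
    row[k++] = c->iupleak; row[k++] = c->fn;
  }
  row[k++] = s[18]; row[k++] = s[19]; row[k++] = s[20];
  row[k++] = s[16]; row[k++] = s[17]; row[k++] = s[12]; row[k++] = s[6];
}

// [[Rcpp::export]]
List cpp_simulate_cell(NumericVector state, List params, double duration,
                       NumericVector stim_starts, double stim_duration,
                       double stim_amplitude, double dt, double record_every,
                       bool record_currents, bool rush_larsen, double t0) {
  if (state.size() != NVAR) stop("state must have %d elements", NVAR);
  Params p = params_from_list(params);
  RateTable tab; tab.build(p);

  double s[NVAR];
  std::memcpy(s, REAL(state), sizeof(s));

  long nsteps = (long)std::llround(duration / dt);
  long rec_stride = std::max(1L, (long)std::llround(record_every / dt));
  long nrec = nsteps / rec_stride + 1;
  int ncol = 2 + (record_currents ? NCUR : 0) + 7;
  NumericMatrix trace(nrec, ncol);

  double r[NRATE];
  Currents c;
  long irow = 0;
  std::vector<double> row(ncol);

  for (long i = 0; i <= nsteps; i++) {
    double t = t0 + i * dt;
    double istim = 0.0;
    for (int q = 0; q < stim_starts.size(); q++) {
      double st = stim_starts[q];
      if (t >= st && t < st + stim_duration) { istim = stim_amplitude; break; }
    }
    tab.lookup(s[0], r);
    if (i % rec_stride == 0) { // record the pre-step state
      compute_currents_r(s, p, r, c);
      record_row(row.data(), t, s, &c, record_currents);
      for (int k2 = 0; k2 < ncol; k2++) trace(irow, k2) = row[k2];
      irow++;
    }
    if (i == nsteps) break;
    double dv = step_cell_core(s, p, r, istim, dt, rush_larsen, nullptr);
    s[0] += dt * dv;
    if ((i & 1023) == 0) check_state(s);
  }
  check_state(s);

  NumericVector fs(NVAR);
  std::memcpy(REAL(fs), s, sizeof(s));
  fs.attr("names") = state.attr("names");
  return List::create(_["trace"] = trace(Range(0, irow - 1), Range(0, ncol - 1)),
                      _["final_state"] = fs);
}

// Voltage clamp: V is held on a schedule; gates/concentrations evolve freely.
// cai_clamp: if >= 0, [Ca]i is pinned at that value (Fig 3C style protocol).
// [[Rcpp::export]]
List cpp_voltage_clamp(NumericVector state, List params, double hold_potential,
                       double test_potential, double pre_duration,
                       double step_duration, double dt, double record_every,
                       double cai_clamp, bool rush_larsen) {
  if (state.size() != NVAR) stop("state must have %d elements", NVAR);
  Params p = params_from_list(params);
  RateTable tab; tab.build(p);

  double s[NVAR];
  std::memcpy(s, REAL(state), sizeof(s));
  if (cai_clamp >= 0) s[18] = cai_clamp;

  long npre = (long)std::llround(pre_duration / dt);
  long nstep = (long)std::llround(step_duration / dt);
  long rec_stride = std::max(1L, (long)std::llround(record_every / dt));
  long nrec = nstep / rec_stride + 1;
  NumericMatrix trace(nrec, 2 + NCUR + 7);
  std::vector<double> row(2 + NCUR + 7);

  double r[NRATE];
  Currents c;
  s[0] = hold_potential;
  for (long i = 0; i < npre; i++) {
    tab.lookup(s[0], r);
    step_cell_core(s, p, r, 0.0, dt, rush_larsen, nullptr);
    s[0] = hold_potential;            // clamped
    if (cai_clamp >= 0) s[18] = cai_clamp;
  }
  long irow = 0;
  s[0] = test_potential;
  for (long i = 0; i <= nstep; i++) {
    tab.lookup(s[0], r);
    if (i % rec_stride == 0) {
      compute_currents_r(s, p, r, c);
      record_row(row.data(), i * dt, s, &c, true);
      for (size_t k2 = 0; k2 < row.size(); k2++) trace(irow, k2) = row[k2];
      irow++;
    }
    if (i == nstep) break;
    step_cell_core(s, p, r, 0.0, dt, rush_larsen, nullptr);
    s[0] = test_potential;            // clamped
    if (cai_clamp >= 0) s[18] = cai_clamp;
  }

  NumericVector fs(NVAR);
  std::memcpy(REAL(fs), s, sizeof(s));
  fs.attr("names") = state.attr("names");
  return List::create(_["trace"] = trace(Range(0, irow - 1), Range(0, trace.ncol() - 1)),
                      _["final_state"] = fs);
}

// ------------------------------------------------------------------ tissue

// states: NVAR x ncell matrix (column per cell), nx*ny cells, column-major
// grid index: cell(ix, iy) = column ix + nx*iy
// [[Rcpp::export]]
List cpp_simulate_tissue(NumericMatrix states, List params, int nx, int ny,
                         double dx, double D, List stimuli, double duration,
                         double dt, double snapshot_every, double v_lag,
                         IntegerVector probes, double probe_every,
                         bool rush_larsen, double t0) {
  if (states.nrow() != NVAR) stop("states must have %d rows", NVAR);
  int ncell = nx * ny;
  if (states.ncol() != ncell) stop("states must have nx*ny columns");
  double mu = D * dt / (dx * dx);
  if (mu > 0.25) stop("FTCS stability bound violated: D*dt/dx^2 = %f > 0.25", mu);

  // homogeneous tissue: one parameter set for all cells
  Params p = params_from_list(params);
  RateTable tab; tab.build(p);

  std::vector<double> S((size_t)NVAR * ncell);
  std::memcpy(S.data(), REAL(states), sizeof(double) * NVAR * ncell);

  // stimulus regions
  int nstim = stimuli.size();
  std::vector<std::vector<int>> stim_idx(nstim);
  std::vector<double> stim_amp(nstim), stim_start(nstim), stim_end(nstim);
  for (int q = 0; q < nstim; q++) {
    List st = stimuli[q];
    IntegerVector idx = st["idx"]; // 0-based cell indices
    stim_idx[q] = std::vector<int>(idx.begin(), idx.end());
    stim_amp[q] = as<double>(st["amplitude"]);
    stim_start[q] = as<double>(st["start"]);
    stim_end[q] = stim_start[q] + as<double>(st["duration"]);
  }

  long nsteps = (long)std::llround(duration / dt);
  long snap_stride = snapshot_every > 0 ? std::max(1L, (long)std::llround(snapshot_every / dt)) : 0;
  long probe_stride = probes.size() > 0 ? std::max(1L, (long)std::llround(probe_every / dt)) : 0;
  int lag_steps = v_lag > 0 ? (int)std::llround(v_lag / dt) : 0;

  // ring buffer of V for the lagged field used in phase embedding
  std::vector<std::vector<double>> vring;
  int ring_n = lag_steps + 1, ring_pos = 0;
  if (snap_stride > 0 && lag_steps > 0)
    vring.assign(ring_n, std::vector<double>(ncell));

  List snaps, snaps_lag;
  std::vector<double> snap_times;
  long nprobe_rec = probe_stride > 0 ? nsteps / probe_stride + 1 : 0;
  NumericMatrix probe_v(nprobe_rec > 0 ? nprobe_rec : 1,
                        probes.size() > 0 ? (int)probes.size() : 1);
  std::vector<double> probe_times;

  std::vector<double> istim(ncell), dvdiff(ncell), dvion(ncell);
  double r[NRATE];
  long probe_row = 0;

  for (long i = 0; i <= nsteps; i++) {
    double t = t0 + i * dt;
    double* Vcur = nullptr;
    if (!vring.empty()) {
      Vcur = vring[ring_pos].data();
      for (int cidx = 0; cidx < ncell; cidx++) Vcur[cidx] = S[(size_t)cidx * NVAR];
    }
    // snapshots
    if (snap_stride > 0 && (i % snap_stride == 0)) {
      NumericVector vf(ncell), vl(ncell);
      for (int cidx = 0; cidx < ncell; cidx++) vf[cidx] = S[(size_t)cidx * NVAR];
      if (!vring.empty() && i >= lag_steps) {
        int back = (ring_pos + 1) % ring_n; // oldest entry = t - lag
        const double* Vold = vring[back].data();
        for (int cidx = 0; cidx < ncell; cidx++) vl[cidx] = Vold[cidx];
      } else {
        for (int cidx = 0; cidx < ncell; cidx++) vl[cidx] = vf[cidx];
      }
      snaps.push_back(vf);
      snaps_lag.push_back(vl);
      snap_times.push_back(t);
    }
    if (probe_stride > 0 && (i % probe_stride == 0)) {
      for (int q = 0; q < probes.size(); q++)
        probe_v(probe_row, q) = S[(size_t)probes[q] * NVAR];
      probe_times.push_back(t);
      probe_row++;
    }
    if (i == nsteps) break;
    if (!vring.empty()) ring_pos = (ring_pos + 1) % ring_n;

    // stimulus field
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int q = 0; q < nstim; q++)
      if (t >= stim_start[q] && t < stim_end[q])
        for (int cidx : stim_idx[q]) istim[cidx] += stim_amp[q];

    // diffusion (5-point Laplacian, no-flux via mirrored neighbours)
    for (int iy = 0; iy < ny; iy++) {
      for (int ix = 0; ix < nx; ix++) {
        int cidx = ix + nx * iy;
        double vc = S[(size_t)cidx * NVAR];
        double vw = S[(size_t)(ix > 0 ? cidx - 1 : cidx + 1) * NVAR];
        double ve = S[(size_t)(ix < nx - 1 ? cidx + 1 : cidx - 1) * NVAR];
        double lap = vw + ve - 2.0 * vc;
        if (ny > 1) {
          double vs = S[(size_t)(iy > 0 ? cidx - nx : cidx + nx) * NVAR];
          double vn = S[(size_t)(iy < ny - 1 ? cidx + nx : cidx - nx) * NVAR];
          lap += vs + vn - 2.0 * vc;
        }
        dvdiff[cidx] = D * lap / (dx * dx);
      }
    }
    // reaction
    for (int cidx = 0; cidx < ncell; cidx++) {
      double* sc = &S[(size_t)cidx * NVAR];
      tab.lookup(sc[0], r);
      dvion[cidx] = step_cell_core(sc, p, r, istim[cidx], dt, rush_larsen, nullptr);
    }
    for (int cidx = 0; cidx < ncell; cidx++)
      S[(size_t)cidx * NVAR] += dt * (dvion[cidx] + dvdiff[cidx]);

    if ((i & 255) == 0) {
      for (int cidx = 0; cidx < ncell; cidx += std::max(1, ncell / 64))
        if (!std::isfinite(S[(size_t)cidx * NVAR]))
          stop("tissue voltage became non-finite at t = %f ms", t);
    }
    if ((i & 8191) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_states(NVAR, ncell);
  std::memcpy(REAL(out_states), S.data(), sizeof(double) * NVAR * ncell);

  return List::create(
    _["snap_times"] = wrap(snap_times),
    _["snapshots"] = snaps,
    _["snapshots_lag"] = snaps_lag,
    _["probe_times"] = wrap(probe_times),
    _["probe_v"] = probe_v,
    _["states"] = out_states,
    _["time_end"] = t0 + duration);
}
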