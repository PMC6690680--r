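// ten Tusscher–Panfilov 2006 (epicardial) human ventricular myocyte model
// with an acute-ischemia overlay (I_K(ATP), hyperkalemia, I_Na/I_CaL
// inhibition), a fast fixed/dual-step single-cell pacer and a 1D
// monodomain cable stepper (operator splitting, Rush–Larsen gates).
//
// Two evaluation paths share the same current formulas:
//  * an exact path (direct exp/log evaluation) exposed to R for oracle
//    tests and for the deSolve/lsoda reference integrator;
//  * a tabulated path (voltage-dependent coefficients pre-computed on a
//    0.05 mV grid, linearly interpolated) used by the production steppers.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 19;
// state layout
enum { iV = 0, iKi, iNai, iCai, iCaSS, iCaSR,
       im, ih, ij, ixr1, ixr2, ixs, ir, is_, id_, if_, if2_, ifcass, irbar };

// physical constants
static const double Rgas = 8314.472;   // mJ/(mol K)
static const double Frdy = 96485.3415; // C/mol
static const double Temp = 310.0;      // K
static const double RTONF = Rgas * Temp / Frdy; // mV

// cell geometry / buffering
static const double Cm   = 0.185;
static const double Vc   = 0.016404;
static const double Vsr  = 0.001094;
static const double Vss  = 0.00005468;
static const double Bufc = 0.2,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;

// external concentrations (Ko is run-time, ischemia-dependent)
static const double Nao = 140.0, Cao = 2.0;
static const double Ko_n = 5.4; // control extracellular potassium, mM

// baseline maximal conductances / peak currents (epicardial TP06)
static const double GNa_b  = 14.838;
static const double GCaL_b = 0.0000398;
static const double GKr_b  = 0.153;
static const double GKs_b  = 0.392;
static const double GK1_b  = 5.405;
static const double Gto_b  = 0.294;
static const double GpK_b  = 0.0146;
static const double GpCa_b = 0.1238;
static const double GbNa_b = 0.00029;
static const double GbCa_b = 0.000592;
static const double PNaK_b = 2.724;
static const double kNaCa_b = 1000.0;

// fixed kinetic parameters
static const double pKNa = 0.03;
static const double KmK = 1.0, KmNa = 40.0;
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, alp = 2.5;
static const double KpCa = 0.0005;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;

static const double GkATP = 0.064; // mS/uF, ATP-sensitive K channel conductance

static const int NGATE = 11; // voltage-dependent HH gates (fCass handled apart)
// gate order: m h j xr1 xr2 xs r s d f f2
static const int GIDX[NGATE] = { im, ih, ij, ixr1, ixr2, ixs, ir, is_, id_, if_, if2_ };

static void gate_rates(double V, double* inf, double* tau) {
  // m
  inf[0] = 1.0 / ((1.0 + exp((-56.86 - V) / 9.03)) * (1.0 + exp((-56.86 - V) / 9.03)));
  {
    double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) + 0.1 / (1.0 + exp((V - 50.0) / 200.0));
    tau[0] = am * bm;
  }
  // h
  inf[1] = 1.0 / ((1.0 + exp((V + 71.55) / 7.43)) * (1.0 + exp((V + 71.55) / 7.43)));
  if (V >= -40.0) {
    double bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
    tau[1] = 1.0 / bh;
  } else {
    double ah = 0.057 * exp(-(V + 80.0) / 6.8);
    double bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
    tau[1] = 1.0 / (ah + bh);
  }
  // j
  inf[2] = inf[1];
  if (V >= -40.0) {
    double bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    tau[2] = 1.0 / bj;
  } else {
    double aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
                (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    double bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    tau[2] = 1.0 / (aj + bj);
  }
  // xr1
  inf[3] = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  {
    double a = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    double b = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    tau[3] = a * b;
  }
  // xr2
  inf[4] = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  {
    double a = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    double b = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
    tau[4] = a * b;
  }
  // xs
  inf[5] = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  {
    double a = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
    double b = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
    tau[5] = a * b + 80.0;
  }
  // r
  inf[6] = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau[6] = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  // s (epicardial)
  inf[7] = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  tau[7] = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
           5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  // d
  inf[8] = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  {
    double a = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    double b = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    double g = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    tau[8] = a * b + g;
  }
  // f
  inf[9] = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  tau[9] = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0) +
           200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
           180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  // f2
  inf[10] = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  tau[10] = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0) +
            31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
            80.0 / (1.0 + exp((V + 30.0) / 10.0));
}

// voltage-dependent current coefficients (everything that depends on V only)
struct VCoef {
  double ical_coef; // 4 (V-15) F^2/(RT) / (exp(2(V-15)F/RT) - 1)
  double ical_e1;   // exp(2 (V-15) F / RT)
  double naca_e1;   // exp(gam V F/RT)
  double naca_e2;   // exp((gam-1) V F/RT)
  double nak_rec;   // 1/(1 + 0.1245 exp(-0.1 VF/RT) + 0.0353 exp(-VF/RT))
  double pk_rec;    // 1/(1 + exp((25-V)/5.98))
};

static void vcoef_exact(double V, VCoef& c) {
  double z = 2.0 * (V - 15.0) / RTONF;
  c.ical_e1 = exp(z);
  if (fabs(z) < 1e-7) {
    // limit of z/(e^z - 1) -> 1
    c.ical_coef = 2.0 * Frdy / (1.0 + 0.5 * z);
  } else {
    c.ical_coef = 4.0 * (V - 15.0) * Frdy / RTONF / (c.ical_e1 - 1.0);
  }
  c.naca_e1 = exp(gam * V / RTONF);
  c.naca_e2 = exp((gam - 1.0) * V / RTONF);
  c.nak_rec = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTONF) + 0.0353 * exp(-V / RTONF));
  c.pk_rec = 1.0 / (1.0 + exp((25.0 - V) / 5.98));
}

// inward-rectifier gating factor as a function of u = V - Ek
static double xk1_inf(double u) {
  double a = 0.1 / (1.0 + exp(0.06 * (u - 200.0)));
  double b = (3.0 * exp(0.0002 * (u + 100.0)) + exp(0.1 * (u - 10.0))) /
             (1.0 + exp(-0.5 * u));
  return a / (a + b);
}

struct Currents {
  double ina, ical, ito, ikr, iks, ik1, inaca, inak, ipca, ipk, ibna, ibca, ikatp;
  double itot;
};

// scale vector order (multipliers on baseline values):
// 0 g_na 1 g_cal 2 g_kr 3 g_ks 4 g_k1 5 g_to 6 g_pk 7 g_pca 8 g_bna 9 g_bca
// 10 p_nak 11 k_naca
static inline void compute_currents(const double* s, const VCoef& vc, double xk1,
                                    double ek, double ena, double eks, double eca,
                                    const double* sc, double f_katp, double f_inhib,
                                    double ko, double katp_fac, double sqrt_ko,
                                    Currents& I) {
  double V = s[iV];
  I.ina = f_inhib * sc[0] * GNa_b * s[im] * s[im] * s[im] * s[ih] * s[ij] * (V - ena);
  I.ical = f_inhib * sc[1] * GCaL_b * s[id_] * s[if_] * s[if2_] * s[ifcass] *
           vc.ical_coef * (0.25 * s[iCaSS] * vc.ical_e1 - Cao);
  I.ito = sc[5] * Gto_b * s[ir] * s[is_] * (V - ek);
  I.ikr = sc[2] * GKr_b * sqrt_ko * s[ixr1] * s[ixr2] * (V - ek);
  I.iks = sc[3] * GKs_b * s[ixs] * s[ixs] * (V - eks);
  I.ik1 = sc[4] * GK1_b * sqrt_ko * xk1 * (V - ek);
  I.inaca = sc[11] * kNaCa_b *
            (vc.naca_e1 * s[iNai] * s[iNai] * s[iNai] * Cao -
             vc.naca_e2 * Nao * Nao * Nao * s[iCai] * alp) /
            ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
             (1.0 + ksat * vc.naca_e2));
  I.inak = sc[10] * PNaK_b * ko / (ko + KmK) * s[iNai] / (s[iNai] + KmNa) * vc.nak_rec;
  I.ipca = sc[7] * GpCa_b * s[iCai] / (KpCa + s[iCai]);
  I.ipk = sc[6] * GpK_b * vc.pk_rec * (V - ek);
  I.ibna = sc[8] * GbNa_b * (V - ena);
  I.ibca = sc[9] * GbCa_b * (V - eca);
  I.ikatp = katp_fac * (V - ek); // f_kATP * GkATP * (Ko/Ko_n)^0.24 * (V - Ek)
  I.itot = I.ina + I.ical + I.ito + I.ikr + I.iks + I.ik1 + I.inaca + I.inak +
           I.ipca + I.ipk + I.ibna + I.ibca + I.ikatp;
}

// calcium subsystem + concentration derivatives (shared by both paths)
static inline void conc_derivs(const double* s, const Currents& I, double istim,
                               double* dKi, double* dNai, double* dCai,
                               double* dCaSS, double* dCaSR, double* dRbar,
                               double* IrelOut) {
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / s[iCaSR]) * (EC / s[iCaSR]));
  double k1 = k1p / kCaSR;
  double k2 = k2p * kCaSR;
  *dRbar = k4 * (1.0 - s[irbar]) - k2 * s[iCaSS] * s[irbar];
  double OO = k1 * s[iCaSS] * s[iCaSS] * s[irbar] / (k3 + k1 * s[iCaSS] * s[iCaSS]);
  double Irel = Vrel * OO * (s[iCaSR] - s[iCaSS]);
  double Ileak = Vleak * (s[iCaSR] - s[iCai]);
  double Iup = Vmaxup / (1.0 + Kup * Kup / (s[iCai] * s[iCai]));
  double Ixfer = Vxfer * (s[iCaSS] - s[iCai]);
  double bufc = 1.0 / (1.0 + Bufc * Kbufc / ((s[iCai] + Kbufc) * (s[iCai] + Kbufc)));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((s[iCaSR] + Kbufsr) * (s[iCaSR] + Kbufsr)));
  double bufss = 1.0 / (1.0 + Bufss * Kbufss / ((s[iCaSS] + Kbufss) * (s[iCaSS] + Kbufss)));
  *dCai = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                  (I.ibca + I.ipca - 2.0 * I.inaca) * Cm / (2.0 * Vc * Frdy));
  *dCaSR = bufsr * (Iup - Ileak - Irel);
  *dCaSS = bufss * (-I.ical * Cm / (2.0 * Vss * Frdy) + Irel * Vsr / Vss -
                    Ixfer * Vc / Vss);
  *dNai = -(I.ina + I.ibna + 3.0 * I.inak + 3.0 * I.inaca) * Cm / (Vc * Frdy);
  // stimulus charge and I_K(ATP) are carried by potassium
  *dKi = -(istim + I.ik1 + I.ito + I.ikr + I.iks - 2.0 * I.inak + I.ipk + I.ikatp) *
         Cm / (Vc * Frdy);
  *IrelOut = Irel;
}

static inline void fcass_rates(double cass, double* inf, double* tau) {
  double q = cass / 0.05;
  *inf = 0.6 / (1.0 + q * q) + 0.4;
  *tau = 80.0 / (1.0 + q * q) + 2.0;
}

// ---------------------------------------------------------------------------
// exact full derivative (oracle / deSolve reference path)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".tp06_derivs_cpp")]]
List tp06_derivs_cpp(NumericVector state, NumericVector scale,
                     double f_katp, double f_inhib, double ko, double istim) {
  if (state.size() != NSTATE) stop("state must have length %d", NSTATE);
  if (scale.size() != 12) stop("scale must have length 12");
  if (ko <= 0) stop("extracellular potassium must be positive");
  double s[NSTATE];
  for (int i = 0; i < NSTATE; ++i) {
    s[i] = state[i];
    if (!std::isfinite(s[i])) stop("non-finite state entry at index %d", i + 1);
  }
  double sc[12];
  for (int i = 0; i < 12; ++i) sc[i] = scale[i];

  double ek = RTONF * log(ko / s[iKi]);
  double ena = RTONF * log(Nao / s[iNai]);
  double eks = RTONF * log((ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  double eca = 0.5 * RTONF * log(Cao / s[iCai]);
  VCoef vc;
  vcoef_exact(s[iV], vc);
  double xk1 = xk1_inf(s[iV] - ek);
  double katp_fac = f_katp * GkATP * pow(ko / Ko_n, 0.24);
  double sqrt_ko = sqrt(ko / 5.4);
  Currents I;
  compute_currents(s, vc, xk1, ek, ena, eks, eca, sc, f_katp, f_inhib, ko,
                   katp_fac, sqrt_ko, I);

  double inf[NGATE], tau[NGATE];
  gate_rates(s[iV], inf, tau);
  double fcinf, fctau;
  fcass_rates(s[iCaSS], &fcinf, &fctau);

  NumericVector d(NSTATE);
  d[iV] = -(I.itot + istim);
  double dKi, dNai, dCai, dCaSS, dCaSR, dRbar, Irel;
  conc_derivs(s, I, istim, &dKi, &dNai, &dCai, &dCaSS, &dCaSR, &dRbar, &Irel);
  d[iKi] = dKi; d[iNai] = dNai; d[iCai] = dCai; d[iCaSS] = dCaSS;
  d[iCaSR] = dCaSR; d[irbar] = dRbar;
  for (int g = 0; g < NGATE; ++g) d[GIDX[g]] = (inf[g] - s[GIDX[g]]) / tau[g];
  d[ifcass] = (fcinf - s[ifcass]) / fctau;

  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(d[i]))
      stop("non-finite derivative (index %d) at V = %g mV", i + 1, s[iV]);

  NumericVector cur = NumericVector::create(
      _["i_na"] = I.ina, _["i_cal"] = I.ical, _["i_to"] = I.ito,
      _["i_kr"] = I.ikr, _["i_ks"] = I.iks, _["i_k1"] = I.ik1,
      _["i_naca"] = I.inaca, _["i_nak"] = I.inak, _["i_pca"] = I.ipca,
      _["i_pk"] = I.ipk, _["i_bna"] = I.ibna, _["i_bca"] = I.ibca,
      _["i_katp"] = I.ikatp, _["i_total"] = I.itot,
      _["e_k"] = ek, _["e_na"] = ena, _["e_ks"] = eks, _["e_ca"] = eca);
  return List::create(_["dstate"] = d, _["currents"] = cur);
}

// [[Rcpp::export(name = ".tp06_initial_state_cpp")]]
NumericVector tp06_initial_state_cpp() {
  NumericVector s(NSTATE);
  s[iV] = -86.2; s[iKi] = 138.3; s[iNai] = 7.67;
  s[iCai] = 0.00007; s[iCaSS] = 0.00007; s[iCaSR] = 1.3;
  s[im] = 0.0; s[ih] = 0.75; s[ij] = 0.75;
  s[ixr1] = 0.0; s[ixr2] = 1.0; s[ixs] = 0.0;
  s[ir] = 0.0; s[is_] = 1.0; s[id_] = 0.0;
  s[if_] = 1.0; s[if2_] = 1.0; s[ifcass] = 1.0; s[irbar] = 1.0;
  s.attr("names") = CharacterVector::create(
      "v", "k_i", "na_i", "ca_i", "ca_ss", "ca_sr", "m", "h", "j", "xr1",
      "xr2", "xs", "r", "s", "d", "f", "f2", "fcass", "rbar");
  return s;
}

// ---------------------------------------------------------------------------
// tabulated fast path
// ---------------------------------------------------------------------------

struct Tables {
  double vmin, dv, inv_dv; int n;
  // row layout per V sample: inf[11], rlf[11], rls[11], ical_coef, ical_e1,
  // naca_e1, naca_e2, nak_rec, pk_rec  -> 39 doubles
  std::vector<double> t;
  double umin, du, inv_du; int nu;
  std::vector<double> k1; // xk1_inf over u = V - Ek
  double dt_fast, dt_slow;
};
static const int TROW = 39;

static void build_tables(Tables& T, double dt_fast, double dt_slow) {
  T.vmin = -150.0; T.dv = 0.05; T.inv_dv = 1.0 / T.dv;
  T.n = (int)((150.0 - T.vmin) * T.inv_dv) + 2;
  T.t.resize((size_t)T.n * TROW);
  T.dt_fast = dt_fast; T.dt_slow = dt_slow;
  double inf[NGATE], tau[NGATE];
  for (int i = 0; i < T.n; ++i) {
    double V = T.vmin + i * T.dv;
    double* row = &T.t[(size_t)i * TROW];
    gate_rates(V, inf, tau);
    for (int g = 0; g < NGATE; ++g) {
      row[g] = inf[g];
      row[NGATE + g] = exp(-dt_fast / tau[g]);
      row[2 * NGATE + g] = exp(-dt_slow / tau[g]);
    }
    VCoef vc;
    vcoef_exact(V, vc);
    row[33] = vc.ical_coef; row[34] = vc.ical_e1;
    row[35] = vc.naca_e1;   row[36] = vc.naca_e2;
    row[37] = vc.nak_rec;   row[38] = vc.pk_rec;
  }
  T.umin = -150.0; T.du = 0.05; T.inv_du = 1.0 / T.du;
  T.nu = (int)((300.0 - T.umin) * T.inv_du) + 2;
  T.k1.resize(T.nu);
  for (int i = 0; i < T.nu; ++i) T.k1[i] = xk1_inf(T.umin + i * T.du);
}

// per-node ischemia constants precomputed once
struct NodeIsch {
  double f_inhib, ko, katp_fac, sqrt_ko, log_ko; // log_ko = log(ko)
};

static inline void make_node(double f_katp, double f_inhib, double ko, NodeIsch& n) {
  n.f_inhib = f_inhib;
  n.ko = ko;
  n.katp_fac = f_katp * GkATP * pow(ko / Ko_n, 0.24);
  n.sqrt_ko = sqrt(ko / 5.4);
  n.log_ko = log(ko);
}

// one reaction step on a single cell's state; returns ionic dV/dt (mV/ms).
// V itself is NOT updated here (the caller owns the V update so the cable
// can add the diffusion term); gates and concentrations are updated in place.
static inline double react_step(double* s, const Tables& T, const double* sc,
                                const NodeIsch& nd, double istim, double dt,
                                bool fast) {
  double V = s[iV];
  double w = (V - T.vmin) * T.inv_dv;
  int i0 = (int)w;
  if (i0 < 0) { i0 = 0; w = 0.0; }
  if (i0 >= T.n - 1) { i0 = T.n - 2; w = (double)(T.n - 1); }
  double fr = w - i0;
  const double* r0 = &T.t[(size_t)i0 * TROW];
  const double* r1 = r0 + TROW;

  double ek = RTONF * (nd.log_ko - log(s[iKi]));
  double ena = RTONF * log(Nao / s[iNai]);
  double eks = RTONF * log((nd.ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  double eca = 0.5 * RTONF * log(Cao / s[iCai]);

  double u = V - ek;
  double wu = (u - T.umin) * T.inv_du;
  int j0 = (int)wu;
  if (j0 < 0) { j0 = 0; wu = 0.0; }
  if (j0 >= T.nu - 1) { j0 = T.nu - 2; wu = (double)(T.nu - 1); }
  double fru = wu - j0;
  double xk1 = T.k1[j0] + fru * (T.k1[j0 + 1] - T.k1[j0]);

  VCoef vc;
  vc.ical_coef = r0[33] + fr * (r1[33] - r0[33]);
  vc.ical_e1   = r0[34] + fr * (r1[34] - r0[34]);
  vc.naca_e1   = r0[35] + fr * (r1[35] - r0[35]);
  vc.naca_e2   = r0[36] + fr * (r1[36] - r0[36]);
  vc.nak_rec   = r0[37] + fr * (r1[37] - r0[37]);
  vc.pk_rec    = r0[38] + fr * (r1[38] - r0[38]);

  Currents I;
  compute_currents(s, vc, xk1, ek, ena, eks, eca, sc, 0.0 /*unused*/, nd.f_inhib,
                   nd.ko, nd.katp_fac, nd.sqrt_ko, I);

  double dKi, dNai, dCai, dCaSS, dCaSR, dRbar, Irel;
  conc_derivs(s, I, istim, &dKi, &dNai, &dCai, &dCaSS, &dCaSR, &dRbar, &Irel);

  // Rush-Larsen gate updates from tabulated exp(-dt/tau)
  int off = fast ? NGATE : 2 * NGATE;
  for (int g = 0; g < NGATE; ++g) {
    double inf = r0[g] + fr * (r1[g] - r0[g]);
    double rl = r0[off + g] + fr * (r1[off + g] - r0[off + g]);
    int k = GIDX[g];
    s[k] = inf + (s[k] - inf) * rl;
  }
  // fCass (depends on CaSS, not tabulated)
  {
    double fcinf, fctau;
    fcass_rates(s[iCaSS], &fcinf, &fctau);
    s[ifcass] = fcinf + (s[ifcass] - fcinf) * exp(-dt / fctau);
  }
  // forward Euler for concentrations and release gate
  s[iKi] += dt * dKi;
  s[iNai] += dt * dNai;
  s[iCai] += dt * dCai;
  s[iCaSS] += dt * dCaSS;
  s[iCaSR] += dt * dCaSR;
  s[irbar] += dt * dRbar;

  return -(I.itot + istim);
}

// duration above -70 mV within a beat: a cheap per-beat APD proxy used only
// to flag beat-to-beat non-convergence (alternans) in trace metadata
struct BeatTracker {
  double above_since = NA_REAL;
  double dur = 0.0;
  bool was_above = false;
  void update(double t, double V) {
    bool above = V > -70.0;
    if (above && !was_above) above_since = t;
    if (!above && was_above && R_finite(above_since)) dur += t - above_since;
    was_above = above;
  }
  double finish(double t) {
    double d = dur;
    if (was_above && R_finite(above_since)) d += t - above_since;
    dur = 0.0; was_above = false; above_since = NA_REAL;
    return d;
  }
};

// [[Rcpp::export(name = ".tp06_pace_cpp")]]
List tp06_pace_cpp(NumericVector scale, double f_katp, double f_inhib, double ko,
                   double cl, int n_beats, double stim_amp, double stim_dur,
                   double dt_fast, double dt_slow, double record_dt,
                   double dvdt_switch, NumericVector state0, bool record_all) {
  if (scale.size() != 12) stop("scale must have length 12");
  if (ko <= 0) stop("extracellular potassium must be positive");
  if (n_beats < 1) stop("n_beats must be >= 1");
  if (cl <= stim_dur || stim_dur <= 0) stop("need CL > stimulus duration > 0");

  Tables T;
  build_tables(T, dt_fast, dt_slow);
  NodeIsch nd;
  make_node(f_katp, f_inhib, ko, nd);
  double sc[12];
  for (int i = 0; i < 12; ++i) sc[i] = scale[i];
  double s[NSTATE];
  for (int i = 0; i < NSTATE; ++i) s[i] = state0[i];

  // integer-aligned dual time step: all times are multiples of dt_fast
  long long kslow = (long long)std::llround(dt_slow / dt_fast);
  long long krec = (long long)std::llround(record_dt / dt_fast);
  long long steps_per_beat = (long long)std::llround(cl / dt_fast);
  if (fabs(kslow * dt_fast - dt_slow) > 1e-9 || fabs(krec * dt_fast - record_dt) > 1e-9 ||
      fabs(steps_per_beat * dt_fast - cl) > 1e-9)
    stop("dt_slow, record_dt and CL must be integer multiples of dt_fast");
  long long stim_steps = (long long)std::llround(stim_dur / dt_fast);

  long long rec_per_beat = steps_per_beat / krec + 1;
  long long n_rec = record_all ? ((rec_per_beat - 1) * n_beats + 1) : rec_per_beat;
  NumericVector time_out((R_xlen_t)n_rec), v_out((R_xlen_t)n_rec);
  NumericVector beat_apd(n_beats);
  BeatTracker bt;

  double dvdt = 0.0;
  long long ridx = 0;
  for (int b = 0; b < n_beats; ++b) {
    bool last = (b == n_beats - 1);
    long long step = 0;
    while (step < steps_per_beat) {
      double t_in_beat = step * dt_fast;
      if ((record_all || last) && step % krec == 0) {
        time_out[(R_xlen_t)ridx] = record_all ? b * cl + t_in_beat : t_in_beat;
        v_out[(R_xlen_t)ridx] = s[iV];
        ++ridx;
      }
      bt.update(t_in_beat, s[iV]);
      bool in_stim = step < stim_steps;
      bool fast = in_stim || fabs(dvdt) > dvdt_switch || step % kslow != 0 ||
                  (step + kslow > steps_per_beat);
      double dt = fast ? dt_fast : dt_slow;
      double istim = in_stim ? stim_amp : 0.0;
      dvdt = react_step(s, T, sc, nd, istim, dt, fast);
      s[iV] += dt * dvdt;
      if (!std::isfinite(s[iV]))
        stop("numerical failure: non-finite V at beat %d, t = %g ms", b + 1, t_in_beat);
      step += fast ? 1 : kslow;
    }
    beat_apd[b] = bt.finish(cl);
  }
  // closing sample at t = CL of the last beat
  time_out[(R_xlen_t)ridx] = record_all ? (double)n_beats * cl : cl;
  v_out[(R_xlen_t)ridx] = s[iV];
  ++ridx;

  NumericVector fin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) fin[i] = s[i];
  fin.attr("names") = tp06_initial_state_cpp().attr("names");
  return List::create(_["time"] = time_out, _["v"] = v_out,
                      _["state_final"] = fin, _["beat_apd"] = beat_apd);
}

// [[Rcpp::export(name = ".tp06_cable_cpp")]]
List tp06_cable_cpp(NumericVector scale, NumericVector f_katp,
                    NumericVector f_inhib, NumericVector ko, double D, double dl,
                    double cl, int n_beats, double stim_amp, double stim_dur,
                    int stim_nodes, double dt_fast, double dt_slow,
                    double record_dt, double dvdt_switch, NumericMatrix state0) {
  int nn = f_katp.size();
  if (f_inhib.size() != nn || ko.size() != nn) stop("per-node ischemia vectors must agree");
  if (state0.nrow() != NSTATE || state0.ncol() != nn)
    stop("state0 must be a %d x n_nodes matrix", NSTATE);
  if (scale.size() != 12) stop("scale must have length 12");
  if (n_beats < 1) stop("n_beats must be >= 1");
  for (int i = 0; i < nn; ++i)
    if (ko[i] <= 0) stop("extracellular potassium must be positive");

  Tables T;
  build_tables(T, dt_fast, dt_slow);
  std::vector<NodeIsch> nd(nn);
  for (int i = 0; i < nn; ++i) make_node(f_katp[i], f_inhib[i], ko[i], nd[i]);
  double sc[12];
  for (int i = 0; i < 12; ++i) sc[i] = scale[i];

  std::vector<double> S((size_t)NSTATE * nn);
  for (int j = 0; j < nn; ++j)
    for (int i = 0; i < NSTATE; ++i) S[(size_t)j * NSTATE + i] = state0(i, j);

  long long kslow = (long long)std::llround(dt_slow / dt_fast);
  long long krec = (long long)std::llround(record_dt / dt_fast);
  long long steps_per_beat = (long long)std::llround(cl / dt_fast);
  if (fabs(kslow * dt_fast - dt_slow) > 1e-9 || fabs(krec * dt_fast - record_dt) > 1e-9 ||
      fabs(steps_per_beat * dt_fast - cl) > 1e-9)
    stop("dt_slow, record_dt and CL must be integer multiples of dt_fast");
  long long stim_steps = (long long)std::llround(stim_dur / dt_fast);

  // explicit-diffusion stability (r = D dt / dl^2 <= 1/2)
  if (D * dt_slow / (dl * dl) > 0.5)
    stop("diffusion number D*dt/dl^2 exceeds stability limit; reduce dt_slow");

  long long n_rec = steps_per_beat / krec + 1;
  NumericMatrix v_out((R_xlen_t)n_rec, nn);
  NumericVector time_out((R_xlen_t)n_rec);

  std::vector<double> dv(nn), lap(nn);
  double rmax = 0.0; // max |dV/dt| over nodes from previous step
  long long ridx = 0;
  double rD = D / (dl * dl);

  for (int b = 0; b < n_beats; ++b) {
    bool last = (b == n_beats - 1);
    long long step = 0;
    while (step < steps_per_beat) {
      if (last && step % krec == 0) {
        time_out[(R_xlen_t)ridx] = step * dt_fast;
        for (int j = 0; j < nn; ++j) v_out((R_xlen_t)ridx, j) = S[(size_t)j * NSTATE + iV];
        ++ridx;
      }
      bool in_stim = step < stim_steps;
      bool fast = in_stim || rmax > dvdt_switch || step % kslow != 0 ||
                  (step + kslow > steps_per_beat);
      double dt = fast ? dt_fast : dt_slow;

      // diffusion term (second-order central differences, no-flux ends)
      for (int j = 0; j < nn; ++j) {
        double vm = S[(size_t)(j == 0 ? 1 : j - 1) * NSTATE + iV];
        double vp = S[(size_t)(j == nn - 1 ? nn - 2 : j + 1) * NSTATE + iV];
        lap[j] = rD * (vm - 2.0 * S[(size_t)j * NSTATE + iV] + vp);
      }
      double newmax = 0.0;
      for (int j = 0; j < nn; ++j) {
        double istim = (in_stim && j < stim_nodes) ? stim_amp : 0.0;
        double* sj = &S[(size_t)j * NSTATE];
        double d = react_step(sj, T, sc, nd[j], istim, dt, fast);
        double tot = d + lap[j];
        sj[iV] += dt * tot;
        if (!std::isfinite(sj[iV]))
          stop("numerical failure: non-finite V at node %d, beat %d, t = %g ms",
               j + 1, b + 1, step * dt_fast);
        if (fabs(tot) > newmax) newmax = fabs(tot);
      }
      rmax = newmax;
      step += fast ? 1 : kslow;
    }
  }
  time_out[(R_xlen_t)ridx] = cl;
  for (int j = 0; j < nn; ++j) v_out((R_xlen_t)ridx, j) = S[(size_t)j * NSTATE + iV];
  ++ridx;

  NumericMatrix fin(NSTATE, nn);
  for (int j = 0; j < nn; ++j)
    for (int i = 0; i < NSTATE; ++i) fin(i, j) = S[(size_t)j * NSTATE + i];
  return List::create(_["time"] = time_out, _["v"] = v_out, _["state_final"] = fin);
}
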