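// Compiled core: cardiomyocyte / fibroblast / custom-cell right-hand sides and
// the coupled fixed-grid integrator.
//
// Cardiomyocyte: O'Hara-Rudy (2011) human endocardial ventricular model with the
// fast sodium current replaced by the ten Tusscher-Panfilov formulation (the
// published heart-failure parameterization of this model uses that substitution).
// Units follow the source models: mV, ms, mM, uA/uF (== pA/pF) for densities.
//
// Integration: hybrid scheme -- Rush-Larsen exponential updates for gating
// variables, forward Euler for voltage and concentrations, with local step
// refinement driven by |dV/dt|. Voltage-dependent rates are linearly
// interpolated from a lookup table (0.02 mV grid); the single-evaluation RHS
// entry points used by tests bypass the table and evaluate rates directly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- constants
const double RGAS = 8314.0;     // mJ/(mol*K)
const double TEMP = 310.0;      // K
const double FDY  = 96485.0;    // C/mol
const double RTF  = RGAS * TEMP / FDY;

// extracellular milieu (shared by all cells)
const double NAO = 140.0, CAO = 1.8, KO = 5.4;

// ORd cell geometry (endocardial)
const double CELL_L = 0.01, CELL_RAD = 0.0011;
const double VCELL = 1000.0 * 3.14 * CELL_RAD * CELL_RAD * CELL_L;
const double AGEO  = 2.0 * 3.14 * CELL_RAD * CELL_RAD + 2.0 * 3.14 * CELL_RAD * CELL_L;
const double ACAP  = 2.0 * AGEO;              // cm^2
const double CM_CAP_PF = ACAP * 1.0e6;        // 1 uF/cm^2 -> pF (~153.4)
const double VMYO = 0.68 * VCELL, VNSR = 0.0552 * VCELL;
const double VJSR = 0.0048 * VCELL, VSS = 0.02 * VCELL;

// fibroblast (MacCannell active model)
const double FIB_CAP_PF = 6.3;
const double FIB_NAI = 8.5547, FIB_KI = 129.4350;
const double FIB_GKV = 0.25, FIB_GK1 = 0.4822, FIB_GBNA = 0.0095, FIB_PNAK = 2.002;
const double FIB_KMK = 1.0, FIB_KMNA = 11.0;

const double CUST_CAP_PF = 40.0;

// CaMK
const double KMCAMK = 0.15, ACAMK = 0.05, BCAMK = 0.00068, CAMKO = 0.05, KMCAM = 0.0015;

inline double safe_ratio(double x) {            // x / (exp(x)-1) -> 1 at x=0
  return (std::fabs(x) < 1e-8) ? 1.0 - 0.5 * x : x / std::expm1(x);
}

// ------------------------------------------------------------- state layout
enum CmState {
  S_V = 0, S_NAI, S_NASS, S_KI, S_KSS, S_CAI, S_CASS, S_CANSR, S_CAJSR,
  S_M, S_H, S_J, S_ML, S_HL, S_HLP, S_A, S_IF, S_IS, S_AP, S_IFP, S_ISP,
  S_D, S_FF, S_FS, S_FCAF, S_FCAS, S_JCA, S_NCA, S_FFP, S_FCAFP,
  S_XRF, S_XRS, S_XS1, S_XS2, S_XK1, S_JRELNP, S_JRELP, S_CAMKT,
  N_CM_STATE
};

enum CmScale {
  SC_GNA = 0, SC_GNAL, SC_GTO, SC_PCA, SC_GKR, SC_GKS, SC_GK1, SC_GNCX,
  SC_PNAK, SC_GKB, SC_GPCA, SC_JUP, SC_JLEAK, SC_JREL, SC_THL, SC_CAMK,
  SC_GNAB, SC_GCAB,
  N_CM_SCALE
};

enum CmCur {
  C_INA = 0, C_INAL, C_ITO, C_ICAL, C_ICANA, C_ICAK, C_IKR, C_IKS, C_IK1,
  C_INACA, C_INAK, C_INAB, C_ICAB, C_IPCA, C_IKB, C_JREL, C_JUP, C_JDIFF,
  N_CM_CUR
};

enum FibState { F_V = 0, F_R, F_S, N_FIB_STATE };

// custom cell: voltage + one gating block per channel family (blocks for
// channels absent from a roster are integrated but carry zero current)
enum CustState {
  U_V = 0,
  U_M, U_H, U_J, U_ML, U_HL, U_A, U_IF, U_IS,            // hCM Na/NaL/to
  U_D, U_FF, U_FS, U_FCAF, U_FCAS, U_JCA, U_NCA,         // hCM CaL
  U_XRF, U_XRS, U_XS1, U_XS2, U_XK1,                     // hCM Kr/Ks/K1
  U_CIC_M, U_CIC_H, U_CIC_R, U_CIC_S,                    // hCIC Na, to
  U_MSC_R, U_MSC_S, U_MSC_M, U_MSC_H, U_MSC_D, U_MSC_F, U_MSC_N, // hMSC
  U_CF_R, U_CF_S,                                        // CF Kv
  N_CUST_STATE
};

// channel order of the custom-cell conductance-density vector (nS/pF except
// cf_nak which is a maximal current density in pA/pF)
enum CustChan {
  CH_CIC_NA = 0, CH_CIC_KIR, CH_CIC_KCA, CH_CIC_TO,
  CH_MSC_TO, CH_MSC_TO_SS, CH_MSC_NA, CH_MSC_CAL, CH_MSC_KCA, CH_MSC_DR,
  CH_CF_KV, CH_CF_KIR, CH_CF_NAK,
  CH_CM_NA, CH_CM_NAL, CH_CM_TO, CH_CM_CAL, CH_CM_KR, CH_CM_KS, CH_CM_K1,
  CH_PASSIVE,
  N_CUST_CHAN
};

// ------------------------------------------------- gate rate formulations
// Each returns steady state (inf) and time constant (tau, ms) at voltage v.
typedef void (*GateFn)(double, double&, double&);

// ten Tusscher-Panfilov fast sodium current gates (the INa substitution)
void g_m(double v, double& inf, double& tau) {
  double a = 1.0 / (1.0 + std::exp((-56.86 - v) / 9.03));
  inf = a * a;
  double am = 1.0 / (1.0 + std::exp((-60.0 - v) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
              0.1 / (1.0 + std::exp((v - 50.0) / 200.0));
  tau = am * bm;
}
void g_h(double v, double& inf, double& tau) {
  double a = 1.0 / (1.0 + std::exp((v + 71.55) / 7.43));
  inf = a * a;
  double ah, bh;
  if (v >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
  } else {
    ah = 0.057 * std::exp(-(v + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
  }
  tau = 1.0 / (ah + bh);
}
void g_j(double v, double& inf, double& tau) {
  double a = 1.0 / (1.0 + std::exp((v + 71.55) / 7.43));
  inf = a * a;
  double aj, bj;
  if (v >= -40.0) {
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  } else {
    aj = (-2.5428e4 * std::exp(0.2444 * v) - 6.948e-6 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  }
  tau = 1.0 / (aj + bj);
}

// ORd late sodium
void g_mL(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  tau = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
               8.552 * std::exp(-(v + 77.42) / 5.955));
}
void g_hL(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  tau = 200.0;                                   // scaled by tau_hl at use site
}
void g_hLp(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  tau = 600.0;
}

// ORd transient outward (endocardial: no epicardial delta factor)
void g_a(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  tau = 1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
                  3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
}
void g_iF(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  tau = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                       0.08004 * std::exp((v + 50.0) / 16.59));
}
void g_iS(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  tau = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                       1.780e-8 * std::exp((v + 114.1) / 8.079));
}
void g_ap(double v, double& inf, double& tau) {
  double ainf;
  g_a(v, ainf, tau);                 // shares tau with the a gate
  inf = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
}
inline double dti_develop(double v) {
  return 1.354 + 1.0e-4 / (std::exp((v - 167.4) / 15.89) +
                           std::exp(-(v - 12.23) / 0.2154));
}
inline double dti_recover(double v) {
  return 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
}
void g_iFp(double v, double& inf, double& tau) {
  double t0; g_iF(v, inf, t0);
  tau = dti_develop(v) * dti_recover(v) * t0;
}
void g_iSp(double v, double& inf, double& tau) {
  double t0; g_iS(v, inf, t0);
  tau = dti_develop(v) * dti_recover(v) * t0;
}

// ORd L-type calcium
void g_d(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  tau = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) + std::exp(0.09 * (v + 14.0)));
}
void g_ff(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  tau = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                     0.0045 * std::exp((v + 20.0) / 10.0));
}
void g_fs(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  tau = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                        0.000035 * std::exp((v + 5.0) / 6.0));
}
void g_fcaf(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  tau = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                     0.04 * std::exp((v - 4.0) / 7.0));
}
void g_fcas(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  tau = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                       0.00012 * std::exp(v / 7.0));
}
void g_jca(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  tau = 75.0;
}
void g_ffp(double v, double& inf, double& tau) {
  double t0; g_ff(v, inf, t0); tau = 2.5 * t0;
}
void g_fcafp(double v, double& inf, double& tau) {
  double t0; g_fcaf(v, inf, t0); tau = 2.5 * t0;
}

// ORd rapid delayed rectifier
void g_xrf(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  tau = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                       4.123e-5 * std::exp(-(v - 47.78) / 20.38));
}
void g_xrs(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  tau = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                       1.128e-5 * std::exp(-(v - 29.74) / 25.94));
}

// ORd slow delayed rectifier
void g_xs1(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  tau = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                       0.001292 * std::exp(-(v + 210.0) / 230.0));
}
void g_xs2(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  tau = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
               0.0193 * std::exp(-(v + 66.54) / 31.0));
}

// ORd inward rectifier gate
void g_xk1(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 2.5538 * KO + 144.59) / (1.5692 * KO + 3.8115)));
  tau = 122.2 / (std::exp(-(v + 127.2) / 20.36) + std::exp((v + 236.8) / 69.33));
}

// hCIC gates (reconstructed formulations; see package documentation)
void g_cic_m(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 27.0) / 5.9));
  double z = (v + 30.0) / 25.0;
  tau = 0.15 + 0.6 * std::exp(-z * z);
}
void g_cic_h(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 61.0) / 6.0));
  double z = (v + 55.0) / 20.0;
  tau = 3.0 + 40.0 * std::exp(-z * z);
}
void g_cic_r(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v - 5.0) / 13.0));
  double z = (v + 10.0) / 30.0;
  tau = 1.5 + 3.0 * std::exp(-z * z);
}
void g_cic_s(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 37.0) / 7.0));
  double z = (v + 40.0) / 25.0;
  tau = 25.0 + 200.0 * std::exp(-z * z);
}

// hMSC gates (reconstructed formulations)
void g_msc_r(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v - 4.0) / 14.0));
  double z = (v + 15.0) / 30.0;
  tau = 2.0 + 8.0 * std::exp(-z * z);
}
void g_msc_s(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 32.0) / 7.0));
  double z = (v + 35.0) / 30.0;
  tau = 40.0 + 500.0 * std::exp(-z * z);
}
void g_msc_m(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 32.0) / 6.0));
  double z = (v + 35.0) / 25.0;
  tau = 0.3 + 1.0 * std::exp(-z * z);
}
void g_msc_h(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 62.0) / 6.5));
  double z = (v + 60.0) / 20.0;
  tau = 5.0 + 60.0 * std::exp(-z * z);
}
void g_msc_d(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 11.0) / 6.2));
  double z = (v + 15.0) / 20.0;
  tau = 1.0 + 3.0 * std::exp(-z * z);
}
void g_msc_f(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 26.0) / 6.0));
  double z = (v + 25.0) / 25.0;
  tau = 30.0 + 250.0 * std::exp(-z * z);
}
void g_msc_n(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v - 12.0) / 11.0));
  double z = (v + 10.0) / 35.0;
  tau = 30.0 + 300.0 * std::exp(-z * z);
}

// MacCannell fibroblast Kv gates
void g_cf_r(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 20.0) / 11.0));
  double z = (v + 20.0) / 25.9;
  tau = 20.3 + 138.0 * std::exp(-z * z);
}
void g_cf_s(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 23.0) / 7.0));
  double z = (v + 23.0) / 22.7;
  tau = 1574.0 + 5268.0 * std::exp(-z * z);
}

// gate tables: order must match the update loops below
const GateFn CM_GATES[] = {
  g_m, g_h, g_j, g_mL, g_hL, g_hLp, g_a, g_iF, g_iS, g_ap, g_iFp, g_iSp,
  g_d, g_ff, g_fs, g_fcaf, g_fcas, g_jca, g_ffp, g_fcafp,
  g_xrf, g_xrs, g_xs1, g_xs2, g_xk1
};
const int CM_GATE_STATE[] = {
  S_M, S_H, S_J, S_ML, S_HL, S_HLP, S_A, S_IF, S_IS, S_AP, S_IFP, S_ISP,
  S_D, S_FF, S_FS, S_FCAF, S_FCAS, S_JCA, S_FFP, S_FCAFP,
  S_XRF, S_XRS, S_XS1, S_XS2, S_XK1
};
const int N_CM_GATE = 25;

const GateFn CUST_GATES[] = {
  g_m, g_h, g_j, g_mL, g_hL, g_a, g_iF, g_iS,
  g_d, g_ff, g_fs, g_fcaf, g_fcas, g_jca,
  g_xrf, g_xrs, g_xs1, g_xs2, g_xk1,
  g_cic_m, g_cic_h, g_cic_r, g_cic_s,
  g_msc_r, g_msc_s, g_msc_m, g_msc_h, g_msc_d, g_msc_f, g_msc_n,
  g_cf_r, g_cf_s
};
const int CUST_GATE_STATE[] = {
  U_M, U_H, U_J, U_ML, U_HL, U_A, U_IF, U_IS,
  U_D, U_FF, U_FS, U_FCAF, U_FCAS, U_JCA,
  U_XRF, U_XRS, U_XS1, U_XS2, U_XK1,
  U_CIC_M, U_CIC_H, U_CIC_R, U_CIC_S,
  U_MSC_R, U_MSC_S, U_MSC_M, U_MSC_H, U_MSC_D, U_MSC_F, U_MSC_N,
  U_CF_R, U_CF_S
};
const int N_CUST_GATE = 32;

const GateFn FIB_GATES[] = { g_cf_r, g_cf_s };
const int FIB_GATE_STATE[] = { F_R, F_S };
const int N_FIB_GATE = 2;

// ------------------------------- voltage-dependent algebraic terms (non-gate)
struct VDep {
  double expvfrt, a1, exp2vfrt, a2;   // GHK building blocks
  double hca, hna, knai, knao;        // NCX / NaK exponentials
  double rkr, rk1, xkb;               // instantaneous rectifications
  double aif, axrf, afcaf;            // component splits
  double cic_kca_o, msc_kca_o;        // voltage part of KCa open fractions
  double fib_k1r;                     // fibroblast IK1 rectification (aK1/(aK1+bK1))
};

void vdep_direct(double v, VDep& w) {
  double vfrt = v / RTF;
  w.expvfrt = std::exp(vfrt);
  w.exp2vfrt = std::exp(2.0 * vfrt);
  w.a1 = FDY * safe_ratio(vfrt);
  w.a2 = 2.0 * FDY * safe_ratio(2.0 * vfrt);
  w.hca = std::exp(0.1670 * vfrt);
  w.hna = std::exp(0.5224 * vfrt);
  w.knai = 9.073 * std::exp(-0.1550 * vfrt / 3.0);
  w.knao = 27.78 * std::exp((1.0 + 0.1550) * vfrt / 3.0);
  w.rkr = 1.0 / ((1.0 + std::exp((v + 55.0) / 75.0)) *
                 (1.0 + std::exp((v - 10.0) / 30.0)));
  w.rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * KO) / 9.493));
  w.xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  w.aif = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  w.axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  w.afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  w.cic_kca_o = 1.0 / (1.0 + std::exp(-(v - 10.0) / 14.0));
  w.msc_kca_o = 1.0 / (1.0 + std::exp(-(v - 5.0) / 16.0));
  double ekf = RTF * std::log(KO / FIB_KI);
  double dv = v - ekf;
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (dv - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (dv + 100.0)) + std::exp(0.1 * (dv - 10.0))) /
               (1.0 + std::exp(-0.5 * dv));
  w.fib_k1r = ak1 / (ak1 + bk1);
}

// ------------------------------------------------------------- lookup table
const double TAB_VMIN = -150.0, TAB_VMAX = 100.0, TAB_STEP = 0.02;
const int TAB_NROW = 12501;
const int NG_ALL = N_CM_GATE + N_CUST_GATE + N_FIB_GATE;   // some duplication, fine
const int TAB_NCOL = 3 * NG_ALL + 17;                      // inf/tau/efac + VDep

struct Table {
  std::vector<double> d;
  double dtmax;
  bool built;
  Table() : dtmax(-1.0), built(false) {}
};
Table g_tab;

const GateFn* ALL_GATES[3] = { CM_GATES, CUST_GATES, FIB_GATES };
const int ALL_NG[3] = { N_CM_GATE, N_CUST_GATE, N_FIB_GATE };

void build_table(double dtmax) {
  g_tab.d.assign((size_t)TAB_NROW * TAB_NCOL, 0.0);
  for (int i = 0; i < TAB_NROW; i++) {
    double v = TAB_VMIN + i * TAB_STEP;
    double* row = &g_tab.d[(size_t)i * TAB_NCOL];
    int c = 0;
    for (int blk = 0; blk < 3; blk++) {
      for (int gidx = 0; gidx < ALL_NG[blk]; gidx++) {
        double inf, tau;
        ALL_GATES[blk][gidx](v, inf, tau);
        row[c++] = inf;
        row[c++] = tau;
        row[c++] = std::exp(-dtmax / tau);
      }
    }
    VDep w; vdep_direct(v, w);
    row[c++] = w.expvfrt; row[c++] = w.a1; row[c++] = w.exp2vfrt; row[c++] = w.a2;
    row[c++] = w.hca; row[c++] = w.hna; row[c++] = w.knai; row[c++] = w.knao;
    row[c++] = w.rkr; row[c++] = w.rk1; row[c++] = w.xkb;
    row[c++] = w.aif; row[c++] = w.axrf; row[c++] = w.afcaf;
    row[c++] = w.cic_kca_o; row[c++] = w.msc_kca_o; row[c++] = w.fib_k1r;
  }
  g_tab.dtmax = dtmax;
  g_tab.built = true;
}

struct TabRow {
  const double* r0;
  const double* r1;
  double w;
  void locate(double v) {
    double x = (v - TAB_VMIN) / TAB_STEP;
    if (x < 0.0) x = 0.0;
    if (x > TAB_NROW - 1.001) x = TAB_NROW - 1.001;
    int i = (int)x;
    w = x - i;
    r0 = &g_tab.d[(size_t)i * TAB_NCOL];
    r1 = r0 + TAB_NCOL;
  }
  inline double get(int c) const { return r0[c] + w * (r1[c] - r0[c]); }
};

const int COL_CUST0 = 3 * N_CM_GATE;
const int COL_FIB0 = 3 * (N_CM_GATE + N_CUST_GATE);
const int COL_X0 = 3 * NG_ALL;

void vdep_from_table(const TabRow& tr, VDep& w) {
  int c = COL_X0;
  w.expvfrt = tr.get(c++); w.a1 = tr.get(c++); w.exp2vfrt = tr.get(c++); w.a2 = tr.get(c++);
  w.hca = tr.get(c++); w.hna = tr.get(c++); w.knai = tr.get(c++); w.knao = tr.get(c++);
  w.rkr = tr.get(c++); w.rk1 = tr.get(c++); w.xkb = tr.get(c++);
  w.aif = tr.get(c++); w.axrf = tr.get(c++); w.afcaf = tr.get(c++);
  w.cic_kca_o = tr.get(c++); w.msc_kca_o = tr.get(c++); w.fib_k1r = tr.get(c++);
}

// --------------------------------------------- cardiomyocyte current algebra
// Computes all membrane currents / fluxes (uA/uF or mM/ms) plus derivatives of
// the non-gating states. i_ext is the total external current density applied
// to the voltage equation (stimulus + gap-junction load), uA/uF.
void cm_algebra(const double* s, const double* sc, double i_ext, const VDep& w,
                double* cur, double* dnon /* length N_CM_STATE, gate slots 0 */) {
  double v = s[S_V];
  double nai = s[S_NAI], nass = s[S_NASS], ki = s[S_KI], kss = s[S_KSS];
  double cai = s[S_CAI], cass = s[S_CASS], cansr = s[S_CANSR], cajsr = s[S_CAJSR];

  double ena = RTF * std::log(NAO / nai);
  double ek = RTF * std::log(KO / ki);
  double eks = RTF * std::log((KO + 0.01833 * NAO) / (ki + 0.01833 * nai));

  double camkb = sc[SC_CAMK] * CAMKO * (1.0 - s[S_CAMKT]) / (1.0 + KMCAM / cass);
  double camka = camkb + s[S_CAMKT];
  double fp = 1.0 / (1.0 + KMCAMK / camka);

  // fast Na (ten Tusscher-Panfilov substitution)
  double ina = sc[SC_GNA] * 14.838 * s[S_M] * s[S_M] * s[S_M] * s[S_H] * s[S_J] * (v - ena);

  // late Na
  double inal = sc[SC_GNAL] * 0.0075 * s[S_ML] *
                ((1.0 - fp) * s[S_HL] + fp * s[S_HLP]) * (v - ena);

  // transient outward
  double i_i = w.aif * s[S_IF] + (1.0 - w.aif) * s[S_IS];
  double i_ip = w.aif * s[S_IFP] + (1.0 - w.aif) * s[S_ISP];
  double ito = sc[SC_GTO] * 0.02 * (v - ek) *
               ((1.0 - fp) * s[S_A] * i_i + fp * s[S_AP] * i_ip);

  // L-type Ca (GHK), with Na and K components through the channel
  double phical = w.a2 * (cass * w.exp2vfrt - 0.341 * CAO);
  double phicana = w.a1 * (0.75 * nass * w.expvfrt - 0.75 * NAO);
  double phicak = w.a1 * (0.75 * kss * w.expvfrt - 0.75 * KO);
  double pca = sc[SC_PCA] * 0.0001;
  double pcap = 1.1 * pca;
  double f = 0.6 * s[S_FF] + 0.4 * s[S_FS];
  double fca = w.afcaf * s[S_FCAF] + (1.0 - w.afcaf) * s[S_FCAS];
  double fpch = 0.6 * s[S_FFP] + 0.4 * s[S_FS];
  double fcap = w.afcaf * s[S_FCAFP] + (1.0 - w.afcaf) * s[S_FCAS];
  double nca = s[S_NCA];
  double op = s[S_D] * (f * (1.0 - nca) + s[S_JCA] * fca * nca);
  double opp = s[S_D] * (fpch * (1.0 - nca) + s[S_JCA] * fcap * nca);
  double ical = (1.0 - fp) * pca * phical * op + fp * pcap * phical * opp;
  double icana = ((1.0 - fp) * 0.00125 * pca * phicana * op +
                  fp * 0.00125 * pcap * phicana * opp);
  double icak = ((1.0 - fp) * 3.574e-4 * pca * phicak * op +
                 fp * 3.574e-4 * pcap * phicak * opp);

  // rapid delayed rectifier
  double xr = w.axrf * s[S_XRF] + (1.0 - w.axrf) * s[S_XRS];
  double ikr = sc[SC_GKR] * 0.046 * 1.0 * xr * w.rkr * (v - ek);

  // slow delayed rectifier
  double ksca = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  double iks = sc[SC_GKS] * 0.0034 * ksca * s[S_XS1] * s[S_XS2] * (v - eks);

  // inward rectifier
  double ik1 = sc[SC_GK1] * 0.1908 * 2.3237900077244501 * s[S_XK1] * w.rk1 * (v - ek);

  // Na/Ca exchanger (myoplasmic and subspace components)
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
  double inaca_i = 0.0, inaca_ss = 0.0;
  for (int part = 0; part < 2; part++) {
    double na = part == 0 ? nai : nass;
    double ca = part == 0 ? cai : cass;
    double h1 = 1.0 + na / kna3 * (1.0 + w.hna);
    double h2 = na * w.hna / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + na / kna1 * (1.0 + na / kna2);
    double h5 = na * na / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + NAO / kna3 * (1.0 + 1.0 / w.hna);
    double h8 = NAO / (kna3 * w.hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + NAO / kna1 * (1.0 + NAO / kna2);
    double h11 = NAO * NAO / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * CAO * kcaon;
    double k2 = kcaoff;
    double k3p = h9 * wca;
    double k3pp = h8 * wnaca;
    double k3 = k3p + k3pp;
    double k4p = h3 * wca / w.hca;
    double k4pp = h2 * wnaca;
    double k4 = k4p + k4pp;
    double k5 = kcaoff;
    double k6 = h6 * ca * kcaon;
    double k7 = h5 * h2 * wna;
    double k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double tot = x1 + x2 + x3 + x4;
    double e1 = x1 / tot, e2 = x2 / tot, e3 = x3 / tot, e4 = x4 / tot;
    double allo_t = 150.0e-6 / ca;
    double allo = 1.0 / (1.0 + allo_t * allo_t);
    double jncxna = 3.0 * (e4 * k7 - e1 * k8) + e3 * k4pp - e2 * k3pp;
    double jncxca = e2 * k2 - e1 * k1;
    double g = sc[SC_GNCX] * 0.0008 * allo * (jncxna + 2.0 * jncxca);
    if (part == 0) inaca_i = 0.8 * g; else inaca_ss = 0.2 * g;
  }

  // Na/K pump
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double kki = 0.5, kko = 0.3582, mgadp = 0.05, mgatp = 9.8;
    const double kmgatp = 1.698e-7, hp = 1.0e-7, ep = 4.2;
    const double khp = 1.698e-7, knap = 224.0, kxkur = 292.0;
    double knai = w.knai, knao = w.knao;
    double p = ep / (1.0 + hp / khp + nai / knap + ki / kxkur);
    double u; // cube/square helpers
    double c_nai = (u = 1.0 + nai / knai, u * u * u);
    double c_nao = (u = 1.0 + NAO / knao, u * u * u);
    double s_ki = (u = 1.0 + ki / kki, u * u);
    double s_ko = (u = 1.0 + KO / kko, u * u);
    double d1 = c_nai + s_ki - 1.0;
    double d2 = c_nao + s_ko - 1.0;
    double a1 = k1p * (u = nai / knai, u * u * u) / d1;
    double b1 = k1m * mgadp;
    double a2 = k2p;
    double b2 = k2m * (u = NAO / knao, u * u * u) / d2;
    double a3 = k3p * (u = KO / kko, u * u) / d2;
    double b3 = k3m * p * hp / (1.0 + mgatp / kmgatp);
    double a4 = k4p * mgatp / kmgatp / (1.0 + mgatp / kmgatp);
    double b4 = k4m * (u = ki / kki, u * u) / d1;
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b1 * a1;
    double tot = x1 + x2 + x3 + x4;
    double e1 = x1 / tot, e2 = x2 / tot, e3 = x3 / tot, e4 = x4 / tot;
    double jnakna = 3.0 * (e1 * a3 - e2 * b3);
    double jnakk = 2.0 * (e4 * b1 - e3 * a1);
    cur[C_INAK] = sc[SC_PNAK] * 30.0 * (jnakna + jnakk);
  }

  // background and pump currents
  double ikb = sc[SC_GKB] * 0.003 * w.xkb * (v - ek);
  double inab = sc[SC_GNAB] * 3.75e-10 * w.a1 * (nai * w.expvfrt - NAO);
  double icab = sc[SC_GCAB] * 2.5e-8 * w.a2 * (cai * w.exp2vfrt - 0.341 * CAO);
  double ipca = sc[SC_GPCA] * 0.0005 * cai / (0.0005 + cai);

  // SR fluxes
  double fjrelp = fp;
  double bt = 4.75, a_rel = 0.5 * bt;
  double jt = 1.5 / cajsr; jt *= jt; jt *= jt; jt *= jt;   // (1.5/cajsr)^8
  double jrel_inf_np = sc[SC_JREL] * a_rel * (-ical) / (1.0 + jt);
  double btp = 1.25 * bt, a_relp = 0.5 * btp;
  double jrel_inf_p = sc[SC_JREL] * a_relp * (-ical) / (1.0 + jt);
  double jrel = (1.0 - fjrelp) * s[S_JRELNP] + fjrelp * s[S_JRELP];

  double fjupp = fp;
  double jupnp = 0.004375 * cai / (cai + 0.00092);
  double jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  double jleak = sc[SC_JLEAK] * 0.0039375 * cansr / 15.0;
  double jup = sc[SC_JUP] * ((1.0 - fjupp) * jupnp + fjupp * jupp) - jleak;
  double jtr = (cansr - cajsr) / 100.0;

  double jdiffna = (nass - nai) / 2.0;
  double jdiffk = (kss - ki) / 2.0;
  double jdiff = (cass - cai) / 0.2;

  cur[C_INA] = ina; cur[C_INAL] = inal; cur[C_ITO] = ito;
  cur[C_ICAL] = ical; cur[C_ICANA] = icana; cur[C_ICAK] = icak;
  cur[C_IKR] = ikr; cur[C_IKS] = iks; cur[C_IK1] = ik1;
  cur[C_INACA] = inaca_i + inaca_ss;
  cur[C_INAB] = inab; cur[C_ICAB] = icab; cur[C_IPCA] = ipca; cur[C_IKB] = ikb;
  cur[C_JREL] = jrel; cur[C_JUP] = jup; cur[C_JDIFF] = jdiff;

  std::memset(dnon, 0, sizeof(double) * N_CM_STATE);
  double itot = ina + inal + ito + ical + icana + icak + ikr + iks + ik1 +
                inaca_i + inaca_ss + cur[C_INAK] + inab + icab + ipca + ikb + i_ext;
  dnon[S_V] = -itot;

  double acapf = ACAP / (FDY * VMYO);
  dnon[S_NAI] = -(ina + inal + 3.0 * inaca_i + 3.0 * cur[C_INAK] + inab) * acapf +
                jdiffna * VSS / VMYO;
  dnon[S_NASS] = -(icana + 3.0 * inaca_ss) * ACAP / (FDY * VSS) - jdiffna;
  dnon[S_KI] = -(ito + ikr + iks + ik1 + ikb + i_ext - 2.0 * cur[C_INAK]) * acapf +
               jdiffk * VSS / VMYO;
  dnon[S_KSS] = -icak * ACAP / (FDY * VSS) - jdiffk;

  double q1 = 0.00238 + cai, q2 = 0.0005 + cai;
  double bcai = 1.0 / (1.0 + 0.05 * 0.00238 / (q1 * q1) +
                       0.07 * 0.0005 / (q2 * q2));
  dnon[S_CAI] = bcai * (-(ipca + icab - 2.0 * inaca_i) * ACAP / (2.0 * FDY * VMYO) -
                        jup * VNSR / VMYO + jdiff * VSS / VMYO);
  double q3 = 0.00087 + cass, q4 = 0.0087 + cass;
  double bcass = 1.0 / (1.0 + 0.047 * 0.00087 / (q3 * q3) +
                        1.124 * 0.0087 / (q4 * q4));
  dnon[S_CASS] = bcass * (-(ical - 2.0 * inaca_ss) * ACAP / (2.0 * FDY * VSS) +
                          jrel * VJSR / VSS - jdiff);
  dnon[S_CANSR] = jup - jtr * VJSR / VNSR;
  double q5 = 0.8 + cajsr;
  double bcajsr = 1.0 / (1.0 + 10.0 * 0.8 / (q5 * q5));
  dnon[S_CAJSR] = bcajsr * (jtr - jrel);

  dnon[S_CAMKT] = ACAMK * camkb * (camkb + s[S_CAMKT]) - BCAMK * s[S_CAMKT];

  // relaxation targets for the SR-release quasi-gates and nca, packed into the
  // otherwise-unused gate slots as (inf, tau) pairs via two extra outputs:
  // handled by the callers through cm_aux below.
  (void)jrel_inf_np; (void)jrel_inf_p;
}

// auxiliary relaxation targets that depend on non-voltage state
struct CmAux {
  double jrelnp_inf, jrelnp_tau, jrelp_inf, jrelp_tau;
  double nca_inf, nca_tau;
};
void cm_aux(const double* s, const double* sc, const double* cur, CmAux& a) {
  double cajsr = s[S_CAJSR], cass = s[S_CASS];
  double ical = cur[C_ICAL];
  double bt = 4.75, btp = 1.25 * 4.75;
  double jt = 1.5 / cajsr; jt *= jt; jt *= jt; jt *= jt;
  double denom = 1.0 + jt;
  a.jrelnp_inf = sc[SC_JREL] * 0.5 * bt * (-ical) / denom;
  a.jrelnp_tau = bt / (1.0 + 0.0123 / cajsr);
  if (a.jrelnp_tau < 0.001) a.jrelnp_tau = 0.001;
  a.jrelp_inf = sc[SC_JREL] * 0.5 * btp * (-ical) / denom;
  a.jrelp_tau = btp / (1.0 + 0.0123 / cajsr);
  if (a.jrelp_tau < 0.001) a.jrelp_tau = 0.001;
  double jca = s[S_JCA];
  double km2n = jca * 1.0;
  double nt = 1.0 + 0.002 / cass; nt *= nt; nt *= nt;
  double anca = 1.0 / (1000.0 / km2n + nt);
  a.nca_inf = anca * 1000.0 / km2n;    // = anca*k2n/km2n
  a.nca_tau = 1.0 / km2n;
}

// ------------------------------------------------------- fibroblast algebra
// currents in pA/pF; i_ext_pA is the whole-cell external current (gap), pA
void fib_algebra(const double* s, double i_ext_pA, const VDep& w, double* cur,
                 double& dv, const double* fsc = NULL) {
  static const double ones[4] = {1.0, 1.0, 1.0, 1.0};
  if (!fsc) fsc = ones;
  double v = s[F_V];
  double ekf = RTF * std::log(KO / FIB_KI);
  double enaf = RTF * std::log(NAO / FIB_NAI);
  double ikv = fsc[0] * FIB_GKV * s[F_R] * s[F_S] * (v - ekf);
  double ik1 = fsc[1] * FIB_GK1 * w.fib_k1r * (v - ekf);
  static const double nak_na = std::pow(FIB_NAI, 1.5) /
    (std::pow(FIB_NAI, 1.5) + std::pow(FIB_KMNA, 1.5));
  double inak = fsc[2] * FIB_PNAK * (KO / (KO + FIB_KMK)) * nak_na *
                (v + 150.0) / (v + 200.0);
  double ibna = fsc[3] * FIB_GBNA * (v - enaf);
  cur[0] = ikv; cur[1] = ik1; cur[2] = inak; cur[3] = ibna;
  dv = -(ikv + ik1 + inak + ibna + i_ext_pA / FIB_CAP_PF);
}

// ------------------------------------------------------ custom-cell algebra
// dens: effective conductance densities (baseline * scaling), nS/pF
// conc: fixed intracellular concentrations (nai, ki, cai), mM
// i_gap_pA: whole-cell gap-junction current entering the voltage equation, pA
void cust_algebra(const double* s, const double* dens, const double* conc,
                  double i_gap_pA, const VDep& w, double* cur, double& dv) {
  double v = s[U_V];
  double nai = conc[0], ki = conc[1], cai = conc[2];
  double ena = RTF * std::log(NAO / nai);
  double ek = RTF * std::log(KO / ki);
  double eca = 0.5 * RTF * std::log(CAO / cai);
  double eks = RTF * std::log((KO + 0.01833 * NAO) / (ki + 0.01833 * nai));
  double caact = cai * cai / (cai * cai + 1.0e-8);     // KCa Ca-sensitivity, Kd 1e-4 mM

  // hCIC channels
  cur[CH_CIC_NA] = dens[CH_CIC_NA] * s[U_CIC_M] * s[U_CIC_M] * s[U_CIC_M] *
                   s[U_CIC_H] * (v - ena);
  double kir_o = 1.0 / (1.0 + std::exp((v - ek - 10.0) / 18.0));
  cur[CH_CIC_KIR] = dens[CH_CIC_KIR] * std::sqrt(KO / 5.4) * kir_o * (v - ek);
  cur[CH_CIC_KCA] = dens[CH_CIC_KCA] * w.cic_kca_o * caact * (v - ek);
  cur[CH_CIC_TO] = dens[CH_CIC_TO] * s[U_CIC_R] * s[U_CIC_S] * (v - ek);

  // hMSC channels
  cur[CH_MSC_TO] = dens[CH_MSC_TO] * s[U_MSC_R] * s[U_MSC_S] * (v - ek);
  double rinf, rtau; g_msc_r(v, rinf, rtau);
  cur[CH_MSC_TO_SS] = dens[CH_MSC_TO_SS] * rinf * (v - ek);
  cur[CH_MSC_NA] = dens[CH_MSC_NA] * s[U_MSC_M] * s[U_MSC_M] * s[U_MSC_M] *
                   s[U_MSC_H] * (v - ena);
  cur[CH_MSC_CAL] = dens[CH_MSC_CAL] * s[U_MSC_D] * s[U_MSC_F] * (v - eca);
  cur[CH_MSC_KCA] = dens[CH_MSC_KCA] * w.msc_kca_o * caact * (v - ek);
  cur[CH_MSC_DR] = dens[CH_MSC_DR] * s[U_MSC_N] * (v - ek);

  // CF channels (MacCannell, background leak excluded by design)
  double ekf = RTF * std::log(KO / FIB_KI);
  cur[CH_CF_KV] = dens[CH_CF_KV] * s[U_CF_R] * s[U_CF_S] * (v - ekf);
  cur[CH_CF_KIR] = dens[CH_CF_KIR] * w.fib_k1r * (v - ekf);
  double nai15 = nai * std::sqrt(nai);
  cur[CH_CF_NAK] = dens[CH_CF_NAK] * (KO / (KO + FIB_KMK)) *
                   (nai15 / (nai15 + FIB_KMNA * std::sqrt(FIB_KMNA))) *
                   (v + 150.0) / (v + 200.0);

  // hCM channels (no CaMK machinery in custom cells: non-phosphorylated forms)
  cur[CH_CM_NA] = dens[CH_CM_NA] * s[U_M] * s[U_M] * s[U_M] * s[U_H] * s[U_J] * (v - ena);
  cur[CH_CM_NAL] = dens[CH_CM_NAL] * s[U_ML] * s[U_HL] * (v - ena);
  double i_i = w.aif * s[U_IF] + (1.0 - w.aif) * s[U_IS];
  cur[CH_CM_TO] = dens[CH_CM_TO] * s[U_A] * i_i * (v - ek);
  double phical = w.a2 * (cai * w.exp2vfrt - 0.341 * CAO);
  double phicana = w.a1 * (0.75 * nai * w.expvfrt - 0.75 * NAO);
  double phicak = w.a1 * (0.75 * ki * w.expvfrt - 0.75 * KO);
  double f = 0.6 * s[U_FF] + 0.4 * s[U_FS];
  double fca = w.afcaf * s[U_FCAF] + (1.0 - w.afcaf) * s[U_FCAS];
  double nca = s[U_NCA];
  double op = s[U_D] * (f * (1.0 - nca) + s[U_JCA] * fca * nca);
  cur[CH_CM_CAL] = dens[CH_CM_CAL] *
                   (phical + 0.00125 * phicana + 3.574e-4 * phicak) * op;
  double xr = w.axrf * s[U_XRF] + (1.0 - w.axrf) * s[U_XRS];
  cur[CH_CM_KR] = dens[CH_CM_KR] * std::sqrt(KO / 5.4) * xr * w.rkr * (v - ek);
  double ksca = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  cur[CH_CM_KS] = dens[CH_CM_KS] * ksca * s[U_XS1] * s[U_XS2] * (v - eks);
  cur[CH_CM_K1] = dens[CH_CM_K1] * std::sqrt(KO) * s[U_XK1] * w.rk1 * (v - ek);

  // passive cell: linear leak
  cur[CH_PASSIVE] = dens[CH_PASSIVE] * (v - (-20.0));

  double tot = 0.0;
  for (int k = 0; k < N_CUST_CHAN; k++) tot += cur[k];
  dv = -(tot + i_gap_pA / CUST_CAP_PF);
}

void cust_aux_nca(const double* s, double cai, double& inf, double& tau) {
  double km2n = s[U_JCA] * 1.0;
  double nt = 1.0 + 0.002 / cai; nt *= nt; nt *= nt;
  double anca = 1.0 / (1000.0 / km2n + nt);
  inf = anca * 1000.0 / km2n;
  tau = 1.0 / km2n;
}

// ------------------------------------------------------------ default states
// ORd endocardial model paced to rest (published near-steady values), with the
// ten Tusscher INa gates at their resting values.
void cm_default_state(double* s) {
  s[S_V] = -87.5; s[S_NAI] = 7.268; s[S_NASS] = 7.268;
  s[S_KI] = 144.65; s[S_KSS] = 144.65;
  s[S_CAI] = 8.6e-5; s[S_CASS] = 8.49e-5; s[S_CANSR] = 1.61; s[S_CAJSR] = 1.56;
  s[S_M] = 0.00165; s[S_H] = 0.749; s[S_J] = 0.6788;
  s[S_ML] = 0.00019; s[S_HL] = 0.496; s[S_HLP] = 0.266;
  s[S_A] = 0.001; s[S_IF] = 0.9996; s[S_IS] = 0.5898;
  s[S_AP] = 0.00051; s[S_IFP] = 0.9996; s[S_ISP] = 0.6419;
  s[S_D] = 2.43e-9; s[S_FF] = 1.0; s[S_FS] = 0.9107;
  s[S_FCAF] = 1.0; s[S_FCAS] = 0.9998; s[S_JCA] = 0.99998;
  s[S_NCA] = 0.00267; s[S_FFP] = 1.0; s[S_FCAFP] = 1.0;
  s[S_XRF] = 8.27e-6; s[S_XRS] = 0.4533; s[S_XS1] = 0.2707; s[S_XS2] = 0.000197;
  s[S_XK1] = 0.9968; s[S_JRELNP] = 2.54e-5; s[S_JRELP] = 3.17e-7;
  s[S_CAMKT] = 0.0124;
}

void fib_default_state(double* s) {
  s[F_V] = -49.6;
  double inf, tau;
  g_cf_r(s[F_V], inf, tau); s[F_R] = inf;
  g_cf_s(s[F_V], inf, tau); s[F_S] = inf;
}

void cust_default_state(double* s, double v0) {
  s[U_V] = v0;
  for (int g = 0; g < N_CUST_GATE; g++) {
    double inf, tau;
    CUST_GATES[g](v0, inf, tau);
    s[CUST_GATE_STATE[g]] = inf;
  }
  s[U_NCA] = 0.0;
}

// --------------------------------------------------------------- step kernel
struct SimCells {
  double cm[N_CM_STATE];
  double fib[N_FIB_STATE];
  double cust[N_CUST_STATE];
  bool has_fib, has_cust;
  int n_fib, n_cust;
  double g_fib, g_cust;          // nS per junction
  const double* sc;              // CM scales
  const double* dens;            // custom densities
  const double* conc;            // custom fixed concentrations
};

// one explicit step of size dt; returns max |dV/dt| seen at the step start
double step_cells(SimCells& c, double dt, double dtmax, double i_stim,
                  double* cur_out /* optional N_CM_CUR + extras */) {
  TabRow tr; VDep w;
  double cur[N_CM_CUR];
  double fcur[4], ucur[N_CUST_CHAN];
  double dnon[N_CM_STATE];

  // gap currents (pA), computed at step start (explicit coupling)
  double igap_fib = 0.0, igap_cust = 0.0;
  if (c.has_fib) igap_fib = c.g_fib * (c.cm[S_V] - c.fib[F_V]);
  if (c.has_cust) igap_cust = c.g_cust * (c.cm[S_V] - c.cust[U_V]);
  double i_ext = i_stim + (c.n_fib * igap_fib + c.n_cust * igap_cust) / CM_CAP_PF;

  // --- cardiomyocyte
  tr.locate(c.cm[S_V]);
  vdep_from_table(tr, w);
  cm_algebra(c.cm, c.sc, i_ext, w, cur, dnon);
  CmAux aux; cm_aux(c.cm, c.sc, cur, aux);

  double maxdv = std::fabs(dnon[S_V]);

  // --- fibroblast
  double fdv = 0.0;
  TabRow trf; VDep wf;
  if (c.has_fib) {
    trf.locate(c.fib[F_V]);
    vdep_from_table(trf, wf);
    fib_algebra(c.fib, -igap_fib, wf, fcur, fdv);
    if (std::fabs(fdv) > maxdv) maxdv = std::fabs(fdv);
  }

  // --- custom cell
  double udv = 0.0;
  TabRow tru; VDep wu;
  if (c.has_cust) {
    tru.locate(c.cust[U_V]);
    vdep_from_table(tru, wu);
    cust_algebra(c.cust, c.dens, c.conc, -igap_cust, wu, ucur, udv);
    if (std::fabs(udv) > maxdv) maxdv = std::fabs(udv);
  }

  if (cur_out) {
    std::memcpy(cur_out, cur, sizeof(double) * N_CM_CUR);
    cur_out[N_CM_CUR] = igap_cust;
    cur_out[N_CM_CUR + 1] = igap_fib;
  }

  bool fast = (dt == dtmax);

  // cardiomyocyte gates (Rush-Larsen)
  for (int g = 0; g < N_CM_GATE; g++) {
    int cidx = 3 * g;
    double inf = tr.get(cidx);
    double tau = tr.get(cidx + 1);
    double ef;
    int sidx = CM_GATE_STATE[g];
    if (sidx == S_HL || sidx == S_HLP) {
      tau *= c.sc[SC_THL];
      ef = std::exp(-dt / tau);
    } else if (fast) {
      ef = tr.get(cidx + 2);
    } else {
      ef = std::exp(-dt / tau);
    }
    c.cm[sidx] = inf + (c.cm[sidx] - inf) * ef;
  }
  // non-voltage-gated relaxations
  c.cm[S_JRELNP] = aux.jrelnp_inf + (c.cm[S_JRELNP] - aux.jrelnp_inf) *
                   std::exp(-dt / aux.jrelnp_tau);
  c.cm[S_JRELP] = aux.jrelp_inf + (c.cm[S_JRELP] - aux.jrelp_inf) *
                  std::exp(-dt / aux.jrelp_tau);
  c.cm[S_NCA] = aux.nca_inf + (c.cm[S_NCA] - aux.nca_inf) *
                std::exp(-dt / aux.nca_tau);
  // Euler for voltage, concentrations, CaMK
  c.cm[S_V] += dt * dnon[S_V];
  c.cm[S_NAI] += dt * dnon[S_NAI];
  c.cm[S_NASS] += dt * dnon[S_NASS];
  c.cm[S_KI] += dt * dnon[S_KI];
  c.cm[S_KSS] += dt * dnon[S_KSS];
  c.cm[S_CAI] += dt * dnon[S_CAI];
  c.cm[S_CASS] += dt * dnon[S_CASS];
  c.cm[S_CANSR] += dt * dnon[S_CANSR];
  c.cm[S_CAJSR] += dt * dnon[S_CAJSR];
  c.cm[S_CAMKT] += dt * dnon[S_CAMKT];

  if (c.has_fib) {
    for (int g = 0; g < N_FIB_GATE; g++) {
      int cidx = COL_FIB0 + 3 * g;
      double inf = trf.get(cidx);
      double ef = fast ? trf.get(cidx + 2) : std::exp(-dt / trf.get(cidx + 1));
      c.fib[FIB_GATE_STATE[g]] = inf + (c.fib[FIB_GATE_STATE[g]] - inf) * ef;
    }
    c.fib[F_V] += dt * fdv;
  }

  if (c.has_cust) {
    for (int g = 0; g < N_CUST_GATE; g++) {
      int cidx = COL_CUST0 + 3 * g;
      double inf = tru.get(cidx);
      double ef = fast ? tru.get(cidx + 2) : std::exp(-dt / tru.get(cidx + 1));
      c.cust[CUST_GATE_STATE[g]] = inf + (c.cust[CUST_GATE_STATE[g]] - inf) * ef;
    }
    double ninf, ntau;
    cust_aux_nca(c.cust, c.conc[2], ninf, ntau);
    c.cust[U_NCA] = ninf + (c.cust[U_NCA] - ninf) * std::exp(-dt / ntau);
    c.cust[U_V] += dt * udv;
  }

  return maxdv;
}

}  // namespace

// ============================================================ R entry points

// [[Rcpp::export(rng = false)]]
int n_cm_state_cpp() { return N_CM_STATE; }
// [[Rcpp::export(rng = false)]]
int n_cust_state_cpp() { return N_CUST_STATE; }
// [[Rcpp::export(rng = false)]]
double cm_capacitance_pf_cpp() { return CM_CAP_PF; }

// [[Rcpp::export(rng = false)]]
NumericVector cm_default_state_cpp() {
  NumericVector out(N_CM_STATE);
  cm_default_state(REAL(out));
  return out;
}
// [[Rcpp::export(rng = false)]]
NumericVector fib_default_state_cpp() {
  NumericVector out(N_FIB_STATE);
  fib_default_state(REAL(out));
  return out;
}
// [[Rcpp::export(rng = false)]]
NumericVector cust_default_state_cpp(double v0) {
  NumericVector out(N_CUST_STATE);
  cust_default_state(REAL(out), v0);
  return out;
}

// Single-evaluation RHS entry points (direct rate evaluation, no tables).
// These return full time derivatives (gates as (inf-x)/tau) plus currents.

// [[Rcpp::export(rng = false)]]
List cm_rhs_cpp(NumericVector state, NumericVector scale, double i_ext) {
  if (state.size() != N_CM_STATE) stop("cardiomyocyte state must have %d entries", N_CM_STATE);
  if (scale.size() != N_CM_SCALE) stop("scale vector must have %d entries", N_CM_SCALE);
  VDep w; vdep_direct(state[S_V], w);
  double cur[N_CM_CUR], dnon[N_CM_STATE];
  cm_algebra(REAL(state), REAL(scale), i_ext, w, cur, dnon);
  CmAux aux; cm_aux(REAL(state), REAL(scale), cur, aux);
  NumericVector ds(N_CM_STATE);
  for (int i = 0; i < N_CM_STATE; i++) ds[i] = dnon[i];
  for (int g = 0; g < N_CM_GATE; g++) {
    double inf, tau;
    CM_GATES[g](state[S_V], inf, tau);
    int sidx = CM_GATE_STATE[g];
    if (sidx == S_HL || sidx == S_HLP) tau *= scale[SC_THL];
    ds[sidx] = (inf - state[sidx]) / tau;
  }
  ds[S_JRELNP] = (aux.jrelnp_inf - state[S_JRELNP]) / aux.jrelnp_tau;
  ds[S_JRELP] = (aux.jrelp_inf - state[S_JRELP]) / aux.jrelp_tau;
  ds[S_NCA] = (aux.nca_inf - state[S_NCA]) / aux.nca_tau;
  NumericVector cv(N_CM_CUR);
  for (int i = 0; i < N_CM_CUR; i++) cv[i] = cur[i];
  return List::create(_["deriv"] = ds, _["currents"] = cv);
}

// [[Rcpp::export(rng = false)]]
List fib_rhs_cpp(NumericVector state, double i_ext_pa, NumericVector fscale) {
  if (state.size() != N_FIB_STATE) stop("fibroblast state must have %d entries", N_FIB_STATE);
  if (fscale.size() != 4) stop("fscale must have 4 entries (kv, kir, nak, bna)");
  VDep w; vdep_direct(state[F_V], w);
  double cur[4], dv;
  fib_algebra(REAL(state), i_ext_pa, w, cur, dv, REAL(fscale));
  NumericVector ds(N_FIB_STATE);
  ds[F_V] = dv;
  for (int g = 0; g < N_FIB_GATE; g++) {
    double inf, tau;
    FIB_GATES[g](state[F_V], inf, tau);
    ds[FIB_GATE_STATE[g]] = (inf - state[FIB_GATE_STATE[g]]) / tau;
  }
  NumericVector cv = NumericVector::create(
    _["i_kv"] = cur[0], _["i_kir"] = cur[1], _["i_nak"] = cur[2], _["i_bna"] = cur[3]);
  return List::create(_["deriv"] = ds, _["currents"] = cv);
}

// [[Rcpp::export(rng = false)]]
List cust_rhs_cpp(NumericVector state, NumericVector dens, NumericVector conc,
                  double i_gap_pa) {
  if (state.size() != N_CUST_STATE) stop("custom-cell state must have %d entries", N_CUST_STATE);
  if (dens.size() != N_CUST_CHAN) stop("density vector must have %d entries", N_CUST_CHAN);
  if (conc.size() != 3) stop("conc must be (nai, ki, cai)");
  VDep w; vdep_direct(state[U_V], w);
  double cur[N_CUST_CHAN], dv;
  cust_algebra(REAL(state), REAL(dens), REAL(conc), i_gap_pa, w, cur, dv);
  NumericVector ds(N_CUST_STATE);
  ds[U_V] = dv;
  for (int g = 0; g < N_CUST_GATE; g++) {
    double inf, tau;
    CUST_GATES[g](state[U_V], inf, tau);
    ds[CUST_GATE_STATE[g]] = (inf - state[CUST_GATE_STATE[g]]) / tau;
  }
  double ninf, ntau;
  cust_aux_nca(REAL(state), conc[2], ninf, ntau);
  ds[U_NCA] = (ninf - state[U_NCA]) / ntau;
  NumericVector cv(N_CUST_CHAN);
  for (int i = 0; i < N_CUST_CHAN; i++) cv[i] = cur[i];
  return List::create(_["deriv"] = ds, _["currents"] = cv);
}

// Coupled paced simulation on a fixed 1-ms output grid.
//
// cm_scale    : N_CM_SCALE multipliers (phenotype)
// n_fib/g_fib : fibroblast count and per-junction conductance (nS); n_fib 0 disables
// cust_dens   : length-0 (no custom cell) or N_CUST_CHAN effective densities
// g_cust      : custom gap conductance (nS); n_cust identical lumped cells
// conc        : fixed custom intracellular (nai, ki, cai)
// n_beats, cl : pacing beats and cycle length (ms); stimulus at beat start
// record_from_beat: 1-based beat index at which 1-ms recording starts
// [[Rcpp::export(rng = false)]]
List sim_run_cpp(NumericVector cm_scale, int n_fib, double g_fib,
                 NumericVector cust_dens, double g_cust, int n_cust,
                 NumericVector conc, int n_beats, double cl,
                 double stim_amp, double stim_dur, double dtmax,
                 int record_from_beat, bool record_currents,
                 NumericVector init_cm, NumericVector init_fib,
                 NumericVector init_cust, double cust_v0) {
  if (cm_scale.size() != N_CM_SCALE) stop("scale vector must have %d entries", N_CM_SCALE);
  if (!g_tab.built || g_tab.dtmax != dtmax) build_table(dtmax);

  SimCells c;
  c.has_fib = n_fib > 0;
  c.has_cust = cust_dens.size() == N_CUST_CHAN;
  if (cust_dens.size() != 0 && !c.has_cust)
    stop("custom density vector must have %d entries", N_CUST_CHAN);
  c.n_fib = n_fib; c.n_cust = c.has_cust ? n_cust : 0;
  c.g_fib = g_fib; c.g_cust = g_cust;
  c.sc = REAL(cm_scale);
  c.dens = c.has_cust ? REAL(cust_dens) : NULL;
  static const double default_conc[3] = {10.0, 140.0, 1.0e-4};
  c.conc = conc.size() == 3 ? REAL(conc) : default_conc;

  if (init_cm.size() == N_CM_STATE) std::memcpy(c.cm, REAL(init_cm), sizeof(c.cm));
  else cm_default_state(c.cm);
  if (init_fib.size() == N_FIB_STATE) std::memcpy(c.fib, REAL(init_fib), sizeof(c.fib));
  else fib_default_state(c.fib);
  if (c.has_cust) {
    if (init_cust.size() == N_CUST_STATE) std::memcpy(c.cust, REAL(init_cust), sizeof(c.cust));
    else cust_default_state(c.cust, cust_v0);
  } else {
    cust_default_state(c.cust, cust_v0);
  }

  if (record_from_beat < 1) record_from_beat = 1;
  if (record_from_beat > n_beats) record_from_beat = n_beats;
  int cl_i = (int)cl;
  if (std::fabs(cl - cl_i) > 1e-9) stop("cycle length must be an integer number of ms");
  int n_rec = (n_beats - record_from_beat + 1) * cl_i + 1;

  NumericVector t_out(n_rec), vm_out(n_rec), cai_out(n_rec);
  NumericVector vcust_out(c.has_cust ? n_rec : 0), vfib_out(c.has_fib ? n_rec : 0);
  NumericVector igapc_out(c.has_cust ? n_rec : 0), igapf_out(c.has_fib ? n_rec : 0);
  NumericMatrix cur_out(record_currents ? n_rec : 0,
                        record_currents ? (N_CM_CUR + 2) : 0);

  double curbuf[N_CM_CUR + 2];
  long nsteps = 0;
  int rec = 0;

  auto record_now = [&](double tglob) {
    t_out[rec] = tglob;
    vm_out[rec] = c.cm[S_V];
    cai_out[rec] = c.cm[S_CAI];
    if (c.has_cust) {
      vcust_out[rec] = c.cust[U_V];
      igapc_out[rec] = c.g_cust * (c.cm[S_V] - c.cust[U_V]);
    }
    if (c.has_fib) {
      vfib_out[rec] = c.fib[F_V];
      igapf_out[rec] = c.g_fib * (c.cm[S_V] - c.fib[F_V]);
    }
    if (record_currents) {
      // currents re-evaluated at the recorded state
      VDep w; TabRow tr; tr.locate(c.cm[S_V]); vdep_from_table(tr, w);
      double dnon[N_CM_STATE];
      double igf = c.has_fib ? c.g_fib * (c.cm[S_V] - c.fib[F_V]) : 0.0;
      double igc = c.has_cust ? c.g_cust * (c.cm[S_V] - c.cust[U_V]) : 0.0;
      double iext = (c.n_fib * igf + c.n_cust * igc) / CM_CAP_PF;
      cm_algebra(c.cm, c.sc, iext, w, curbuf, dnon);
      curbuf[N_CM_CUR] = igc;
      curbuf[N_CM_CUR + 1] = igf;
      for (int k = 0; k < N_CM_CUR + 2; k++) cur_out(rec, k) = curbuf[k];
    }
    rec++;
  };

  const double DT_MIN = 0.001;
  for (int beat = 0; beat < n_beats; beat++) {
    bool recording = (beat + 1) >= record_from_beat;
    double t = 0.0;
    int next_ms = 1;
    if (recording) record_now(beat * cl);   // sample at stimulus onset
    while (t < cl - 1e-9) {
      double boundary = recording ? (double)next_ms : cl;
      if (t < stim_dur && stim_dur < boundary) boundary = stim_dur;
      double i_stim = (t < stim_dur - 1e-12) ? stim_amp : 0.0;
      double dt = dtmax;
      if (t + dt > boundary) dt = boundary - t;
      // take the step; if it was too coarse during a fast phase, rewind and
      // redo it in refined substeps targeting ~0.1 mV of voltage change each
      SimCells saved = c;
      double maxdv = step_cells(c, dt, dtmax, i_stim, NULL);
      nsteps++;
      if (maxdv * dt > 0.2 && dt > DT_MIN) {
        c = saved;
        double dts = 0.1 / maxdv;
        if (dts < DT_MIN) dts = DT_MIN;
        int nsub = (int)std::ceil(dt / dts);
        double dtn = dt / nsub;
        for (int k = 0; k < nsub; k++) {
          step_cells(c, dtn, dtmax, i_stim, NULL);
          nsteps++;
        }
      }
      t += dt;
      if (recording && t >= next_ms - 1e-9) {
        // interior 1-ms samples; the beat-end sample is the next beat's onset
        if (next_ms < cl_i) record_now(beat * cl + next_ms);
        next_ms++;
      }
    }
    if (recording && beat == n_beats - 1) record_now((double)n_beats * cl);
  }

  NumericVector fin_cm(N_CM_STATE), fin_fib(N_FIB_STATE), fin_cust(N_CUST_STATE);
  std::memcpy(REAL(fin_cm), c.cm, sizeof(c.cm));
  std::memcpy(REAL(fin_fib), c.fib, sizeof(c.fib));
  std::memcpy(REAL(fin_cust), c.cust, sizeof(c.cust));

  List out = List::create(
    _["time"] = t_out, _["vm"] = vm_out, _["cai"] = cai_out,
    _["vm_custom"] = vcust_out, _["vm_fib"] = vfib_out,
    _["igap_custom"] = igapc_out, _["igap_fib"] = igapf_out,
    _["currents"] = cur_out,
    _["final_cm"] = fin_cm, _["final_fib"] = fin_fib, _["final_cust"] = fin_cust,
    _["n_steps"] = (double)nsteps);
  return out;
}

// Relax an uncoupled custom cell from v0 for t_ms; used to find its resting
// state before coupling (gates start at steady state for v0).
// [[Rcpp::export(rng = false)]]
NumericVector cust_relax_cpp(NumericVector dens, NumericVector conc, double v0,
                             double t_ms, double dt) {
  if (dens.size() != N_CUST_CHAN) stop("density vector must have %d entries", N_CUST_CHAN);
  static const double default_conc[3] = {10.0, 140.0, 1.0e-4};
  const double* cc = conc.size() == 3 ? REAL(conc) : default_conc;
  double s[N_CUST_STATE];
  cust_default_state(s, v0);
  double t = 0.0;
  double cur[N_CUST_CHAN];
  while (t < t_ms) {
    double h = dt;
    if (t + h > t_ms) h = t_ms - t;
    VDep w; vdep_direct(s[U_V], w);
    double dv;
    cust_algebra(s, REAL(dens), cc, 0.0, w, cur, dv);
    if (std::fabs(dv) * h > 0.2) h = 0.2 / std::fabs(dv);
    for (int g = 0; g < N_CUST_GATE; g++) {
      double inf, tau;
      CUST_GATES[g](s[U_V], inf, tau);
      int si = CUST_GATE_STATE[g];
      s[si] = inf + (s[si] - inf) * std::exp(-h / tau);
    }
    double ninf, ntau;
    cust_aux_nca(s, cc[2], ninf, ntau);
    s[U_NCA] = ninf + (s[U_NCA] - ninf) * std::exp(-h / ntau);
    s[U_V] += h * dv;
    t += h;
  }
  NumericVector out(N_CUST_STATE);
  std::memcpy(REAL(out), s, sizeof(s));
  return out;
}
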