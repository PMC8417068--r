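// Modified O'Hara-Rudy (2011) human ventricular myocyte with the ten Tusscher
// (2006) fast sodium current, plus pacing drivers and a 1-D monodomain cable.
//
// State layout (38 variables):
//  0 v    1 nai  2 nass 3 ki   4 kss  5 cai  6 cass 7 cansr 8 cajsr
//  9 m   10 h   11 j                         (ten Tusscher INa gates)
// 12 mL  13 hL  14 hLp                       (late sodium)
// 15 a   16 iF  17 iS  18 ap  19 iFp 20 iSp  (transient outward)
// 21 d   22 ff  23 fs  24 fcaf 25 fcas 26 jca 27 nca 28 ffp 29 fcafp (L-type)
// 30 xrf 31 xrs                              (rapid delayed rectifier)
// 32 xs1 33 xs2                              (slow delayed rectifier)
// 34 xk1                                     (inward rectifier)
// 35 Jrelnp 36 Jrelp                         (SR release fluxes)
// 37 CaMKt                                   (CaMK trap)
//
// Parameter layout (17 doubles):
//  0 mult INa   1 mult INaL  2 mult Ito  3 mult IpCa  4 mult IKr  5 mult IKs
//  6 mult IK1   7 mult INaCa 8 mult INaK 9 mult IKb  10 mult Jrel 11 mult Jup
// 12 mult CMDN 13 layer (0 endo, 1 mid, 2 epi)
// 14 stim amplitude (uA/uF, negative depolarizes) 15 stim duration (ms)
// 16 mult ICaL (drug block on the L-type channel complex)
//
// Multipliers combine the sex/layer activity-table factor with any
// (1 - beta) drug block; they scale the baseline ENDOCARDIAL conductances.
// Only the L-type permeability (x2.5 mid, x1.2 epi) and the epicardial Ito
// inactivation-tau modifier retain built-in layer dependence, because those
// are the only layer-varying pieces not covered by the activity table.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 38;

// physical constants
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;

// cell geometry
static const double Lcell = 0.01, rad = 0.0011;
static const double vcell = 1000.0 * 3.14 * rad * rad * Lcell;
static const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell;
static const double vnsr = 0.0552 * vcell;
static const double vjsr = 0.0048 * vcell;
static const double vss  = 0.02  * vcell;

// CaMK
static const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
static const double CaMKo = 0.05, KmCaM = 0.0015;

static inline double rl(double x, double xinf, double tau, double dt) {
  // Rush-Larsen exponential update for gates of the form dx = (xinf - x)/tau
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

// advance one cell state by dt; Ist is the stimulus current (uA/uF) active
// over the step, dv_diff an externally supplied diffusion term (mV/ms).
// Returns dV/dt actually applied (for step-size control and upstroke checks).
static double step_cell(double* y, const double* p, double dt, double Ist,
                        double dv_diff) {
  double v = y[0];
  const double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
  const double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
  const int layer = (int)(p[13] + 0.5);
  const bool epi = (layer == 2), mid = (layer == 1);

  // CaMK
  const double CaMKb = CaMKo * (1.0 - y[37]) / (1.0 + KmCaM / cass);
  const double CaMKa = CaMKb + y[37];
  const double dCaMKt = aCaMK * CaMKb * (CaMKb + y[37]) - bCaMK * y[37];

  // reversal potentials
  const double ENa = (Rgas * Temp / Frdy) * std::log(nao / nai);
  const double EK  = (Rgas * Temp / Frdy) * std::log(ko / ki);
  const double PKNa = 0.01833;
  const double EKs = (Rgas * Temp / Frdy) *
                     std::log((ko + PKNa * nao) / (ki + PKNa * nai));
  double vm = v;
  if (std::fabs(vm) < 1e-4) vm = (vm >= 0.0) ? 1e-4 : -1e-4;  // GHK guard
  const double vffrt = vm * Frdy * Frdy / (Rgas * Temp);
  const double vfrt  = vm * Frdy / (Rgas * Temp);

  // --- fast sodium (ten Tusscher 2006) -----------------------------------
  const double mss_tt = 1.0 / std::pow(1.0 + std::exp((-56.86 - v) / 9.03), 2.0);
  const double am = 1.0 / (1.0 + std::exp((-60.0 - v) / 5.0));
  const double bm = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
                    0.1 / (1.0 + std::exp((v - 50.0) / 200.0));
  const double taum_tt = am * bm;
  const double hss_tt = 1.0 / std::pow(1.0 + std::exp((v + 71.55) / 7.43), 2.0);
  double ah, bh, aj, bj;
  if (v >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(v + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
    aj = (-2.5428e4 * std::exp(0.2444 * v) - 6.948e-6 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * v) /
         (1.0 + std::exp(-0.1378 * (v + 40.14)));
  }
  const double tauh_tt = 1.0 / (ah + bh);
  const double tauj_tt = 1.0 / (aj + bj);
  const double GNa = 14.838 * p[0];
  const double INa = GNa * y[9] * y[9] * y[9] * y[10] * y[11] * (v - ENa);

  // --- late sodium -------------------------------------------------------
  const double mLss = 1.0 / (1.0 + std::exp((-(v + 42.85)) / 5.264));
  const double tmL = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                            8.552 * std::exp(-(v + 77.42) / 5.955));
  const double hLss = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  const double thL = 200.0;
  const double hLssp = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  const double thLp = 3.0 * thL;
  const double GNaL = 0.0075 * p[1];
  const double fINaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double INaL = GNaL * (v - ENa) * y[12] *
                      ((1.0 - fINaLp) * y[13] + fINaLp * y[14]);

  // --- transient outward -------------------------------------------------
  const double ass = 1.0 / (1.0 + std::exp((-(v - 14.34)) / 14.82));
  const double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
                              3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  const double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  const double delta_epi = epi ? 1.0 - 0.95 / (1.0 + std::exp((v + 70.0) / 5.0)) : 1.0;
  double tiF = 4.562 + 1.0 / (0.3933 * std::exp((-(v + 100.0)) / 100.0) +
                              0.08004 * std::exp((v + 50.0) / 16.59));
  double tiS = 23.62 + 1.0 / (0.001416 * std::exp((-(v + 96.52)) / 59.05) +
                              1.780e-8 * std::exp((v + 114.1) / 8.079));
  tiF *= delta_epi; tiS *= delta_epi;
  const double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  const double AiS = 1.0 - AiF;
  const double assp = 1.0 / (1.0 + std::exp((-(v - 24.34)) / 14.82));
  const double dti_develop = 1.354 + 1.0e-4 / (std::exp((v - 167.4) / 15.89) +
                                               std::exp(-(v - 12.23) / 0.2154));
  const double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  const double tiFp = dti_develop * dti_recover * tiF;
  const double tiSp = dti_develop * dti_recover * tiS;
  const double i_gate  = AiF * y[16] + AiS * y[17];
  const double ip_gate = AiF * y[19] + AiS * y[20];
  const double Gto = 0.02 * p[2];
  const double fItop = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double Ito = Gto * (v - EK) *
                     ((1.0 - fItop) * y[15] * i_gate + fItop * y[18] * ip_gate);

  // --- L-type calcium ----------------------------------------------------
  const double dss = 1.0 / (1.0 + std::exp((-(v + 3.940)) / 4.230));
  const double td = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                                 std::exp(0.09 * (v + 14.0)));
  const double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  const double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                                  0.0045 * std::exp((v + 20.0) / 10.0));
  const double tfs = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                                     0.000035 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 0.4;
  const double f_gate = Aff * y[22] + Afs * y[23];
  const double fcass = fss;
  const double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                                    0.04 * std::exp((v - 4.0) / 7.0));
  const double tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                                      0.00012 * std::exp(v / 7.0));
  const double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  const double Afcas = 1.0 - Afcaf;
  const double fca_gate = Afcaf * y[24] + Afcas * y[25];
  const double tjca = 75.0;
  const double tffp = 2.5 * tff;
  const double fp_gate = Aff * y[28] + Afs * y[23];
  const double tfcafp = 2.5 * tfcaf;
  const double fcap_gate = Afcaf * y[29] + Afcas * y[25];
  const double Kmn = 0.002, k2n = 1000.0;
  const double km2n = y[26] * 1.0;
  const double anca = 1.0 / (k2n / km2n + std::pow(1.0 + Kmn / cass, 4.0));
  const double PhiCaL = 4.0 * vffrt * (cass * std::exp(2.0 * vfrt) - 0.341 * cao) /
                        (std::exp(2.0 * vfrt) - 1.0);
  const double PhiCaNa = 1.0 * vffrt * (0.75 * nass * std::exp(vfrt) - 0.75 * nao) /
                         (std::exp(vfrt) - 1.0);
  const double PhiCaK = 1.0 * vffrt * (0.75 * kss * std::exp(vfrt) - 0.75 * ko) /
                        (std::exp(vfrt) - 1.0);
  // baseline endo permeability with built-in layer factors; p[16] carries the
  // L-type multiplier (drug block (1 - beta_CaL); the activity table has no ICaL row)
  const double PCa = 0.0001 * (mid ? 2.5 : (epi ? 1.2 : 1.0)) * p[16];
  const double PCap = 1.1 * PCa;
  const double PCaNa = 0.00125 * PCa;
  const double PCaK = 3.574e-4 * PCa;
  const double PCaNap = 0.00125 * PCap;
  const double PCaKp = 3.574e-4 * PCap;
  const double fICaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double d_g = y[21], nca = y[27], jca_g = y[26];
  const double ICaL = (1.0 - fICaLp) * PCa * PhiCaL * d_g *
                          (f_gate * (1.0 - nca) + jca_g * fca_gate * nca) +
                      fICaLp * PCap * PhiCaL * d_g *
                          (fp_gate * (1.0 - nca) + jca_g * fcap_gate * nca);
  const double ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * d_g *
                           (f_gate * (1.0 - nca) + jca_g * fca_gate * nca) +
                       fICaLp * PCaNap * PhiCaNa * d_g *
                           (fp_gate * (1.0 - nca) + jca_g * fcap_gate * nca);
  const double ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * d_g *
                          (f_gate * (1.0 - nca) + jca_g * fca_gate * nca) +
                      fICaLp * PCaKp * PhiCaK * d_g *
                          (fp_gate * (1.0 - nca) + jca_g * fcap_gate * nca);

  // --- rapid delayed rectifier ------------------------------------------
  const double xrss = 1.0 / (1.0 + std::exp((-(v + 8.337)) / 6.789));
  const double txrf = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                                     4.123e-5 * std::exp((-(v - 47.78)) / 20.38));
  const double txrs = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                                     1.128e-5 * std::exp((-(v - 29.74)) / 25.94));
  const double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  const double Axrs = 1.0 - Axrf;
  const double xr = Axrf * y[30] + Axrs * y[31];
  const double rkr = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
                     1.0 / (1.0 + std::exp((v - 10.0) / 30.0));
  const double GKr = 0.046 * p[4];
  const double IKr = GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // --- slow delayed rectifier -------------------------------------------
  const double xs1ss = 1.0 / (1.0 + std::exp((-(v + 11.60)) / 8.932));
  const double txs1 = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                                     0.001292 * std::exp((-(v + 210.0)) / 230.0));
  const double xs2ss = xs1ss;
  const double txs2 = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                             0.0193 * std::exp((-(v + 66.54)) / 31.0));
  const double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  const double GKs = 0.0034 * p[5];
  const double IKs = GKs * KsCa * y[32] * y[33] * (v - EKs);

  // --- inward rectifier --------------------------------------------------
  const double xk1ss = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                             (1.5692 * ko + 3.8115)));
  const double txk1 = 122.2 / (std::exp((-(v + 127.2)) / 20.36) +
                               std::exp((v + 236.8) / 69.33));
  const double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  const double GK1 = 0.1908 * p[6];
  const double IK1 = GK1 * std::sqrt(ko) * rk1 * y[34] * (v - EK);

  // --- sodium-calcium exchange ------------------------------------------
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
  const double qna = 0.5224, qca = 0.1670;
  const double hca = std::exp(qca * vfrt), hna = std::exp(qna * vfrt);
  const double Gncx = 0.0008 * p[7];
  const double KmCaAct = 150.0e-6;
  double INaCa_i, INaCa_ss;
  {
    const double h1 = 1.0 + nai / kna3 * (1.0 + hna);
    const double h2 = (nai * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
    const double h5 = nai * nai / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon;
    const double k2 = kcaoff;
    const double k3p = h9 * wca;
    const double k3pp = h8 * wnaca;
    const double k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca;
    const double k4pp = h2 * wnaca;
    const double k4 = k4p + k4pp;
    const double k5 = kcaoff;
    const double k6 = h6 * cai * kcaon;
    const double k7 = h5 * h2 * wna;
    const double k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double E1 = x1 / (x1 + x2 + x3 + x4);
    const double E2 = x2 / (x1 + x2 + x3 + x4);
    const double E3 = x3 / (x1 + x2 + x3 + x4);
    const double E4 = x4 / (x1 + x2 + x3 + x4);
    const double allo = 1.0 / (1.0 + std::pow(KmCaAct / cai, 2.0));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_i = 0.8 * Gncx * allo * (1.0 * JncxNa + 2.0 * JncxCa);
  }
  {
    const double h1 = 1.0 + nass / kna3 * (1.0 + hna);
    const double h2 = (nass * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
    const double h5 = nass * nass / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon;
    const double k2 = kcaoff;
    const double k3p = h9 * wca;
    const double k3pp = h8 * wnaca;
    const double k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca;
    const double k4pp = h2 * wnaca;
    const double k4 = k4p + k4pp;
    const double k5 = kcaoff;
    const double k6 = h6 * cass * kcaon;
    const double k7 = h5 * h2 * wna;
    const double k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double E1 = x1 / (x1 + x2 + x3 + x4);
    const double E2 = x2 / (x1 + x2 + x3 + x4);
    const double E3 = x3 / (x1 + x2 + x3 + x4);
    const double E4 = x4 / (x1 + x2 + x3 + x4);
    const double allo = 1.0 / (1.0 + std::pow(KmCaAct / cass, 2.0));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_ss = 0.2 * Gncx * allo * (1.0 * JncxNa + 2.0 * JncxCa);
  }

  // --- sodium-potassium pump --------------------------------------------
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    const double Knai = Knai0 * std::exp(delta * vfrt / 3.0);
    const double Knao = Knao0 * std::exp((1.0 - delta) * vfrt / 3.0);
    const double Kki = 0.5, Kko = 0.3582;
    const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
    const double H = 1.0e-7, eP = 4.2, Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
    const double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
    const double a1 = k1p * std::pow(nai / Knai, 3.0) /
                      (std::pow(1.0 + nai / Knai, 3.0) + std::pow(1.0 + ki / Kki, 2.0) - 1.0);
    const double b1 = k1m * MgADP;
    const double a2 = k2p;
    const double b2 = k2m * std::pow(nao / Knao, 3.0) /
                      (std::pow(1.0 + nao / Knao, 3.0) + std::pow(1.0 + ko / Kko, 2.0) - 1.0);
    const double a3 = k3p * std::pow(ko / Kko, 2.0) /
                      (std::pow(1.0 + nao / Knao, 3.0) + std::pow(1.0 + ko / Kko, 2.0) - 1.0);
    const double b3 = k3m * P * H / (1.0 + MgATP / Kmgatp);
    const double a4 = k4p * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
    const double b4 = k4m * std::pow(ki / Kki, 2.0) /
                      (std::pow(1.0 + nai / Knai, 3.0) + std::pow(1.0 + ki / Kki, 2.0) - 1.0);
    const double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    const double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    const double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    const double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b1 * a4;
    const double E1 = x1 / (x1 + x2 + x3 + x4);
    const double E2 = x2 / (x1 + x2 + x3 + x4);
    const double E3 = x3 / (x1 + x2 + x3 + x4);
    const double E4 = x4 / (x1 + x2 + x3 + x4);
    const double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    const double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    INaK = 30.0 * p[8] * (1.0 * JnakNa + 1.0 * JnakK);
  }

  // --- background and pump currents -------------------------------------
  const double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  const double IKb = 0.003 * p[9] * xkb * (v - EK);
  const double INab = 3.75e-10 * vffrt * (nai * std::exp(vfrt) - nao) /
                      (std::exp(vfrt) - 1.0);
  const double ICab = 2.5e-8 * 4.0 * vffrt *
                      (cai * std::exp(2.0 * vfrt) - 0.341 * cao) /
                      (std::exp(2.0 * vfrt) - 1.0);
  const double IpCa = 0.0005 * p[3] * cai / (0.0005 + cai);

  // --- SR fluxes ---------------------------------------------------------
  const double bt = 4.75;
  const double a_rel = 0.5 * bt;
  double Jrel_inf = a_rel * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  const double btp = 1.25 * bt;
  const double a_relp = 0.5 * btp;
  double Jrel_infp = a_relp * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  const double fJrelp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double Jrel = p[10] * ((1.0 - fJrelp) * y[35] + fJrelp * y[36]);

  const double Jupnp = 0.004375 * cai / (cai + 0.00092);
  const double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  const double fJupp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double Jleak = 0.0039375 * cansr / 15.0;
  const double Jup = p[11] * ((1.0 - fJupp) * Jupnp + fJupp * Jupp) - Jleak;
  const double Jtr = (cansr - cajsr) / 100.0;

  const double JdiffNa = (nass - nai) / 2.0;
  const double JdiffK = (kss - ki) / 2.0;
  const double Jdiff = (cass - cai) / 0.2;

  // --- membrane potential ------------------------------------------------
  const double Iion = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                      INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab;
  const double dv = -(Iion + Ist) + dv_diff;

  // --- concentration derivatives ----------------------------------------
  const double dnai = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
                          (Frdy * vmyo) + JdiffNa * vss / vmyo;
  const double dnass = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  const double dki = -(Ito + IKr + IKs + IK1 + IKb + Ist - 2.0 * INaK) * Acap /
                         (Frdy * vmyo) + JdiffK * vss / vmyo;
  const double dkss = -ICaK * Acap / (Frdy * vss) - JdiffK;
  const double cmdnmax = 0.05 * p[12], kmcmdn = 0.00238;
  const double trpnmax = 0.07, kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087;
  const double BSLmax = 1.124, KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;
  const double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / std::pow(kmcmdn + cai, 2.0) +
                             trpnmax * kmtrpn / std::pow(kmtrpn + cai, 2.0));
  const double dcai = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                                  (2.0 * Frdy * vmyo) -
                              Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  const double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / std::pow(KmBSR + cass, 2.0) +
                              BSLmax * KmBSL / std::pow(KmBSL + cass, 2.0));
  const double dcass = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss) +
                                Jrel * vjsr / vss - Jdiff);
  const double dcansr = Jup - Jtr * vjsr / vnsr;
  const double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / std::pow(kmcsqn + cajsr, 2.0));
  const double dcajsr = Bcajsr * (Jtr - Jrel);

  // --- update ------------------------------------------------------------
  y[0] = v + dt * dv;
  y[1] = nai + dt * dnai;
  y[2] = nass + dt * dnass;
  y[3] = ki + dt * dki;
  y[4] = kss + dt * dkss;
  y[5] = cai + dt * dcai;
  y[6] = cass + dt * dcass;
  y[7] = cansr + dt * dcansr;
  y[8] = cajsr + dt * dcajsr;
  y[9]  = rl(y[9],  mss_tt, taum_tt, dt);
  y[10] = rl(y[10], hss_tt, tauh_tt, dt);
  y[11] = rl(y[11], hss_tt, tauj_tt, dt);  // TT06: j_inf = h_inf
  y[12] = rl(y[12], mLss, tmL, dt);
  y[13] = rl(y[13], hLss, thL, dt);
  y[14] = rl(y[14], hLssp, thLp, dt);
  y[15] = rl(y[15], ass, ta, dt);
  y[16] = rl(y[16], iss, tiF, dt);
  y[17] = rl(y[17], iss, tiS, dt);
  y[18] = rl(y[18], assp, ta, dt);
  y[19] = rl(y[19], iss, tiFp, dt);
  y[20] = rl(y[20], iss, tiSp, dt);
  y[21] = rl(y[21], dss, td, dt);
  y[22] = rl(y[22], fss, tff, dt);
  y[23] = rl(y[23], fss, tfs, dt);
  y[24] = rl(y[24], fcass, tfcaf, dt);
  y[25] = rl(y[25], fcass, tfcas, dt);
  y[26] = rl(y[26], fcass, tjca, dt);
  // nca: dnca = anca*k2n - nca*km2n, exact exponential update
  if (km2n > 1e-12) {
    const double target = anca * k2n / km2n;
    y[27] = target + (nca - target) * std::exp(-km2n * dt);
  } else {
    y[27] = nca + dt * (anca * k2n - nca * km2n);
  }
  y[28] = rl(y[28], fss, tffp, dt);
  y[29] = rl(y[29], fcass, tfcafp, dt);
  y[30] = rl(y[30], xrss, txrf, dt);
  y[31] = rl(y[31], xrss, txrs, dt);
  y[32] = rl(y[32], xs1ss, txs1, dt);
  y[33] = rl(y[33], xs2ss, txs2, dt);
  y[34] = rl(y[34], xk1ss, txk1, dt);
  y[35] = rl(y[35], Jrel_inf, tau_rel, dt);
  y[36] = rl(y[36], Jrel_infp, tau_relp, dt);
  y[37] = y[37] + dt * dCaMKt;

  return dv;
}

// initial state: resting potential with gates at steady state
// [[Rcpp::export]]
NumericVector cell_initial_state_cpp() {
  NumericVector y(NSTATE);
  const double v = -87.0;
  y[0] = v;
  y[1] = 7.0; y[2] = 7.0; y[3] = 145.0; y[4] = 145.0;
  y[5] = 1.0e-4; y[6] = 1.0e-4; y[7] = 1.2; y[8] = 1.2;
  y[9] = 1.0 / std::pow(1.0 + std::exp((-56.86 - v) / 9.03), 2.0);
  y[10] = 1.0 / std::pow(1.0 + std::exp((v + 71.55) / 7.43), 2.0);
  y[11] = y[10];
  y[12] = 1.0 / (1.0 + std::exp((-(v + 42.85)) / 5.264));
  y[13] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  y[14] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  y[15] = 1.0 / (1.0 + std::exp((-(v - 14.34)) / 14.82));
  y[16] = y[17] = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  y[18] = 1.0 / (1.0 + std::exp((-(v - 24.34)) / 14.82));
  y[19] = y[20] = y[16];
  y[21] = 1.0 / (1.0 + std::exp((-(v + 3.940)) / 4.230));
  y[22] = y[23] = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  y[24] = y[25] = y[26] = y[22];
  y[27] = 0.0;
  y[28] = y[22]; y[29] = y[22];
  y[30] = y[31] = 1.0 / (1.0 + std::exp((-(v + 8.337)) / 6.789));
  y[32] = y[33] = 1.0 / (1.0 + std::exp((-(v + 11.60)) / 8.932));
  y[34] = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) / (1.5692 * ko + 3.8115)));
  y[35] = y[36] = 0.0;
  y[37] = 0.0;
  return y;
}

struct SolverOpts {
  double dt_fine, dt_coarse, vdot_switch;
};

// advance one cell from time t0 to t1 given sorted stimulus onset times,
// writing nothing; used as the inner kernel by the exported drivers.
static void advance_cell(double* y, const double* p, double t0, double t1,
                         const std::vector<double>& stims, const SolverOpts& o,
                         double& dvdt_prev) {
  const double stim_amp = p[14], stim_dur = p[15];
  double t = t0;
  while (t < t1 - 1e-12) {
    // stimulus active?
    double Ist = 0.0;
    bool near_stim = false;
    double next_edge = t1;
    for (size_t k = 0; k < stims.size(); ++k) {
      const double s = stims[k];
      if (t >= s - 1e-12 && t < s + stim_dur - 1e-12) {
        Ist = stim_amp;
        if (s + stim_dur < next_edge) next_edge = s + stim_dur;
      } else if (s > t && s < next_edge) {
        next_edge = s;  // do not step across a stimulus onset
      }
      if (t >= s - 0.5 && t <= s + stim_dur + 5.0) near_stim = true;
    }
    double dt = (near_stim || std::fabs(dvdt_prev) > o.vdot_switch)
                    ? o.dt_fine : o.dt_coarse;
    if (t + dt > next_edge) dt = next_edge - t;
    if (dt < 1e-9) dt = 1e-9;
    dvdt_prev = step_cell(y, p, dt, Ist, 0.0);
    t += dt;
  }
}

// run a single cell with explicit stimulus times, sampling V at sample_dt
// [[Rcpp::export]]
List cell_run_cpp(NumericVector params, NumericVector state,
                  NumericVector stim_times, double t_end, double sample_dt,
                  double dt_fine, double dt_coarse, double vdot_switch) {
  std::vector<double> y(state.begin(), state.end());
  std::vector<double> stims(stim_times.begin(), stim_times.end());
  SolverOpts o{dt_fine, dt_coarse, vdot_switch};
  const int nsamp = (int)std::floor(t_end / sample_dt + 1e-9) + 1;
  NumericVector tout(nsamp), vout(nsamp);
  double dvdt = 0.0;
  tout[0] = 0.0; vout[0] = y[0];
  for (int i = 1; i < nsamp; ++i) {
    const double t1 = i * sample_dt;
    advance_cell(y.data(), params.begin(), (i - 1) * sample_dt, t1, stims, o, dvdt);
    tout[i] = t1; vout[i] = y[0];
    if (!std::isfinite(y[0]))
      return List::create(_["time"] = tout, _["vm"] = vout,
                          _["state"] = NumericVector(y.begin(), y.end()),
                          _["ok"] = false, _["fail_time"] = t1);
  }
  return List::create(_["time"] = tout, _["vm"] = vout,
                      _["state"] = NumericVector(y.begin(), y.end()),
                      _["ok"] = true, _["fail_time"] = NA_REAL);
}

// prepace n_cycles at cycle length cl, recording V (1 ms) for the final
// record_last cycles so APD drift can be assessed
// [[Rcpp::export]]
List cell_prepace_cpp(NumericVector params, NumericVector state, int n_cycles,
                      double cl, int record_last, double dt_fine,
                      double dt_coarse, double vdot_switch) {
  std::vector<double> y(state.begin(), state.end());
  SolverOpts o{dt_fine, dt_coarse, vdot_switch};
  if (record_last > n_cycles) record_last = n_cycles;
  const int n_silent = n_cycles - record_last;
  double dvdt = 0.0;
  std::vector<double> stim1(1, 0.0);
  for (int c = 0; c < n_silent; ++c) {
    advance_cell(y.data(), params.begin(), 0.0, cl, stim1, o, dvdt);
    if (!std::isfinite(y[0]))
      return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                          _["ok"] = false, _["fail_cycle"] = c + 1);
  }
  const double sample_dt = 1.0;
  const int per = (int)std::floor(cl / sample_dt + 1e-9);
  NumericVector tout(record_last * per), vout(record_last * per);
  NumericVector stim_rec(record_last);
  int idx = 0;
  for (int c = 0; c < record_last; ++c) {
    stim_rec[c] = c * cl;
    for (int i = 0; i < per; ++i) {
      tout[idx] = c * cl + i * sample_dt;
      vout[idx] = y[0];
      ++idx;
      advance_cell(y.data(), params.begin(), i * sample_dt,
                   (i + 1) * sample_dt, stim1, o, dvdt);
    }
    if (!std::isfinite(y[0]))
      return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                          _["ok"] = false, _["fail_cycle"] = n_silent + c + 1);
  }
  return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                      _["ok"] = true, _["fail_cycle"] = NA_REAL,
                      _["time"] = tout, _["vm"] = vout,
                      _["stim_times"] = stim_rec);
}

// 1-D monodomain cable, explicit finite differences, fixed time step.
// params: NSTATE-free 17-row x nnode matrix (column per node);
// states: NSTATE x nnode matrix; D in mm^2/ms; dx in mm.
// Stimulus applied to nodes in stim_nodes (0-based) at stim_times.
// [[Rcpp::export]]
List cable_run_cpp(NumericMatrix params, NumericMatrix states, double D,
                   double dx, double dt, IntegerVector stim_nodes,
                   NumericVector stim_times, double t_end, double sample_dt) {
  const int nn = states.ncol();
  std::vector<double> y(NSTATE * nn);
  for (int j = 0; j < nn; ++j)
    for (int i = 0; i < NSTATE; ++i) y[j * NSTATE + i] = states(i, j);
  std::vector<char> is_stim(nn, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) is_stim[stim_nodes[k]] = 1;
  const double r = D / (dx * dx);
  const int nsteps = (int)std::round(t_end / dt);
  const int sample_every = std::max(1, (int)std::round(sample_dt / dt));
  const int nsamp = nsteps / sample_every + 1;
  NumericMatrix vm(nsamp, nn);
  NumericVector tout(nsamp);
  std::vector<double> vold(nn);
  int row = 0;
  for (int j = 0; j < nn; ++j) vm(0, j) = y[j * NSTATE];
  tout[0] = 0.0; row = 1;
  const double stim_dur = params(15, 0);
  const double stim_amp = params(14, 0);
  size_t stim_idx = 0;
  bool ok = true; double fail_t = NA_REAL;
  for (int s = 0; s < nsteps && ok; ++s) {
    const double t = s * dt;
    // stimulus window check (stim_times sorted)
    bool stim_on = false;
    for (int k = 0; k < stim_times.size(); ++k) {
      if (t >= stim_times[k] - 1e-9 && t < stim_times[k] + stim_dur - 1e-9) {
        stim_on = true; break;
      }
      if (stim_times[k] > t) break;
    }
    for (int j = 0; j < nn; ++j) vold[j] = y[j * NSTATE];
    for (int j = 0; j < nn; ++j) {
      const double vl = (j == 0) ? vold[1] : vold[j - 1];        // no-flux ends
      const double vr = (j == nn - 1) ? vold[nn - 2] : vold[j + 1];
      const double diff = r * (vl - 2.0 * vold[j] + vr);
      const double Ist = (stim_on && is_stim[j]) ? stim_amp : 0.0;
      step_cell(&y[j * NSTATE], &params(0, j), dt, Ist, diff);
    }
    if ((s + 1) % sample_every == 0) {
      const double tnow = (s + 1) * dt;
      for (int j = 0; j < nn; ++j) {
        vm(row, j) = y[j * NSTATE];
        if (!std::isfinite(y[j * NSTATE])) { ok = false; fail_t = tnow; }
      }
      tout[row] = tnow; ++row;
    }
  }
  (void)stim_idx;
  NumericMatrix final_states(NSTATE, nn);
  for (int j = 0; j < nn; ++j)
    for (int i = 0; i < NSTATE; ++i) final_states(i, j) = y[j * NSTATE + i];
  return List::create(_["time"] = tout, _["vm"] = vm,
                      _["states"] = final_states, _["ok"] = ok,
                      _["fail_time"] = fail_t);
}
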