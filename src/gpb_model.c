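/* Endocardial human ventricular action-potential model (Grandi-type
 * compartmental formulation) extended with a Hodgkin-Huxley late Na+
 * current (conductance gNaL, inactivation gate h_L).
 *
 * State vector (40 entries, order fixed; see R/parameters.R):
 *   0  m       INa activation
 *   1  h       INa fast inactivation
 *   2  j       INa slow inactivation
 *   3  xkr     IKr activation
 *   4  xks     IKs activation
 *   5  xtos    Ito slow activation
 *   6  ytos    Ito slow inactivation
 *   7  xtof    Ito fast activation
 *   8  ytof    Ito fast inactivation
 *   9  d       ICaL activation
 *   10 f       ICaL voltage inactivation
 *   11 fcaBj   ICaL Ca-dependent inactivation, junctional
 *   12 fcaBsl  ICaL Ca-dependent inactivation, subsarcolemmal
 *   13 RyRr    SR release channel, resting fraction
 *   14 RyRo    SR release channel, open fraction
 *   15 RyRi    SR release channel, inactivated fraction
 *   16 NaBj    Na buffer, junctional (mM)
 *   17 NaBsl   Na buffer, subsarcolemmal (mM)
 *   18 TnCL    troponin C low-affinity site (mM)
 *   19 TnCHc   troponin C high-affinity site, Ca bound (mM)
 *   20 TnCHm   troponin C high-affinity site, Mg bound (mM)
 *   21 CaM     calmodulin-bound Ca (mM)
 *   22 Myoc    myosin, Ca bound (mM)
 *   23 Myom    myosin, Mg bound (mM)
 *   24 SRB     SR membrane buffer (mM)
 *   25 SLLj    sarcolemmal low-affinity buffer, junctional (mM)
 *   26 SLLsl   sarcolemmal low-affinity buffer, subsarcolemmal (mM)
 *   27 SLHj    sarcolemmal high-affinity buffer, junctional (mM)
 *   28 SLHsl   sarcolemmal high-affinity buffer, subsarcolemmal (mM)
 *   29 Csqnb   calsequestrin-bound Ca (mM)
 *   30 CaSR    free SR Ca (mM)
 *   31 Naj     junctional Na (mM)
 *   32 Nasl    subsarcolemmal Na (mM)
 *   33 Nai     bulk cytosolic Na (mM)
 *   34 Ki      cytosolic K (mM, held fixed per baseline convention)
 *   35 Caj     junctional Ca (mM)
 *   36 Casl    subsarcolemmal Ca (mM)
 *   37 Cai     bulk cytosolic Ca (mM)
 *   38 Vm      membrane potential (mV)
 *   39 hL      late Na+ inactivation gate
 *
 * Units: time ms, potential mV, concentration mM, current A/F (uA/uF).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NSTATE 40
#define NPARMS 34
#define NOUT   23

/* parameter indices -- keep in sync with R/parameters.R */
#define P_GNa        0
#define P_GNaL       1
#define P_tau_hL     2
#define P_hL_vhalf   3
#define P_hL_k       4
#define P_GNaB       5
#define P_IbarNaK    6
#define P_GtoSlow    7
#define P_GtoFast    8
#define P_GKr        9
#define P_GKs       10
#define P_GKp       11
#define P_GK1       12
#define P_GClCa     13
#define P_GClB      14
#define P_pCa       15
#define P_pK        16
#define P_pNa       17
#define P_IbarNCX   18
#define P_IbarSLCaP 19
#define P_GCaB      20
#define P_VmaxSERCA 21
#define P_ks_rel    22
#define P_leak_rate 23
#define P_ec50SR    24
#define P_Ko        25
#define P_Nao       26
#define P_Cao       27
#define P_Cli       28
#define P_Clo       29
#define P_Mgi       30
#define P_stim_amp  31
#define P_vclamp    32
#define P_naclamp   33

static double parms[NPARMS];

/* deSolve parameter initialiser */
void hfcell_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* core right-hand side; `out` receives NOUT current values (may be NULL) */
static void gpb_rhs(double t, const double *y, double *ydot, double *out,
                    const double *p)
{
    /* physical constants */
    const double R_gas = 8314.0;    /* J/(kmol K) */
    const double Frdy  = 96485.0;   /* C/mol */
    const double Temp  = 310.0;     /* K */
    const double FoRT  = Frdy / (R_gas * Temp);
    const double Cmem  = 1.3810e-10; /* F */

    /* cell geometry */
    const double cellLength = 100.0, cellRadius = 10.25; /* um */
    const double Vcell = M_PI * cellRadius * cellRadius * cellLength * 1.0e-15; /* L */
    const double Vmyo  = 0.65 * Vcell;
    const double Vsr   = 0.035 * Vcell;
    const double Vsl   = 0.02 * Vcell;
    const double Vjunc = 0.0539 * 0.01 * Vcell;

    /* inter-compartment transfer rates [L/ms] */
    const double J_ca_juncsl = 1.0 / 1.2134e12;
    const double J_ca_slmyo  = 1.0 / 2.68510e11;
    const double J_na_juncsl = 1.0 / (1.6382e12 / 3.0 * 100.0);
    const double J_na_slmyo  = 1.0 / (1.8308e10 / 3.0 * 100.0);

    /* membrane current partitioning */
    const double Fjunc = 0.11, Fsl = 1.0 - 0.11;
    const double Fjunc_CaL = 0.9, Fsl_CaL = 1.0 - 0.9;

    const double Ko  = p[P_Ko];
    const double Nao = p[P_Nao];
    const double Cao = p[P_Cao];
    const double Cli = p[P_Cli];
    const double Clo = p[P_Clo];
    const double Mgi = p[P_Mgi];

    const double m = y[0], hgate = y[1], jgate = y[2];
    const double xkr = y[3], xks = y[4];
    const double xtos = y[5], ytos = y[6], xtof = y[7], ytof = y[8];
    const double d = y[9], f = y[10], fcaBj = y[11], fcaBsl = y[12];
    const double RyRr = y[13], RyRo = y[14], RyRi = y[15];
    const double CaSR = y[30];
    const double Naj = y[31], Nasl = y[32], Nai = y[33];
    const double Ki = y[34];
    const double Caj = y[35], Casl = y[36], Cai = y[37];
    const double V = y[38];
    const double hL = y[39];

    /* reversal potentials */
    const double ena_junc = (1.0 / FoRT) * log(Nao / Naj);
    const double ena_sl   = (1.0 / FoRT) * log(Nao / Nasl);
    const double ek       = (1.0 / FoRT) * log(Ko / Ki);
    const double eca_junc = (1.0 / FoRT / 2.0) * log(Cao / Caj);
    const double eca_sl   = (1.0 / FoRT / 2.0) * log(Cao / Casl);
    const double ecl      = (1.0 / FoRT) * log(Cli / Clo);

    /* ---- fast Na+ current ---------------------------------------- */
    double mss = 1.0 / pow(1.0 + exp(-(56.86 + V) / 9.03), 2.0);
    double taum = 0.1292 * exp(-pow((V + 45.79) / 15.54, 2.0))
                + 0.06487 * exp(-pow((V - 4.823) / 51.12, 2.0));
    double ah, bh, aj, bj;
    if (V >= -40.0) {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    } else {
        ah = 0.057 * exp(-(V + 80.0) / 6.8);
        bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
        aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V))
             * (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    }
    double tauh = 1.0 / (ah + bh);
    double hss = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
    double tauj = 1.0 / (aj + bj);
    double jss = hss;

    ydot[0] = (mss - m) / taum;
    ydot[1] = (hss - hgate) / tauh;
    ydot[2] = (jss - jgate) / tauj;

    double m3hj = m * m * m * hgate * jgate;
    double I_Na_junc = Fjunc * p[P_GNa] * m3hj * (V - ena_junc);
    double I_Na_sl   = Fsl * p[P_GNa] * m3hj * (V - ena_sl);
    double I_Na = I_Na_junc + I_Na_sl;

    /* ---- late Na+ current ----------------------------------------- */
    double hLss = 1.0 / (1.0 + exp((V - p[P_hL_vhalf]) / p[P_hL_k]));
    ydot[39] = (hLss - hL) / p[P_tau_hL];
    double m3 = m * m * m;
    double I_NaL_junc = Fjunc * p[P_GNaL] * m3 * hL * (V - ena_junc);
    double I_NaL_sl   = Fsl * p[P_GNaL] * m3 * hL * (V - ena_sl);
    double I_NaL = I_NaL_junc + I_NaL_sl;

    /* ---- background Na+ current ----------------------------------- */
    double I_nabk_junc = Fjunc * p[P_GNaB] * (V - ena_junc);
    double I_nabk_sl   = Fsl * p[P_GNaB] * (V - ena_sl);
    double I_nabk = I_nabk_junc + I_nabk_sl;

    /* ---- Na+/K+ pump ---------------------------------------------- */
    const double KmNaip = 11.0, KmKo = 1.5;
    double sigma = (exp(Nao / 67.3) - 1.0) / 7.0;
    double fnak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V * FoRT)
                         + 0.0365 * sigma * exp(-V * FoRT));
    double I_nak_junc = Fjunc * p[P_IbarNaK] * fnak * Ko
        / (1.0 + pow(KmNaip / Naj, 4.0)) / (Ko + KmKo);
    double I_nak_sl = Fsl * p[P_IbarNaK] * fnak * Ko
        / (1.0 + pow(KmNaip / Nasl, 4.0)) / (Ko + KmKo);
    double I_nak = I_nak_junc + I_nak_sl;

    /* ---- rapid delayed rectifier K+ ------------------------------- */
    double gkr = p[P_GKr] * sqrt(Ko / 5.4);
    double xrss = 1.0 / (1.0 + exp(-(V + 10.0) / 5.0));
    double tauxr = 550.0 / (1.0 + exp((-22.0 - V) / 9.0)) * 6.0
                   / (1.0 + exp((V + 11.0) / 9.0))
                 + 230.0 / (1.0 + exp((V + 40.0) / 20.0));
    ydot[3] = (xrss - xkr) / tauxr;
    double rkr = 1.0 / (1.0 + exp((V + 74.0) / 24.0));
    double I_kr = gkr * xkr * rkr * (V - ek);

    /* ---- slow delayed rectifier K+ -------------------------------- */
    const double pNaK = 0.01833;
    double eks = (1.0 / FoRT) * log((Ko + pNaK * Nao) / (Ki + pNaK * Nai));
    double xsss = 1.0 / (1.0 + exp(-(V + 3.8) / 14.25));
    double tauxs = 990.1 / (1.0 + exp(-(V + 2.436) / 14.12));
    ydot[4] = (xsss - xks) / tauxs;
    double I_ks = p[P_GKs] * xks * xks * (V - eks); /* junc+sl share gKs */

    /* ---- plateau K+ ----------------------------------------------- */
    double kp_kp = 1.0 / (1.0 + exp(7.488 - V / 5.98));
    double I_kp = p[P_GKp] * kp_kp * (V - ek);

    /* ---- transient outward K+ (slow + fast) ----------------------- */
    double xtoss = 1.0 / (1.0 + exp(-(V - 19.0) / 13.0));
    double ytoss = 1.0 / (1.0 + exp((V + 19.5) / 5.0));
    double tauxtos = 9.0 / (1.0 + exp((V + 3.0) / 15.0)) + 0.5;
    double tauytos = 800.0 / (1.0 + exp((V + 60.0) / 10.0)) + 30.0;
    ydot[5] = (xtoss - xtos) / tauxtos;
    ydot[6] = (ytoss - ytos) / tauytos;
    double I_tos = p[P_GtoSlow] * xtos * ytos * (V - ek);

    double tauxtof = 8.5 * exp(-pow((V + 45.0) / 50.0, 2.0)) + 0.5;
    double tauytof = 85.0 * exp(-pow(V + 40.0, 2.0) / 220.0) + 7.0;
    ydot[7] = (xtoss - xtof) / tauxtof;
    ydot[8] = (ytoss - ytof) / tauytof;
    double I_tof = p[P_GtoFast] * xtof * ytof * (V - ek);
    double I_to = I_tos + I_tof;

    /* ---- inward rectifier K+ -------------------------------------- */
    double aki = 1.02 / (1.0 + exp(0.2385 * (V - ek - 59.215)));
    double bki = (0.49124 * exp(0.08032 * (V + 5.476 - ek))
                  + exp(0.06175 * (V - ek - 594.31)))
                 / (1.0 + exp(-0.5143 * (V - ek + 4.753)));
    double kiss = aki / (aki + bki);
    double I_k1 = p[P_GK1] * sqrt(Ko / 5.4) * kiss * (V - ek);

    /* ---- Cl- currents --------------------------------------------- */
    const double KdClCa = 0.1;
    double I_ClCa = Fjunc * p[P_GClCa] / (1.0 + KdClCa / Caj) * (V - ecl)
                  + Fsl * p[P_GClCa] / (1.0 + KdClCa / Casl) * (V - ecl);
    double I_Clbk = p[P_GClB] * (V - ecl);

    /* ---- L-type Ca2+ current -------------------------------------- */
    double dss = 1.0 / (1.0 + exp(-(V + 5.0) / 6.0));
    double Vd = V + 5.0;
    double taud;
    if (fabs(Vd) < 1.0e-4) Vd = (Vd >= 0.0 ? 1.0e-4 : -1.0e-4);
    taud = dss * (1.0 - exp(-Vd / 6.0)) / (0.035 * Vd);
    double fss = 1.0 / (1.0 + exp((V + 35.0) / 9.0))
               + 0.6 / (1.0 + exp((50.0 - V) / 20.0));
    double tauf = 1.0 / (0.0197 * exp(-pow(0.0337 * (V + 14.5), 2.0)) + 0.02);
    ydot[9]  = (dss - d) / taud;
    ydot[10] = (fss - f) / tauf;
    ydot[11] = 1.7 * Caj * (1.0 - fcaBj) - 11.9e-3 * fcaBj;
    ydot[12] = 1.7 * Casl * (1.0 - fcaBsl) - 11.9e-3 * fcaBsl;

    double Vn = (fabs(V) < 1.0e-4) ? 1.0e-4 : V; /* GHK singularity guard */
    double e2v = exp(2.0 * Vn * FoRT);
    double e1v = exp(Vn * FoRT);
    double ibarca_j = p[P_pCa] * 4.0 * (Vn * Frdy * FoRT)
        * (0.341 * Caj * e2v - 0.341 * Cao) / (e2v - 1.0);
    double ibarca_sl = p[P_pCa] * 4.0 * (Vn * Frdy * FoRT)
        * (0.341 * Casl * e2v - 0.341 * Cao) / (e2v - 1.0);
    double ibark = p[P_pK] * (Vn * Frdy * FoRT)
        * (0.75 * Ki * e1v - 0.75 * Ko) / (e1v - 1.0);
    double ibarna_j = p[P_pNa] * (Vn * Frdy * FoRT)
        * (0.75 * Naj * e1v - 0.75 * Nao) / (e1v - 1.0);
    double ibarna_sl = p[P_pNa] * (Vn * Frdy * FoRT)
        * (0.75 * Nasl * e1v - 0.75 * Nao) / (e1v - 1.0);

    double I_Ca_junc = Fjunc_CaL * ibarca_j * d * f * (1.0 - fcaBj) * 0.45;
    double I_Ca_sl   = Fsl_CaL * ibarca_sl * d * f * (1.0 - fcaBsl) * 0.45;
    double I_Ca = I_Ca_junc + I_Ca_sl;
    double I_CaK = ibark * d * f
        * (Fjunc_CaL * (1.0 - fcaBj) + Fsl_CaL * (1.0 - fcaBsl)) * 0.45;
    double I_CaNa_junc = Fjunc_CaL * ibarna_j * d * f * (1.0 - fcaBj) * 0.45;
    double I_CaNa_sl   = Fsl_CaL * ibarna_sl * d * f * (1.0 - fcaBsl) * 0.45;
    double I_CaNa = I_CaNa_junc + I_CaNa_sl;

    /* ---- Na+/Ca2+ exchanger --------------------------------------- */
    const double KmCai = 3.59e-3, KmCao = 1.3, KmNai = 12.29, KmNao = 87.5;
    const double ksat = 0.32, nu = 0.27, Kdact = 0.150e-3;
    double Ka_junc = 1.0 / (1.0 + pow(Kdact / Caj, 2.0));
    double Ka_sl   = 1.0 / (1.0 + pow(Kdact / Casl, 2.0));
    double expnu   = exp(nu * V * FoRT);
    double expnu1  = exp((nu - 1.0) * V * FoRT);
    double Naj3 = Naj * Naj * Naj, Nasl3 = Nasl * Nasl * Nasl;
    double Nao3 = Nao * Nao * Nao;
    double s1_junc = expnu * Naj3 * Cao;
    double s1_sl   = expnu * Nasl3 * Cao;
    double s2_junc = expnu1 * Nao3 * Caj;
    double s2_sl   = expnu1 * Nao3 * Casl;
    double s3_junc = KmCai * Nao3 * (1.0 + pow(Naj / KmNai, 3.0))
        + KmNao * KmNao * KmNao * Caj * (1.0 + Caj / KmCai)
        + KmCao * Naj3 + Naj3 * Caj + Nao3 * Caj;
    double s3_sl = KmCai * Nao3 * (1.0 + pow(Nasl / KmNai, 3.0))
        + KmNao * KmNao * KmNao * Casl * (1.0 + Casl / KmCai)
        + KmCao * Nasl3 + Nasl3 * Casl + Nao3 * Casl;
    double I_ncx_junc = Fjunc * p[P_IbarNCX] * Ka_junc
        * (s1_junc - s2_junc) / s3_junc / (1.0 + ksat * expnu1);
    double I_ncx_sl = Fsl * p[P_IbarNCX] * Ka_sl
        * (s1_sl - s2_sl) / s3_sl / (1.0 + ksat * expnu1);
    double I_ncx = I_ncx_junc + I_ncx_sl;

    /* ---- sarcolemmal Ca2+ pump and background Ca2+ ----------------- */
    const double KmPCa = 0.5e-3;
    double kmpca16 = pow(KmPCa, 1.6);
    double caj16 = pow(Caj, 1.6), casl16 = pow(Casl, 1.6);
    double I_pca_junc = Fjunc * p[P_IbarSLCaP] * caj16 / (kmpca16 + caj16);
    double I_pca_sl   = Fsl * p[P_IbarSLCaP] * casl16 / (kmpca16 + casl16);
    double I_pca = I_pca_junc + I_pca_sl;
    double I_cabk_junc = Fjunc * p[P_GCaB] * (V - eca_junc);
    double I_cabk_sl   = Fsl * p[P_GCaB] * (V - eca_sl);
    double I_cabk = I_cabk_junc + I_cabk_sl;

    /* ---- SR fluxes: release, uptake, leak -------------------------- */
    const double MaxSR = 15.0, MinSR = 1.0;
    const double koCa = 10.0, kom = 0.06, kiCa = 0.5, kim = 0.005;
    double kCaSR = MaxSR - (MaxSR - MinSR)
        / (1.0 + pow(p[P_ec50SR] / CaSR, 2.5));
    double koSRCa = koCa / kCaSR;
    double kiSRCa = kiCa * kCaSR;
    double RI = 1.0 - RyRr - RyRo - RyRi;
    ydot[13] = (kim * RI - kiSRCa * Caj * RyRr)
             - (koSRCa * Caj * Caj * RyRr - kom * RyRo);
    ydot[14] = (koSRCa * Caj * Caj * RyRr - kom * RyRo)
             - (kiSRCa * Caj * RyRo - kim * RyRi);
    ydot[15] = (kiSRCa * Caj * RyRo - kim * RyRi)
             - (kom * RyRi - koSRCa * Caj * Caj * RI);
    double J_SRCarel = p[P_ks_rel] * RyRo * (CaSR - Caj); /* mM/ms */

    const double Kmf = 0.246e-3, Kmr = 1.7, hillSRCaP = 1.787;
    double upf = pow(Cai / Kmf, hillSRCaP);
    double upr = pow(CaSR / Kmr, hillSRCaP);
    double J_serca = p[P_VmaxSERCA] * (upf - upr) / (1.0 + upf + upr);
    double J_SRleak = p[P_leak_rate] * (CaSR - Caj);

    /* ---- Na+ buffering --------------------------------------------- */
    const double Bmax_Naj = 7.561, Bmax_Nasl = 1.65;
    const double koff_na = 1.0e-3, kon_na = 0.1e-3;
    ydot[16] = kon_na * Naj * (Bmax_Naj - y[16]) - koff_na * y[16];
    ydot[17] = kon_na * Nasl * (Bmax_Nasl - y[17]) - koff_na * y[17];

    /* ---- cytosolic Ca2+ buffering ----------------------------------- */
    const double Bmax_TnClow = 70e-3, koff_tncl = 19.6e-3, kon_tncl = 32.7;
    const double Bmax_TnChigh = 140e-3;
    const double koff_tnchca = 0.032e-3, kon_tnchca = 2.37;
    const double koff_tnchmg = 3.33e-3, kon_tnchmg = 3.0e-3;
    const double Bmax_CaM = 24e-3, koff_cam = 238e-3, kon_cam = 34.0;
    const double Bmax_myosin = 140e-3;
    const double koff_myoca = 0.46e-3, kon_myoca = 13.8;
    const double koff_myomg = 0.057e-3, kon_myomg = 0.0157;
    const double Bmax_SR = 19.0 * 0.9e-3, koff_sr = 60e-3, kon_sr = 100.0;
    ydot[18] = kon_tncl * Cai * (Bmax_TnClow - y[18]) - koff_tncl * y[18];
    ydot[19] = kon_tnchca * Cai * (Bmax_TnChigh - y[19] - y[20])
             - koff_tnchca * y[19];
    ydot[20] = kon_tnchmg * Mgi * (Bmax_TnChigh - y[19] - y[20])
             - koff_tnchmg * y[20];
    ydot[21] = kon_cam * Cai * (Bmax_CaM - y[21]) - koff_cam * y[21];
    ydot[22] = kon_myoca * Cai * (Bmax_myosin - y[22] - y[23])
             - koff_myoca * y[22];
    ydot[23] = kon_myomg * Mgi * (Bmax_myosin - y[22] - y[23])
             - koff_myomg * y[23];
    ydot[24] = kon_sr * Cai * (Bmax_SR - y[24]) - koff_sr * y[24];
    double J_CaB_cytosol = ydot[18] + ydot[19] + ydot[20] + ydot[21]
                         + ydot[22] + ydot[23] + ydot[24];

    /* ---- junctional / subsarcolemmal Ca2+ buffering ------------------ */
    const double Bmax_SLlowsl  = 37.4e-3 * Vmyo / Vsl;
    const double Bmax_SLlowj   = 4.6e-3 * Vmyo / Vjunc * 0.1;
    const double koff_sll = 1300e-3, kon_sll = 100.0;
    const double Bmax_SLhighsl = 13.4e-3 * Vmyo / Vsl;
    const double Bmax_SLhighj  = 1.65e-3 * Vmyo / Vjunc * 0.1;
    const double koff_slh = 30e-3, kon_slh = 100.0;
    ydot[25] = kon_sll * Caj * (Bmax_SLlowj - y[25]) - koff_sll * y[25];
    ydot[26] = kon_sll * Casl * (Bmax_SLlowsl - y[26]) - koff_sll * y[26];
    ydot[27] = kon_slh * Caj * (Bmax_SLhighj - y[27]) - koff_slh * y[27];
    ydot[28] = kon_slh * Casl * (Bmax_SLhighsl - y[28]) - koff_slh * y[28];
    double J_CaB_junction = ydot[25] + ydot[27];
    double J_CaB_sl = ydot[26] + ydot[28];

    /* ---- SR Ca2+ ---------------------------------------------------- */
    const double Bmax_Csqn = 140e-3 * Vmyo / Vsr;
    const double koff_csqn = 65.0, kon_csqn = 100.0;
    ydot[29] = kon_csqn * CaSR * (Bmax_Csqn - y[29]) - koff_csqn * y[29];
    ydot[30] = J_serca - (J_SRleak * Vmyo / Vsr + J_SRCarel) - ydot[29];

    /* ---- Na+ concentrations ----------------------------------------- */
    double I_Na_tot_junc = I_Na_junc + I_NaL_junc + I_nabk_junc
        + 3.0 * I_ncx_junc + 3.0 * I_nak_junc + I_CaNa_junc;
    double I_Na_tot_sl = I_Na_sl + I_NaL_sl + I_nabk_sl
        + 3.0 * I_ncx_sl + 3.0 * I_nak_sl + I_CaNa_sl;
    ydot[31] = -I_Na_tot_junc * Cmem / (Vjunc * Frdy)
        + J_na_juncsl / Vjunc * (Nasl - Naj) - ydot[16];
    ydot[32] = -I_Na_tot_sl * Cmem / (Vsl * Frdy)
        + J_na_juncsl / Vsl * (Naj - Nasl)
        + J_na_slmyo / Vsl * (Nai - Nasl) - ydot[17];
    ydot[33] = J_na_slmyo / Vmyo * (Nasl - Nai);
    if (p[P_naclamp] > 0.5) { ydot[31] = 0.0; ydot[32] = 0.0; ydot[33] = 0.0; }

    /* ---- K+ (held fixed, baseline convention) ------------------------ */
    double I_K_tot = I_to + I_kr + I_ks + I_k1 - 2.0 * I_nak + I_CaK + I_kp;
    ydot[34] = 0.0;

    /* ---- Ca2+ concentrations ----------------------------------------- */
    double I_Ca_tot_junc = I_Ca_junc + I_cabk_junc + I_pca_junc
        - 2.0 * I_ncx_junc;
    double I_Ca_tot_sl = I_Ca_sl + I_cabk_sl + I_pca_sl - 2.0 * I_ncx_sl;
    ydot[35] = -I_Ca_tot_junc * Cmem / (Vjunc * 2.0 * Frdy)
        + J_ca_juncsl / Vjunc * (Casl - Caj) - J_CaB_junction
        + J_SRCarel * Vsr / Vjunc + J_SRleak * Vmyo / Vjunc;
    ydot[36] = -I_Ca_tot_sl * Cmem / (Vsl * 2.0 * Frdy)
        + J_ca_juncsl / Vsl * (Caj - Casl)
        + J_ca_slmyo / Vsl * (Cai - Casl) - J_CaB_sl;
    ydot[37] = -J_serca * Vsr / Vmyo - J_CaB_cytosol
        + J_ca_slmyo / Vmyo * (Casl - Cai);

    /* ---- membrane potential ------------------------------------------ */
    double I_Na_tot = I_Na_tot_junc + I_Na_tot_sl;
    double I_Cl_tot = I_ClCa + I_Clbk;
    double I_Ca_tot = I_Ca_tot_junc + I_Ca_tot_sl;
    double I_tot = I_Na_tot + I_Cl_tot + I_Ca_tot + I_K_tot;
    double I_app = p[P_stim_amp];
    ydot[38] = -(I_tot - I_app);
    if (p[P_vclamp] > 0.5) ydot[38] = 0.0;

    if (out != NULL) {
        out[0]  = I_Na;
        out[1]  = I_NaL;
        out[2]  = I_nak;
        out[3]  = I_nabk;
        out[4]  = I_to;
        out[5]  = I_kr;
        out[6]  = I_ks;
        out[7]  = I_k1;
        out[8]  = I_kp;
        out[9]  = I_Ca;
        out[10] = I_CaK;
        out[11] = I_CaNa;
        out[12] = I_Ca + I_CaK + I_CaNa;
        out[13] = I_ncx;
        out[14] = I_pca;
        out[15] = I_cabk;
        out[16] = I_ClCa;
        out[17] = I_Clbk;
        out[18] = J_SRCarel;
        out[19] = J_serca;
        out[20] = J_SRleak;
        out[21] = I_app;
        out[22] = I_tot;
    }
    (void)t;
}

/* deSolve derivative entry point */
void hfcell_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    if (ip[0] < NOUT) error("hfcell: nout too small");
    gpb_rhs(*t, y, ydot, yout, parms);
    (void)neq;
}

/* single evaluation from R: returns list(ydot, currents) */
SEXP C_gpb_eval(SEXP sy, SEXP sp)
{
    if (LENGTH(sy) != NSTATE) error("state vector must have %d entries", NSTATE);
    if (LENGTH(sp) != NPARMS) error("parameter vector must have %d entries", NPARMS);
    SEXP ydot = PROTECT(allocVector(REALSXP, NSTATE));
    SEXP out = PROTECT(allocVector(REALSXP, NOUT));
    gpb_rhs(0.0, REAL(sy), REAL(ydot), REAL(out), REAL(sp));
    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, ydot);
    SET_VECTOR_ELT(res, 1, out);
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("ydot"));
    SET_STRING_ELT(nms, 1, mkChar("currents"));
    setAttrib(res, R_NamesSymbol, nms);
    UNPROTECT(4);
    return res;
}

static const R_CallMethodDef callMethods[] = {
    {"C_gpb_eval", (DL_FUNC) &C_gpb_eval, 2},
    {NULL, NULL, 0}
};

void R_init_hfcell(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE); /* deSolve looks symbols up by name */
}
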