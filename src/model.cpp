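// Kinetic model of yeast glycolysis + trehalose/glycogen storage metabolism
// under feast/famine substrate cycles, with an optional 13C-enrichment layer.
//
// Layout:
//   - fixed species / reaction / parameter registries (mirrored in R/constants.R;
//     a unit test asserts the two stay in sync),
//   - rate laws and the total-concentration right-hand side,
//   - labelled-fraction balances sharing the same split (fwd/bwd) fluxes,
//   - a RODAS3 linearly-implicit Rosenbrock integrator (stiff, adaptive,
//     embedded order 3(2), finite-difference Jacobian, cubic Hermite output).
//
// All intracellular balances are mM on cytosolic volume; extracellular balances
// mM on broth volume; conversion uses phi = biomass volume fraction (L cytosol
// per L broth). Vacuole is a fixed fraction fvac of cytosolic volume.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- registries

enum Species {
  GLCI = 0, S_G6P, S_F6P, S_FBP, S_DHAP, S_GAP, S_BPG, S_P3G, S_P2G, S_PEP,
  S_PYR, S_ACE, S_G1P, S_UDPG, S_T6P, S_TREC, S_G3P, S_GLYCEROL, S_GLYCOGEN,
  S_ATP, S_ADP, S_AMP, S_NAD, S_NADH, S_PI, S_TREV, S_GLCEC, S_TREEC, S_VOL,
  NSPEC
};

static const char* SPECIES_NAMES[NSPEC] = {
  "GLCi", "G6P", "F6P", "FBP", "DHAP", "GAP", "BPG", "P3G", "P2G", "PEP",
  "PYR", "ACE", "G1P", "UDPG", "T6P", "TREc", "G3P", "GLYCEROL", "GLYCOGEN",
  "ATP", "ADP", "AMP", "NAD", "NADH", "PI", "TREv", "GLCec", "TREec", "VOL"
};

// carbon-tracked species (labelled layer), in state order
static const int CARBON_IDX[] = {
  GLCI, S_G6P, S_F6P, S_FBP, S_DHAP, S_GAP, S_BPG, S_P3G, S_P2G, S_PEP,
  S_PYR, S_ACE, S_G1P, S_UDPG, S_T6P, S_TREC, S_G3P, S_GLYCEROL, S_GLYCOGEN,
  S_TREV, S_GLCEC, S_TREEC
};
static const int NCARBON = 22;

enum Rxn {
  R_HXT = 0, R_HXK, R_PGI, R_PFK, R_FBA, R_TPI, R_GAPDH, R_PGK, R_GPM, R_ENO,
  R_PYK, R_PDC, R_ADH, R_G3PDH, R_GPP, R_GLYCEX, R_PGM1, R_UGP, R_TPS1,
  R_TPS2, R_NTH1, R_AGT1, R_VACT, R_ATH1, R_GLYSYN, R_GLYDEG, R_ATPASE,
  R_ADK, R_MITO, R_PIBUF, R_SINKG6P, R_SINKP3G, R_SINKPYR, R_SINKACE,
  NRXN
};

static const char* RXN_NAMES[NRXN] = {
  "HXT", "HXK", "PGI", "PFK", "FBA", "TPI", "GAPDH", "PGK", "GPM", "ENO",
  "PYK", "PDC", "ADH", "G3PDH", "GPP", "GLYC_EX", "PGM1", "UGP", "TPS1",
  "TPS2", "NTH1", "AGT1", "VACT", "ATH1", "GLY_SYNTH", "GLY_DEG", "ATPase",
  "ADK", "MITO_NADH", "PIBUF", "sink_G6P", "sink_P3G", "sink_PYR", "sink_ACE"
};

// reactions that may run backwards (everything else is irreversible, >= 0;
// PIBUF is a signed exchange flux)
static const bool RXN_REVERSIBLE[NRXN] = {
  true,  true,  true,  false, true,  true,  true,  true,  true,  true,
  false, false, false, false, false, false, true,  true,  false,
  false, false, true,  true,  false, false, false, false,
  true,  false, true,  false, false, false, false
};

enum Par {
  HXT_VMAX = 0, HXT_KM, HXT_KI, HXT_KEQ, HXT_GLCMIN, HXT_SENSING,
  HXK_VMAX, HXK_KM_GLC, HXK_KM_ATP, HXK_KM_G6P, HXK_KM_ADP, HXK_KI_T6P, HXK_KEQ,
  PGI_VMAX, PGI_KM_G6P, PGI_KM_F6P, PGI_KEQ,
  PFK_VMAX, PFK_KM_F6P, PFK_KM_ATP, PFK_L0, PFK_KI_ATP, PFK_KA_AMP, PFK_KA_FBP, PFK_N,
  FBA_VMAX, FBA_KM_FBP, FBA_KM_DHAP, FBA_KM_GAP, FBA_KEQ,
  TPI_VMAX, TPI_KM_DHAP, TPI_KM_GAP, TPI_KEQ,
  GAPDH_VMAX, GAPDH_KM_GAP, GAPDH_KM_NAD, GAPDH_KM_BPG, GAPDH_KM_NADH, GAPDH_KM_PI, GAPDH_KEQ,
  PGK_VMAX, PGK_KM_BPG, PGK_KM_ADP, PGK_KM_P3G, PGK_KM_ATP, PGK_KEQ,
  GPM_VMAX, GPM_KM_P3G, GPM_KM_P2G, GPM_KEQ,
  ENO_VMAX, ENO_KM_P2G, ENO_KM_PEP, ENO_KEQ,
  PYK_VMAX, PYK_K05, PYK_N, PYK_KM_ADP, PYK_KA_FBP,
  PDC_VMAX, PDC_K05, PDC_N,
  ADH_VMAX, ADH_KM_ACE, ADH_KM_NADH,
  G3PDH_VMAX, G3PDH_KM_DHAP, G3PDH_KM_NADH,
  GPP_VMAX, GPP_KM_G3P,
  GLYCEX_K,
  PGM1_VMAX, PGM1_KM_G6P, PGM1_KM_G1P, PGM1_KEQ,
  UGP_VMAX, UGP_KM_G1P, UGP_KM_ATP, UGP_KIA_G1P, UGP_KM_UDPG, UGP_KM_ADP, UGP_KEQ,
  TPS1_VMAX, TPS1_KM_G6P, TPS1_KM_UDPG,
  TPS2_VMAX, TPS2_KM_T6P,
  NTH1_VMAX, NTH1_KM_TRE,
  AGT1_VMAX, AGT1_KM_CYT, AGT1_KM_EC, AGT1_KEQ, AGT1_KI_T6P,
  VACT_VMAX, VACT_KM_CYT, VACT_KM_VAC, VACT_KEQ,
  ATH1_VMAX, ATH1_KM_TRE, ATH1_KI_T6P,
  GLYSYN_KSAT_UDPG, GLYSYN_KI_GLY, GLYSYN_H,
  GLYDEG_KSAT_GLY,
  ATPASE_K, ATPASE_KM, ATPASE_N,
  ADK_K, ADK_KEQ,
  MITO_VMAX, MITO_KM_NADH, MITO_KM_ADP,
  PIBUF_K, PIBUF_PIREF,
  SINKG6P_VMAX, SINKG6P_KM,
  SINKP3G_VMAX, SINKP3G_KM,
  SINKPYR_VMAX, SINKPYR_KM, SINKPYR_F,
  SINKACE_VMAX, SINKACE_KM,
  NPAR
};

static const char* PAR_NAMES[NPAR] = {
  "HXT.Vmax", "HXT.Km", "HXT.Ki", "HXT.Keq", "HXT.GLCec_min", "HXT.sensing",
  "HXK.Vmax", "HXK.Km_GLC", "HXK.Km_ATP", "HXK.Km_G6P", "HXK.Km_ADP", "HXK.Ki_T6P", "HXK.Keq",
  "PGI.Vmax", "PGI.Km_G6P", "PGI.Km_F6P", "PGI.Keq",
  "PFK.Vmax", "PFK.Km_F6P", "PFK.Km_ATP", "PFK.L0", "PFK.Ki_ATP", "PFK.Ka_AMP", "PFK.Ka_FBP", "PFK.n",
  "FBA.Vmax", "FBA.Km_FBP", "FBA.Km_DHAP", "FBA.Km_GAP", "FBA.Keq",
  "TPI.Vmax", "TPI.Km_DHAP", "TPI.Km_GAP", "TPI.Keq",
  "GAPDH.Vmax", "GAPDH.Km_GAP", "GAPDH.Km_NAD", "GAPDH.Km_BPG", "GAPDH.Km_NADH", "GAPDH.Km_PI", "GAPDH.Keq",
  "PGK.Vmax", "PGK.Km_BPG", "PGK.Km_ADP", "PGK.Km_P3G", "PGK.Km_ATP", "PGK.Keq",
  "GPM.Vmax", "GPM.Km_P3G", "GPM.Km_P2G", "GPM.Keq",
  "ENO.Vmax", "ENO.Km_P2G", "ENO.Km_PEP", "ENO.Keq",
  "PYK.Vmax", "PYK.K05", "PYK.n", "PYK.Km_ADP", "PYK.Ka_FBP",
  "PDC.Vmax", "PDC.K05", "PDC.n",
  "ADH.Vmax", "ADH.Km_ACE", "ADH.Km_NADH",
  "G3PDH.Vmax", "G3PDH.Km_DHAP", "G3PDH.Km_NADH",
  "GPP.Vmax", "GPP.Km_G3P",
  "GLYC_EX.k",
  "PGM1.Vmax", "PGM1.Km_G6P", "PGM1.Km_G1P", "PGM1.Keq",
  "UGP.Vmax", "UGP.Km_G1P", "UGP.Km_ATP", "UGP.Kia_G1P", "UGP.Km_UDPG", "UGP.Km_ADP", "UGP.Keq",
  "TPS1.Vmax", "TPS1.Km_G6P", "TPS1.Km_UDPG",
  "TPS2.Vmax", "TPS2.Km_T6P",
  "NTH1.Vmax", "NTH1.Km_TRE",
  "AGT1.Vmax", "AGT1.Km_cyt", "AGT1.Km_ec", "AGT1.Keq", "AGT1.Ki_T6P",
  "VACT.Vmax", "VACT.Km_cyt", "VACT.Km_vac", "VACT.Keq",
  "ATH1.Vmax", "ATH1.Km_TRE", "ATH1.Ki_T6P",
  "GLY_SYNTH.Ksat_UDPG", "GLY_SYNTH.Ki_GLY", "GLY_SYNTH.h",
  "GLY_DEG.Ksat_GLY",
  "ATPase.k", "ATPase.Km", "ATPase.n",
  "ADK.k", "ADK.Keq",
  "MITO_NADH.Vmax", "MITO_NADH.Km_NADH", "MITO_NADH.Km_ADP",
  "PIBUF.k", "PIBUF.Pi_ref",
  "sink_G6P.Vmax", "sink_G6P.Km",
  "sink_P3G.Vmax", "sink_P3G.Km",
  "sink_PYR.Vmax", "sink_PYR.Km", "sink_PYR.f",
  "sink_ACE.Vmax", "sink_ACE.Km"
};

// ---------------------------------------------------------------- environment

// per-phase constants (feed, outflow, compartment geometry, forcings)
struct Env {
  double phi;        // cytosolic volume fraction of broth (L cyt / L broth)
  double fvac;       // vacuolar volume as fraction of cytosolic volume
  double fin;        // feed flow (L/s)
  double fout;       // outflow (L/s)
  double cfeed;      // feed glucose concentration (mM)
  double lfeed;      // labelled fraction of feed glucose (0..1)
  int    gly_mode;   // 0 = constant (table mean), 1 = periodic table on cycle time
  arma::vec syn_t, syn_v, deg_t, deg_v;   // glycogen flux interpolation tables
  double syn_mean, deg_mean;
  double cycle_len;  // s
  double cycle_t0;   // absolute time of cycle start (for table lookup)
  bool   clamp_glcec;
  arma::vec clamp_t, clamp_v;             // forced GLCec trace (cycle time)
};

// periodic reduction into [0, len); std::fmod avoided deliberately (it pulls a
// versioned libm symbol newer than the runtime glibc of this toolchain)
static inline double cyc_mod(double x, double len) {
  double r = x - std::floor(x / len) * len;
  if (r < 0) r += len;
  if (r >= len) r -= len;
  return r;
}

static double lin_interp(const arma::vec& xs, const arma::vec& ys, double x) {
  const int n = xs.n_elem;
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (xs[mid] <= x) lo = mid; else hi = mid; }
  double w = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] + w * (ys[hi] - ys[lo]);
}

static double table_mean(const arma::vec& xs, const arma::vec& ys) {
  // time-average of the piecewise-linear table (trapezoid / span)
  double area = 0.0;
  for (unsigned i = 1; i < xs.n_elem; ++i)
    area += 0.5 * (ys[i] + ys[i - 1]) * (xs[i] - xs[i - 1]);
  return area / (xs[xs.n_elem - 1] - xs[0]);
}

static Env env_from_list(const List& e) {
  Env env;
  env.phi   = as<double>(e["phi"]);
  env.fvac  = as<double>(e["fvac"]);
  env.fin   = as<double>(e["fin"]);
  env.fout  = as<double>(e["fout"]);
  env.cfeed = as<double>(e["cfeed"]);
  env.lfeed = e.containsElementNamed("lfeed") ? as<double>(e["lfeed"]) : 0.0;
  env.gly_mode = as<int>(e["gly_mode"]);
  env.syn_t = as<arma::vec>(e["gly_syn_t"]);
  env.syn_v = as<arma::vec>(e["gly_syn_v"]);
  env.deg_t = as<arma::vec>(e["gly_deg_t"]);
  env.deg_v = as<arma::vec>(e["gly_deg_v"]);
  env.syn_mean = table_mean(env.syn_t, env.syn_v);
  env.deg_mean = table_mean(env.deg_t, env.deg_v);
  env.cycle_len = as<double>(e["cycle_len"]);
  env.cycle_t0  = e.containsElementNamed("cycle_t0") ? as<double>(e["cycle_t0"]) : 0.0;
  env.clamp_glcec = e.containsElementNamed("clamp_t") && as<arma::vec>(e["clamp_t"]).n_elem > 0;
  if (env.clamp_glcec) {
    env.clamp_t = as<arma::vec>(e["clamp_t"]);
    env.clamp_v = as<arma::vec>(e["clamp_v"]);
  }
  return env;
}

// ---------------------------------------------------------------- rate laws

static inline double mm_rev_uni(double Vm, double S, double P, double Ks,
                                double Kp, double Keq, double inh) {
  return inh * (Vm / Ks) * (S - P / Keq) / (1.0 + S / Ks + P / Kp);
}

static inline double mm_rev_bibi(double Vm, double A, double B, double P, double Q,
                                 double Ka, double Kb, double Kp, double Kq,
                                 double Keq, double extra_comp) {
  // convenience-style reversible bi-bi; extra_comp adds to the A-site denominator
  return Vm / (Ka * Kb) * (A * B - P * Q / Keq) /
         ((1.0 + A / Ka + P / Kp + extra_comp) * (1.0 + B / Kb + Q / Kq));
}

static inline double sat(double S, double K) { return S / (K + S); }

// fluxes for the total-concentration model; cycle time tc used for glycogen
static void fluxes(const double* y, double t, const double* p, const Env& env,
                   double* v) {
  // clamp to >= 0: intermediate Rosenbrock stage states may dip marginally
  // below zero, and Michaelis-Menten denominators must not blow up there
  auto nn = [&](int i) { return std::max(y[i], 0.0); };
  const double glci = nn(GLCI), g6p = nn(S_G6P), f6p = nn(S_F6P), fbp = nn(S_FBP),
    dhap = nn(S_DHAP), gap = nn(S_GAP), bpg = nn(S_BPG), p3g = nn(S_P3G),
    p2g = nn(S_P2G), pep = nn(S_PEP), pyr = nn(S_PYR), ace = nn(S_ACE),
    g1p = nn(S_G1P), udpg = nn(S_UDPG), t6p = nn(S_T6P), trec = nn(S_TREC),
    g3p = nn(S_G3P), glyc = nn(S_GLYCEROL), glyg = nn(S_GLYCOGEN),
    atp = nn(S_ATP), adp = nn(S_ADP), amp = nn(S_AMP), nad = nn(S_NAD),
    nadh = nn(S_NADH), pi = nn(S_PI), trev = nn(S_TREV), treec = nn(S_TREEC);
  double glcec = nn(S_GLCEC);
  if (env.clamp_glcec)
    glcec = lin_interp(env.clamp_t, env.clamp_v, cyc_mod(t - env.cycle_t0, env.cycle_len));

  // HXT: facilitated diffusion with glucose-sensing threshold on the outside face
  {
    double xec = (p[HXT_SENSING] > 0.5) ? std::max(glcec - p[HXT_GLCMIN], 0.0) : glcec;
    double Km = p[HXT_KM];
    v[R_HXT] = (p[HXT_VMAX] / Km) * (xec - glci / p[HXT_KEQ]) /
               (1.0 + xec / Km + glci / Km + xec * glci / (p[HXT_KI] * Km * Km));
  }
  // HXK/GLK with competitive T6P inhibition on the glucose site
  v[R_HXK] = mm_rev_bibi(p[HXK_VMAX], glci, atp, g6p, adp,
                         p[HXK_KM_GLC], p[HXK_KM_ATP], p[HXK_KM_G6P], p[HXK_KM_ADP],
                         p[HXK_KEQ], t6p / p[HXK_KI_T6P]);
  v[R_PGI] = mm_rev_uni(p[PGI_VMAX], g6p, f6p, p[PGI_KM_G6P], p[PGI_KM_F6P], p[PGI_KEQ], 1.0);
  // PFK: two-state (MWC) allosteric law; ATP raises, AMP/FBP lower the T/R ratio
  {
    double a = f6p / p[PFK_KM_F6P];
    double n = p[PFK_N];
    double L = p[PFK_L0] * std::pow((1.0 + atp / p[PFK_KI_ATP]) /
               ((1.0 + amp / p[PFK_KA_AMP]) * (1.0 + fbp / p[PFK_KA_FBP])), n);
    double on = std::pow(1.0 + a, n - 1.0);
    v[R_PFK] = p[PFK_VMAX] * sat(atp, p[PFK_KM_ATP]) * a * on / (on * (1.0 + a) + L);
  }
  v[R_FBA] = (p[FBA_VMAX] / p[FBA_KM_FBP]) * (fbp - dhap * gap / p[FBA_KEQ]) /
             (1.0 + fbp / p[FBA_KM_FBP] + dhap / p[FBA_KM_DHAP] + gap / p[FBA_KM_GAP] +
              dhap * gap / (p[FBA_KM_DHAP] * p[FBA_KM_GAP]));
  v[R_TPI] = mm_rev_uni(p[TPI_VMAX], dhap, gap, p[TPI_KM_DHAP], p[TPI_KM_GAP], p[TPI_KEQ], 1.0);
  v[R_GAPDH] = mm_rev_bibi(p[GAPDH_VMAX], gap, nad, bpg, nadh,
                           p[GAPDH_KM_GAP], p[GAPDH_KM_NAD], p[GAPDH_KM_BPG], p[GAPDH_KM_NADH],
                           p[GAPDH_KEQ], 0.0) * sat(pi, p[GAPDH_KM_PI]);
  v[R_PGK] = mm_rev_bibi(p[PGK_VMAX], bpg, adp, p3g, atp,
                         p[PGK_KM_BPG], p[PGK_KM_ADP], p[PGK_KM_P3G], p[PGK_KM_ATP],
                         p[PGK_KEQ], 0.0);
  v[R_GPM] = mm_rev_uni(p[GPM_VMAX], p3g, p2g, p[GPM_KM_P3G], p[GPM_KM_P2G], p[GPM_KEQ], 1.0);
  v[R_ENO] = mm_rev_uni(p[ENO_VMAX], p2g, pep, p[ENO_KM_P2G], p[ENO_KM_PEP], p[ENO_KEQ], 1.0);
  // PYK: Hill in PEP, FBP lowers the half-saturation (feed-forward activation)
  {
    double K = p[PYK_K05] / (1.0 + fbp / p[PYK_KA_FBP]);
    double s = std::pow(pep, p[PYK_N]);
    v[R_PYK] = p[PYK_VMAX] * s / (std::pow(K, p[PYK_N]) + s) * sat(adp, p[PYK_KM_ADP]);
  }
  {
    double s = std::pow(pyr, p[PDC_N]);
    v[R_PDC] = p[PDC_VMAX] * s / (std::pow(p[PDC_K05], p[PDC_N]) + s);
  }
  v[R_ADH]   = p[ADH_VMAX] * sat(ace, p[ADH_KM_ACE]) * sat(nadh, p[ADH_KM_NADH]);
  v[R_G3PDH] = p[G3PDH_VMAX] * sat(dhap, p[G3PDH_KM_DHAP]) * sat(nadh, p[G3PDH_KM_NADH]);
  v[R_GPP]   = p[GPP_VMAX] * sat(g3p, p[GPP_KM_G3P]);
  v[R_GLYCEX] = p[GLYCEX_K] * glyc;
  v[R_PGM1] = mm_rev_uni(p[PGM1_VMAX], g6p, g1p, p[PGM1_KM_G6P], p[PGM1_KM_G1P], p[PGM1_KEQ], 1.0);
  // UGP: ordered bi-bi (G1P binds first; UTP/UDP proxied by ATP/ADP)
  {
    double A = g1p, B = atp, P = udpg, Q = adp;
    double Ka = p[UGP_KM_G1P], Kb = p[UGP_KM_ATP], Kia = p[UGP_KIA_G1P];
    double Kp = p[UGP_KM_UDPG], Kq = p[UGP_KM_ADP];
    double den = Kia * Kb * (1.0 + P / Kp + Q / Kq + P * Q / (Kp * Kq)) +
                 Kb * A + Ka * B + A * B;
    v[R_UGP] = p[UGP_VMAX] * (A * B - P * Q / p[UGP_KEQ]) / den;
  }
  v[R_TPS1] = p[TPS1_VMAX] * sat(g6p, p[TPS1_KM_G6P]) * sat(udpg, p[TPS1_KM_UDPG]);
  v[R_TPS2] = p[TPS2_VMAX] * sat(t6p, p[TPS2_KM_T6P]);
  v[R_NTH1] = p[NTH1_VMAX] * sat(trec, p[NTH1_KM_TRE]);
  v[R_AGT1] = mm_rev_uni(p[AGT1_VMAX], trec, treec, p[AGT1_KM_CYT], p[AGT1_KM_EC],
                         p[AGT1_KEQ], 1.0 / (1.0 + t6p / p[AGT1_KI_T6P]));
  v[R_VACT] = mm_rev_uni(p[VACT_VMAX], trec, trev, p[VACT_KM_CYT], p[VACT_KM_VAC],
                         p[VACT_KEQ], 1.0);
  v[R_ATH1] = p[ATH1_VMAX] * sat(trev, p[ATH1_KM_TRE]) / (1.0 + t6p / p[ATH1_KI_T6P]);
  // glycogen: phenomenological interpolated fluxes with saturation/capacity factors
  {
    double syn_base, deg_base;
    if (env.gly_mode == 1) {
      double tc = cyc_mod(t - env.cycle_t0, env.cycle_len);
      syn_base = lin_interp(env.syn_t, env.syn_v, tc);
      deg_base = lin_interp(env.deg_t, env.deg_v, tc);
    } else {
      syn_base = env.syn_mean;
      deg_base = env.deg_mean;
    }
    v[R_GLYSYN] = syn_base * sat(udpg, p[GLYSYN_KSAT_UDPG]) /
                  (1.0 + std::pow(glyg / p[GLYSYN_KI_GLY], p[GLYSYN_H]));
    v[R_GLYDEG] = deg_base * sat(glyg, p[GLYDEG_KSAT_GLY]);
  }
  {
    double an = std::pow(atp, p[ATPASE_N]);
    v[R_ATPASE] = p[ATPASE_K] * an / (std::pow(p[ATPASE_KM], p[ATPASE_N]) + an);
  }
  v[R_ADK]    = p[ADK_K] * (atp * amp - adp * adp / p[ADK_KEQ]);
  v[R_MITO]   = p[MITO_VMAX] * sat(nadh, p[MITO_KM_NADH]) * sat(adp, p[MITO_KM_ADP]);
  v[R_PIBUF]  = p[PIBUF_K] * (p[PIBUF_PIREF] - pi);
  v[R_SINKG6P] = p[SINKG6P_VMAX] * sat(g6p, p[SINKG6P_KM]);
  v[R_SINKP3G] = p[SINKP3G_VMAX] * sat(p3g, p[SINKP3G_KM]);
  v[R_SINKPYR] = p[SINKPYR_F] * p[SINKPYR_VMAX] * sat(pyr, p[SINKPYR_KM]);
  v[R_SINKACE] = p[SINKACE_VMAX] * sat(ace, p[SINKACE_KM]);
}

// total-concentration right-hand side
static void rhs_total(const double* y, double t, const double* p, const Env& env,
                      double* dy, double* v) {
  fluxes(y, t, p, env, v);
  const double V = y[S_VOL];
  const double din = env.fin / V;

  dy[GLCI] = v[R_HXT] + 2.0 * v[R_NTH1] + 2.0 * v[R_ATH1] - v[R_HXK];
  dy[S_G6P] = v[R_HXK] - v[R_PGI] - v[R_PGM1] - v[R_TPS1] - v[R_SINKG6P];
  dy[S_F6P] = v[R_PGI] - v[R_PFK];
  dy[S_FBP] = v[R_PFK] - v[R_FBA];
  dy[S_DHAP] = v[R_FBA] - v[R_TPI] - v[R_G3PDH];
  dy[S_GAP] = v[R_FBA] + v[R_TPI] - v[R_GAPDH];
  dy[S_BPG] = v[R_GAPDH] - v[R_PGK];
  dy[S_P3G] = v[R_PGK] - v[R_GPM] - v[R_SINKP3G];
  dy[S_P2G] = v[R_GPM] - v[R_ENO];
  dy[S_PEP] = v[R_ENO] - v[R_PYK];
  dy[S_PYR] = v[R_PYK] - v[R_PDC] - v[R_SINKPYR];
  dy[S_ACE] = v[R_PDC] - v[R_ADH] - v[R_SINKACE];
  dy[S_G1P] = v[R_PGM1] - v[R_UGP] + v[R_GLYDEG];
  dy[S_UDPG] = v[R_UGP] - v[R_TPS1] - v[R_GLYSYN];
  dy[S_T6P] = v[R_TPS1] - v[R_TPS2];
  dy[S_TREC] = v[R_TPS2] - v[R_NTH1] - v[R_AGT1] - v[R_VACT];
  dy[S_G3P] = v[R_G3PDH] - v[R_GPP];
  dy[S_GLYCEROL] = v[R_GPP] - v[R_GLYCEX];
  dy[S_GLYCOGEN] = v[R_GLYSYN] - v[R_GLYDEG];
  dy[S_ATP] = v[R_PGK] + v[R_PYK] + v[R_MITO]
            - v[R_HXK] - v[R_PFK] - v[R_UGP] - v[R_ATPASE] - v[R_ADK];
  dy[S_ADP] = -(v[R_PGK] + v[R_PYK] + v[R_MITO])
            + v[R_HXK] + v[R_PFK] + v[R_UGP] + v[R_ATPASE] + 2.0 * v[R_ADK];
  dy[S_AMP] = -v[R_ADK];
  dy[S_NAD] = -v[R_GAPDH] + v[R_ADH] + v[R_G3PDH] + v[R_MITO];
  dy[S_NADH] = -dy[S_NAD];
  dy[S_PI] = v[R_GPP] + v[R_TPS2] + v[R_ATPASE] + v[R_PIBUF]
           - v[R_GAPDH] - v[R_GLYDEG] - v[R_MITO];
  dy[S_TREV] = (v[R_VACT] - v[R_ATH1]) / env.fvac;
  dy[S_GLCEC] = env.clamp_glcec ? 0.0
              : din * (env.cfeed - y[S_GLCEC]) - env.phi * v[R_HXT];
  dy[S_TREEC] = -din * y[S_TREEC] + env.phi * v[R_AGT1];
  dy[S_VOL] = env.fin - env.fout;
}

// labelled-fraction balances (appended states, order CARBON_IDX); the same
// split fluxes feed every term, each multiplied by its substrate's enrichment
static void rhs_labelled(const double* y, const double* L, double t,
                         const double* p, const Env& env, const double* v,
                         double* dL) {
  // enrichment per carbon species (0 where the pool is empty)
  double e[NSPEC];
  for (int k = 0; k < NCARBON; ++k) {
    int s = CARBON_IDX[k];
    e[s] = (y[s] > 1e-12) ? L[k] / y[s] : 0.0;
  }
  double f[NRXN], b[NRXN];
  for (int r = 0; r < NRXN; ++r) {
    f[r] = std::max(v[r], 0.0);
    b[r] = std::max(-v[r], 0.0);
  }
  auto net = [&](int r, int sub, int prod) {       // label flux sub -> prod
    return f[r] * e[sub] - b[r] * e[prod];
  };
  const double V = y[S_VOL];
  const double din = env.fin / V;
  double d[NSPEC];

  d[GLCI] = net(R_HXT, S_GLCEC, GLCI) + 2.0 * f[R_NTH1] * e[S_TREC] +
            2.0 * f[R_ATH1] * e[S_TREV] - net(R_HXK, GLCI, S_G6P);
  d[S_G6P] = net(R_HXK, GLCI, S_G6P) - net(R_PGI, S_G6P, S_F6P) -
             net(R_PGM1, S_G6P, S_G1P) - f[R_TPS1] * e[S_G6P] -
             f[R_SINKG6P] * e[S_G6P];
  d[S_F6P] = net(R_PGI, S_G6P, S_F6P) - f[R_PFK] * e[S_F6P];
  d[S_FBP] = f[R_PFK] * e[S_F6P] - f[R_FBA] * e[S_FBP] +
             b[R_FBA] * 0.5 * (e[S_DHAP] + e[S_GAP]);
  d[S_DHAP] = f[R_FBA] * e[S_FBP] - b[R_FBA] * e[S_DHAP] -
              net(R_TPI, S_DHAP, S_GAP) - f[R_G3PDH] * e[S_DHAP];
  d[S_GAP] = f[R_FBA] * e[S_FBP] - b[R_FBA] * e[S_GAP] +
             net(R_TPI, S_DHAP, S_GAP) - net(R_GAPDH, S_GAP, S_BPG);
  d[S_BPG] = net(R_GAPDH, S_GAP, S_BPG) - net(R_PGK, S_BPG, S_P3G);
  d[S_P3G] = net(R_PGK, S_BPG, S_P3G) - net(R_GPM, S_P3G, S_P2G) -
             f[R_SINKP3G] * e[S_P3G];
  d[S_P2G] = net(R_GPM, S_P3G, S_P2G) - net(R_ENO, S_P2G, S_PEP);
  d[S_PEP] = net(R_ENO, S_P2G, S_PEP) - f[R_PYK] * e[S_PEP];
  d[S_PYR] = f[R_PYK] * e[S_PEP] - f[R_PDC] * e[S_PYR] - f[R_SINKPYR] * e[S_PYR];
  d[S_ACE] = f[R_PDC] * e[S_PYR] - f[R_ADH] * e[S_ACE] - f[R_SINKACE] * e[S_ACE];
  d[S_G1P] = net(R_PGM1, S_G6P, S_G1P) - net(R_UGP, S_G1P, S_UDPG) +
             f[R_GLYDEG] * e[S_GLYCOGEN];
  d[S_UDPG] = net(R_UGP, S_G1P, S_UDPG) - f[R_TPS1] * e[S_UDPG] -
              f[R_GLYSYN] * e[S_UDPG];
  d[S_T6P] = f[R_TPS1] * 0.5 * (e[S_G6P] + e[S_UDPG]) - f[R_TPS2] * e[S_T6P];
  d[S_TREC] = f[R_TPS2] * e[S_T6P] - f[R_NTH1] * e[S_TREC] -
              net(R_AGT1, S_TREC, S_TREEC) - net(R_VACT, S_TREC, S_TREV);
  d[S_G3P] = f[R_G3PDH] * e[S_DHAP] - f[R_GPP] * e[S_G3P];
  d[S_GLYCEROL] = f[R_GPP] * e[S_G3P] - f[R_GLYCEX] * e[S_GLYCEROL];
  d[S_GLYCOGEN] = f[R_GLYSYN] * e[S_UDPG] - f[R_GLYDEG] * e[S_GLYCOGEN];
  d[S_TREV] = (net(R_VACT, S_TREC, S_TREV) - f[R_ATH1] * e[S_TREV]) / env.fvac;
  d[S_GLCEC] = env.clamp_glcec ? 0.0
             : din * (env.lfeed * env.cfeed) - din * L[20] -
               env.phi * net(R_HXT, S_GLCEC, GLCI);
  d[S_TREEC] = -din * L[21] + env.phi * net(R_AGT1, S_TREC, S_TREEC);

  for (int k = 0; k < NCARBON; ++k) dL[k] = d[CARBON_IDX[k]];
}

// full RHS dispatcher: n = NSPEC (totals) or NSPEC + NCARBON (with label layer)
struct Model {
  const double* p;
  Env env;
  bool labelled;
  void operator()(double t, const arma::vec& y, arma::vec& dy) const {
    double v[NRXN];
    rhs_total(y.memptr(), t, p, env, dy.memptr(), v);
    if (labelled)
      rhs_labelled(y.memptr(), y.memptr() + NSPEC, t, p, env, v,
                   dy.memptr() + NSPEC);
  }
};

// ------------------------------------------------------- RODAS3 integrator

// Rosenbrock method, order 3(2), 4 stages, stiffly accurate (Sandu et al.).
struct RosResult {
  arma::vec ylast;
  arma::mat yout;      // length(times) x n
  int nsteps = 0, nreject = 0, nclip = 0;
  int last_neg = -1;   // last state that forced a nonnegativity rejection
  bool ok = true;
  std::string message;
};

template <typename RHS>
RosResult rodas3(const RHS& fun, arma::vec y, const arma::vec& times,
                 double rtol, double atol, double hmax, double neg_clip,
                 double neg_err, bool guard_nonneg, int max_steps = 200000) {
  const int n = y.n_elem;
  static const double A31 = 2.0, A41 = 2.0, A43 = 1.0;
  static const double C21 = 4.0, C31 = 1.0, C32 = -1.0,
                      C41 = 1.0, C42 = -1.0, C43 = -8.0 / 3.0;
  static const double ALPHA[4] = {0.0, 0.0, 1.0, 1.0};
  static const double GAMMAI[4] = {0.5, 1.5, 0.0, 0.0};
  static const double M1 = 2.0, M3 = 1.0, M4 = 1.0;
  static const double GAMMA = 0.5;

  RosResult res;
  res.yout.set_size(times.n_elem, n);
  res.yout.row(0) = y.t();

  double t = times[0];
  const double tend = times[times.n_elem - 1];
  double h = std::min(1e-3, (tend - t) * 0.01);
  if (hmax > 0) h = std::min(h, hmax);
  unsigned iout = 1;

  arma::vec f0(n), ft(n), ytmp(n), f1(n), f2(n), f3(n), f4(n);
  arma::vec k1(n), k2(n), k3(n), k4(n), ynew(n), err(n), fnew(n);
  arma::mat J(n, n), W(n, n);
  const int MAXSTEP = max_steps;

  fun(t, y, f0);
  if (!f0.is_finite()) { res.ok = false; res.message = "non-finite RHS at t0"; res.ylast = y; return res; }

  while (t < tend - 1e-12 * std::max(1.0, std::abs(tend))) {
    if (res.nsteps + res.nreject > MAXSTEP) {
      int iw = 0; double w = 0;
      for (int i = 0; i < n; ++i) if (y[i] < w) { w = y[i]; iw = i; }
      res.ok = false;
      res.message = "step limit exceeded at t=" + std::to_string(t) +
                    " h=" + std::to_string(h) + " ymin_idx=" + std::to_string(iw) +
                    " last_neg=" + std::to_string(res.last_neg);
      res.ylast = y; return res;
    }
    if (h > hmax && hmax > 0) h = hmax;
    if (t + h > tend) h = tend - t;

    // finite-difference Jacobian and time derivative
    for (int j = 0; j < n; ++j) {
      double dj = 1e-8 * std::max(std::abs(y[j]), 1e-5);
      ytmp = y; ytmp[j] += dj;
      fun(t, ytmp, f1);
      J.col(j) = (f1 - f0) / dj;
    }
    {
      double dt = 1e-7 * std::max(1.0, std::abs(t));
      fun(t + dt, y, f1);
      ft = (f1 - f0) / dt;
    }
    if (!J.is_finite()) { res.ok = false; res.message = "non-finite Jacobian"; return res; }

    bool accepted = false;
    while (!accepted) {
      double hg = 1.0 / (h * GAMMA);
      W = -J;
      W.diag() += hg;
      arma::mat WL, WU, Pm;
      if (!arma::lu(WL, WU, Pm, W)) {
        h *= 0.5; res.nreject++;
        if (h < 1e-12) { res.ok = false; res.message = "LU failure"; return res; }
        continue;
      }
      auto wsolve = [&](const arma::vec& rhs) {
        return arma::vec(arma::solve(arma::trimatu(WU),
               arma::solve(arma::trimatl(WL), Pm * rhs,
                           arma::solve_opts::fast), arma::solve_opts::fast));
      };
      // stage 1
      k1 = wsolve(f0 + h * GAMMAI[0] * ft);
      // stage 2 (same y, same t as stage 1)
      k2 = wsolve(f0 + h * GAMMAI[1] * ft + (C21 / h) * k1);
      // stage 3
      ytmp = y + A31 * k1;
      fun(t + ALPHA[2] * h, ytmp, f3);
      k3 = wsolve(f3 + (C31 / h) * k1 + (C32 / h) * k2);
      // stage 4
      ytmp = y + A41 * k1 + A43 * k3;
      fun(t + ALPHA[3] * h, ytmp, f4);
      k4 = wsolve(f4 + (C41 / h) * k1 + (C42 / h) * k2 + (C43 / h) * k3);

      ynew = y + M1 * k1 + M3 * k3 + M4 * k4;
      err = k4;  // embedded difference

      double errnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
        double r = err[i] / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / n);
      if (!std::isfinite(errnorm)) errnorm = 1e10;

      if (errnorm <= 1.0) {
        // negative-concentration guard (volume state exempt): reject and
        // shrink the step while the undershoot exceeds the clip threshold;
        // once steps are tiny, clip to zero; abort on gross violations
        if (guard_nonneg) {
          double worst = 0.0;
          for (int i = 0; i < n; ++i)
            if (i != S_VOL && ynew[i] < worst) worst = ynew[i];
          if (worst < -neg_clip && h > 1e-6) {
            res.nreject++;
            res.last_neg = -1;
            for (int i = 0; i < n; ++i)
              if (i != S_VOL && ynew[i] <= worst) res.last_neg = i;
            h *= 0.5;
            continue;
          }
          if (worst < -neg_err) {
            res.ok = false;
            res.message = "state undershoot " + std::to_string(worst);
            res.ylast = y; return res;
          }
          for (int i = 0; i < n; ++i) {
            if (i == S_VOL || ynew[i] >= 0.0) continue;
            res.nclip++;
            ynew[i] = 0.0;
          }
        }
        fun(t + h, ynew, fnew);
        if (!fnew.is_finite()) {
          h *= 0.5; res.nreject++;
          if (h < 1e-12) { res.ok = false; res.message = "non-finite RHS"; return res; }
          continue;
        }
        // dense output: cubic Hermite on [t, t+h]
        while (iout < times.n_elem && times[iout] <= t + h + 1e-12) {
          double th = (times[iout] - t) / h;
          double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
          double h10 = th * (1 - th) * (1 - th);
          double h01 = th * th * (3 - 2 * th);
          double h11 = th * th * (th - 1);
          res.yout.row(iout) =
            (h00 * y + h10 * h * f0 + h01 * ynew + h11 * h * fnew).t();
          ++iout;
        }
        t += h;
        y = ynew;
        f0 = fnew;
        res.nsteps++;
        double fac = std::min(4.0, std::max(0.2, 0.9 * std::pow(std::max(errnorm, 1e-10), -1.0 / 3.0)));
        h *= fac;
        accepted = true;
      } else {
        res.nreject++;
        h *= std::max(0.2, 0.9 * std::pow(errnorm, -1.0 / 3.0));
        if (h < 1e-12) { res.ok = false; res.message = "step size underflow"; return res; }
      }
    }
  }
  // fill any trailing output times with the final state
  for (; iout < times.n_elem; ++iout) res.yout.row(iout) = y.t();
  res.ylast = y;
  return res;
}

// ---------------------------------------------------------------- R interface

// [[Rcpp::export]]
List cpp_model_info() {
  CharacterVector sp(NSPEC), rx(NRXN), pr(NPAR);
  for (int i = 0; i < NSPEC; ++i) sp[i] = SPECIES_NAMES[i];
  for (int i = 0; i < NRXN; ++i) rx[i] = RXN_NAMES[i];
  for (int i = 0; i < NPAR; ++i) pr[i] = PAR_NAMES[i];
  IntegerVector ci(NCARBON);
  LogicalVector rev(NRXN);
  for (int i = 0; i < NCARBON; ++i) ci[i] = CARBON_IDX[i] + 1;
  for (int i = 0; i < NRXN; ++i) rev[i] = RXN_REVERSIBLE[i];
  return List::create(_["species"] = sp, _["reactions"] = rx,
                      _["parameters"] = pr, _["carbon_idx"] = ci,
                      _["reversible"] = rev);
}

// [[Rcpp::export]]
NumericVector cpp_fluxes(NumericVector y, double t, NumericVector p, List envl) {
  if (y.size() < NSPEC) stop("state vector too short");
  if (p.size() != NPAR) stop("parameter vector has wrong length");
  Env env = env_from_list(envl);
  double v[NRXN];
  fluxes(REAL(y), t, REAL(p), env, v);
  NumericVector out(NRXN);
  CharacterVector nm(NRXN);
  for (int i = 0; i < NRXN; ++i) { out[i] = v[i]; nm[i] = RXN_NAMES[i]; }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector y, double t, NumericVector p, List envl,
                      bool labelled = false) {
  int n = labelled ? NSPEC + NCARBON : NSPEC;
  if (y.size() != n) stop("state vector has wrong length");
  if (p.size() != NPAR) stop("parameter vector has wrong length");
  Env env = env_from_list(envl);
  Model m{REAL(p), env, labelled};
  arma::vec yy(REAL(y), n), dy(n);
  m(t, yy, dy);
  if (!dy.is_finite()) {
    double v[NRXN];
    double* dyp = dy.memptr();
    rhs_total(yy.memptr(), t, REAL(p), env, dyp, v);
    for (int r = 0; r < NRXN; ++r)
      if (!std::isfinite(v[r]))
        stop(std::string("non-finite rate in reaction ") + RXN_NAMES[r]);
    stop("non-finite derivative");
  }
  return NumericVector(dy.begin(), dy.end());
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector y0, NumericVector times, NumericVector p,
                   List envl, double rtol = 1e-8, double atol = 1e-10,
                   bool labelled = false, double hmax = 0.0,
                   double neg_clip = 1e-7, double neg_err = 1e-4,
                   int max_steps = 200000) {
  int n = labelled ? NSPEC + NCARBON : NSPEC;
  if (y0.size() != n) stop("y0 has wrong length");
  if (p.size() != NPAR) stop("parameter vector has wrong length");
  Env env = env_from_list(envl);
  Model m{REAL(p), env, labelled};
  arma::vec y(REAL(y0), n), tms(REAL(times), times.size());
  RosResult r = rodas3(m, y, tms, rtol, atol, hmax, neg_clip, neg_err, true, max_steps);
  return List::create(_["y"] = r.yout, _["ok"] = r.ok, _["message"] = r.message,
                      _["nsteps"] = r.nsteps, _["nreject"] = r.nreject,
                      _["nclip"] = r.nclip,
                      _["ylast"] = r.ylast.n_elem ? NumericVector(r.ylast.begin(), r.ylast.end()) : NumericVector(0));
}

// generic integrator for arbitrary R right-hand sides (test/oracle path)
struct RCallback {
  Function f;
  void operator()(double t, const arma::vec& y, arma::vec& dy) const {
    NumericVector out = f(t, NumericVector(y.begin(), y.end()));
    if ((int)out.size() != (int)y.n_elem) stop("R rhs returned wrong length");
    for (unsigned i = 0; i < y.n_elem; ++i) dy[i] = out[i];
  }
};

// [[Rcpp::export]]
List cpp_ros_integrate(Function f, NumericVector y0, NumericVector times,
                       double rtol = 1e-8, double atol = 1e-10,
                       double hmax = 0.0) {
  RCallback cb{f};
  arma::vec y(REAL(y0), y0.size()), tms(REAL(times), times.size());
  RosResult r = rodas3(cb, y, tms, rtol, atol, hmax, 0.0, 0.0, false);
  return List::create(_["y"] = r.yout, _["ok"] = r.ok, _["message"] = r.message,
                      _["nsteps"] = r.nsteps, _["nreject"] = r.nreject);
}
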