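// Hybrid stochastic-deterministic single-cell engine.
//
// Layout: ~77 deterministic species (receptors, Ras/Raf/MEK/ERK,
// PI3K/AKT/mTOR/4E-BP1/EIF4E, FOXO, AP1/cMyc, cell-cycle oscillator,
// p53-MDM2-WIP1 damage module, apoptosis) plus a per-gene stochastic layer
// (telegraph promoter switching and mRNA birth/death, exact SSA). The two
// layers exchange on a fixed window (default 30 s): mRNA counts are frozen
// for the ODE step, signaling activities are frozen for the SSA propensities.
// Units: molecules and hours; cycle/damage species in activity units.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG (PCG32)
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { // in (0,1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  int binom_half(int n) { // Binomial(n, 1/2) by bit counting
    int k = 0;
    while (n >= 32) { uint32_t r = next(); k += __builtin_popcount(r); n -= 32; }
    if (n > 0) { uint32_t r = next() & ((n == 32) ? 0xffffffffu : ((1u << n) - 1u)); k += __builtin_popcount(r); }
    return k;
  }
};

// ---------------------------------------------------------------- state enum
enum St {
  E_RS = 0, E_PRS, E_PRI,
  I_RS, I_PRS, I_PRI,
  RAS_GDP, RAS_GTP,
  CRAF_I, CRAF_A, CRAF_FB,
  BRAF_I, BRAF_A, BRAF_FB,
  MEK_U, MEK_PP,
  ERK_U, ERK_PP,
  PI3K_I, PI3K_A,
  PIP3,
  AKT_U, AKT_PP,
  MTOR_I, MTOR_A,
  BP1_U, BP1_P,
  E4E_T,
  FOXO_N, FOXO_PC,
  I_ERK, I_AKT,
  CFOS_P, CJUN_P, CMYC_P,
  PTEN_P,
  DR_S, DR_A,
  C8_PRO, C8_A,
  C3_PRO, C3_A,
  PARP_U, PARP_C,
  BID_U, BID_T,
  BAX_C, BAX_A,
  BIM_U, BIM_P,
  BAD_U, BAD_P,
  BCL2_P, PUMA_P, NOXA_P,
  MSH6_P, MGMT_P, BRCA2_P,
  CYCD_M, CYCD, E2F, CYCE, CYCA, CYCB, CDC20, P21, CHK1,
  D_SS, D_DS, ATR_A, ATM_A,
  P53, MDM2_M, MDM2, WIP1_M, WIP1,
  RIB,
  N_STATE
};

// conglomerates: order shared with R
enum Cg {
  CG_EGFR = 0, CG_INSR, CG_RAS, CG_CRAF, CG_BRAF, CG_MEK, CG_ERK, CG_PI3K,
  CG_AKT, CG_MTOR, CG_EIF4EBP1, CG_EIF4E, CG_FOXO, CG_CFOS, CG_CJUN,
  CG_CMYC, CG_PTEN, CG_DR, CG_CASP8, CG_CASP3, CG_PARP, CG_BID, CG_BAX,
  CG_BIM, CG_BAD, CG_BCL2, CG_PUMA, CG_NOXA, CG_MSH6, CG_MGMT, CG_BRCA2,
  N_CONG
};

static const char *CONG_NAMES[N_CONG] = {
  "EGFR", "INSR", "RAS", "CRAF", "BRAF", "MEK", "ERK", "PI3K", "AKT", "MTOR",
  "EIF4EBP1", "EIF4E", "FOXO", "CFOS", "CJUN", "CMYC", "PTEN", "DR", "CASP8",
  "CASP3", "PARP", "BID", "BAX", "BIM", "BAD", "BCL2", "PUMA", "NOXA",
  "MSH6", "MGMT", "BRCA2"
};

static const int CG_BASE[N_CONG] = {
  E_RS, I_RS, RAS_GDP, CRAF_I, BRAF_I, MEK_U, ERK_U, PI3K_I, AKT_U, MTOR_I,
  BP1_U, E4E_T, FOXO_N, CFOS_P, CJUN_P, CMYC_P, PTEN_P, DR_S, C8_PRO,
  C3_PRO, PARP_U, BID_U, BAX_C, BIM_U, BAD_U, BCL2_P, PUMA_P, NOXA_P,
  MSH6_P, MGMT_P, BRCA2_P
};

static const std::vector<std::vector<int> > CG_MEMBERS = {
  {E_RS, E_PRS, E_PRI}, {I_RS, I_PRS, I_PRI}, {RAS_GDP, RAS_GTP},
  {CRAF_I, CRAF_A, CRAF_FB}, {BRAF_I, BRAF_A, BRAF_FB}, {MEK_U, MEK_PP},
  {ERK_U, ERK_PP}, {PI3K_I, PI3K_A}, {AKT_U, AKT_PP}, {MTOR_I, MTOR_A},
  {BP1_U, BP1_P}, {E4E_T}, {FOXO_N, FOXO_PC}, {CFOS_P}, {CJUN_P}, {CMYC_P},
  {PTEN_P}, {DR_S, DR_A}, {C8_PRO, C8_A}, {C3_PRO, C3_A}, {PARP_U, PARP_C},
  {BID_U, BID_T}, {BAX_C, BAX_A}, {BIM_U, BIM_P}, {BAD_U, BAD_P}, {BCL2_P},
  {PUMA_P}, {NOXA_P}, {MSH6_P}, {MGMT_P}, {BRCA2_P}
};

// ---------------------------------------------------------------- parameters
struct Params {
  double k_gac, k_gin;
  double theta_max, theta_K, theta_n, bp1_Kd, k_bp1_phos, k_bp1_dep, k_bp_fos;
  double rib0, k_rib_syn, rib_basal, k_rib_deg, mtor_ref_act, vol_max;
  double k_bind_egfr, K_egf, k_off_egfr, k_int_egfr, k_rec_egfr, k_xdeg_egfr, k_bas_egfr;
  double k_bind_insr, K_ins, k_off_insr, k_int_insr, k_rec_insr, k_xdeg_insr, k_bas_insr;
  double w_erk_egfr, w_erk_insr, w_akt_egfr, w_akt_insr;
  double k_ras_act, k_ras_bas, k_ras_gap;
  double k_raf_act, k_raf_deact, k_raf_fb, k_raf_rec, braf_potency,
    raf_mek_Kd, raf_mek_Kd_hi;
  double k_mek_cat, K_mek_sat, k_mek_dep, k_erk_cat, K_erk_sat, k_erk_dep;
  double K_meki, K_akti, act_frac_ref;
  double k_pi3k_act, k_pi3k_bas, k_pi3k_deact, K_fb_pi3k;
  double k_pip3_syn, k_pip3_deg, pten_basal, pip3_ref;
  double k_akt_cat, K_akt_sat, k_akt_dep, k_mtor_act, k_mtor_deact,
    w_mtor_pip3;
  double k_foxo_phos, k_foxo_dep, k_foxo_xdeg;
  double tau_ierk, tau_iakt;
  double k_fos_ind, K_fos_hill, n_fos, w_jun_erk, K_jun_erk, w_jun_ap1,
    K_jun_ap1, n_jun, w_myc_akt, K_myc_akt, ap1_ref_fos, ap1_ref_jun;
  double ccnd_f_basal, K_ap1_ccnd, n_ap1_ccnd, ccnd_g_basal, K_myc_ccnd,
    myc_ref, myc_basal_frac, ccnd_m_ref;
  double k_sD, k_dD, k_aE2F, K_DE, n_DE, k_iE2F, w_iA, k_sE, k_dE, w_EA,
    k_sA, k_dA, w_20, k_sB, K_AB, n_AB, k_dB, w_20b, k_a20, K_B20, n_B20,
    k_i20, cyca_thr, cycb_thr, K_p21, K_chk, s_entry_thresh, div_frac, cycb_peak_min,
    k_sp21, k_dp21, w_p53_p21, k_aChk, D_ref_chk, k_iChk;
  double k_ss_dam, k_ds_dam, K_sphase, n_sphase, k_rep_ss, k_rep_ds, K_rep;
  double k_aATM, K_datm, n_atm, k_iATM, w_wip1, k_aATR, K_datr, n_atr, k_iATR;
  double k_s53, k_d53, k_d53_mdm2, K_53, w_atm_53, w_atr_53;
  double k_smm, K_5m, n_5m, mdm2_m_bas, k_dmm, k_sm2, k_dm2, w_atm_mdm2;
  double k_swm, k_dwm, k_sw1, k_dw1, wip1_m_bas;
  double w_p53_puma, w_p53_noxa, K_p53_tgt, n_p53_tgt;
  double K_trail, k_dr_act, k_dr_deact, k_c8_bas, k_c8_dr, dr_ref_a,
    k_c8_fb, c3_ref_a, k_iC8, k_bid, c8_ref_a, k_tbid_deg;
  double w_puma_act, K_noxa, K_bad, Kd_act, k_bax_act, A_ref, k_bax_deact;
  double k_c3_momp, K_momp, n_momp, k_c3_c8, k_iC3, k_parp_cl, death_frac;
  double xiap_pool, Kd_xiap;
  double k_bim_phos, k_bim_dep, k_pbim_xdeg, k_bad_phos, w_bad_erk,
    w_bad_akt, k_bad_dep, bim_foxo_basal, K_bim_foxo;
  double w_bim_act, w_bad_act;
  double dt_window_s, n_substeps;
};

static double pget(const NumericVector &pv, const char *nm) {
  if (!pv.containsElementNamed(nm))
    stop(std::string("missing network parameter: ") + nm);
  return pv[nm];
}

static Params read_params(const NumericVector &pv) {
  Params p;
#define GP(x) p.x = pget(pv, #x)
  GP(k_gac); GP(k_gin);
  GP(theta_max); GP(theta_K); GP(theta_n); GP(bp1_Kd); GP(k_bp1_phos);
  GP(k_bp1_dep); GP(k_bp_fos);
  GP(rib0); GP(k_rib_syn); GP(rib_basal); GP(k_rib_deg); GP(mtor_ref_act);
  GP(vol_max);
  GP(k_bind_egfr); GP(K_egf); GP(k_off_egfr); GP(k_int_egfr); GP(k_rec_egfr);
  GP(k_xdeg_egfr); GP(k_bas_egfr);
  GP(k_bind_insr); GP(K_ins); GP(k_off_insr); GP(k_int_insr); GP(k_rec_insr);
  GP(k_xdeg_insr); GP(k_bas_insr);
  GP(w_erk_egfr); GP(w_erk_insr); GP(w_akt_egfr); GP(w_akt_insr);
  GP(k_ras_act); GP(k_ras_bas); GP(k_ras_gap);
  GP(k_raf_act); GP(k_raf_deact); GP(k_raf_fb); GP(k_raf_rec);
  GP(braf_potency); GP(raf_mek_Kd); GP(raf_mek_Kd_hi);
  GP(k_mek_cat); GP(K_mek_sat); GP(k_mek_dep); GP(k_erk_cat); GP(K_erk_sat);
  GP(k_erk_dep); GP(K_meki); GP(K_akti); GP(act_frac_ref);
  GP(k_pi3k_act); GP(k_pi3k_bas); GP(k_pi3k_deact); GP(K_fb_pi3k);
  GP(k_pip3_syn); GP(k_pip3_deg); GP(pten_basal); GP(pip3_ref);
  GP(k_akt_cat); GP(K_akt_sat); GP(k_akt_dep); GP(k_mtor_act); GP(k_mtor_deact);
  GP(w_mtor_pip3);
  GP(k_foxo_phos); GP(k_foxo_dep); GP(k_foxo_xdeg);
  GP(tau_ierk); GP(tau_iakt);
  GP(k_fos_ind); GP(K_fos_hill); GP(n_fos); GP(w_jun_erk); GP(K_jun_erk);
  GP(w_jun_ap1); GP(K_jun_ap1); GP(n_jun); GP(w_myc_akt); GP(K_myc_akt);
  GP(ap1_ref_fos); GP(ap1_ref_jun);
  GP(ccnd_f_basal); GP(K_ap1_ccnd); GP(n_ap1_ccnd); GP(ccnd_g_basal);
  GP(K_myc_ccnd); GP(myc_ref); GP(myc_basal_frac); GP(ccnd_m_ref);
  GP(k_sD); GP(k_dD); GP(k_aE2F); GP(K_DE); GP(n_DE); GP(k_iE2F); GP(w_iA);
  GP(k_sE); GP(k_dE); GP(w_EA); GP(k_sA); GP(k_dA); GP(w_20); GP(k_sB);
  GP(K_AB); GP(n_AB); GP(k_dB); GP(w_20b); GP(k_a20); GP(K_B20); GP(n_B20);
  GP(k_i20); GP(cyca_thr); GP(cycb_thr); GP(K_p21); GP(K_chk); GP(s_entry_thresh); GP(div_frac);
  GP(cycb_peak_min); GP(k_sp21); GP(k_dp21); GP(w_p53_p21); GP(k_aChk);
  GP(D_ref_chk); GP(k_iChk);
  GP(k_ss_dam); GP(k_ds_dam); GP(K_sphase); GP(n_sphase); GP(k_rep_ss);
  GP(k_rep_ds); GP(K_rep);
  GP(k_aATM); GP(K_datm); GP(n_atm); GP(k_iATM); GP(w_wip1); GP(k_aATR);
  GP(K_datr); GP(n_atr); GP(k_iATR);
  GP(k_s53); GP(k_d53); GP(k_d53_mdm2); GP(K_53); GP(w_atm_53); GP(w_atr_53);
  GP(k_smm); GP(K_5m); GP(n_5m); GP(mdm2_m_bas); GP(k_dmm); GP(k_sm2);
  GP(k_dm2); GP(w_atm_mdm2); GP(k_swm); GP(k_dwm); GP(k_sw1); GP(k_dw1); GP(wip1_m_bas);
  GP(w_p53_puma); GP(w_p53_noxa); GP(K_p53_tgt); GP(n_p53_tgt);
  GP(K_trail); GP(k_dr_act); GP(k_dr_deact); GP(k_c8_bas); GP(k_c8_dr);
  GP(dr_ref_a); GP(k_c8_fb); GP(c3_ref_a); GP(k_iC8); GP(k_bid);
  GP(c8_ref_a); GP(k_tbid_deg);
  GP(w_puma_act); GP(K_noxa); GP(K_bad); GP(Kd_act); GP(k_bax_act);
  GP(A_ref); GP(k_bax_deact);
  GP(k_c3_momp); GP(K_momp); GP(n_momp); GP(k_c3_c8); GP(k_iC3);
  GP(k_parp_cl); GP(death_frac); GP(xiap_pool); GP(Kd_xiap);
  GP(k_bim_phos); GP(k_bim_dep); GP(k_pbim_xdeg); GP(k_bad_phos);
  GP(w_bad_erk); GP(w_bad_akt); GP(k_bad_dep); GP(bim_foxo_basal);
  GP(K_bim_foxo);
  GP(dt_window_s); GP(n_substeps);
#undef GP
  // optional arm toggles (default on)
  p.w_bim_act = pv.containsElementNamed("w_bim_act") ? (double)pv["w_bim_act"] : 1.0;
  p.w_bad_act = pv.containsElementNamed("w_bad_act") ? (double)pv["w_bad_act"] : 1.0;
  return p;
}

// model-level (tailoring-derived) quantities
struct ModelCtx {
  std::vector<double> ref;        // per-conglomerate reference totals (MCF10A)
  std::vector<double> kdp;        // per-conglomerate protein degradation 1/h
  double ccnd_kbm_gss, ccnd_kdm;  // cyclin D mRNA synthesis/decay
  double theta_ref;               // translation multiplier at starved steady state
  double ccnd_mult_ref;           // AP1 x cMyc gate at starved steady state
  // gene-level
  int n_genes;
  std::vector<int> g_total, cong, drive; // drive: 0 none 1 FOS 2 JUN 3 MYC 4 BIM 5 PUMA 6 NOXA
  std::vector<double> k_bm, k_bp, k_dm, mult_ref;
};

static double hill(double x, double K, double n) {
  if (x <= 0) return 0.0;
  double r = std::pow(x / K, n);
  return r / (1.0 + r);
}

static double quad_free(double A, double B, double Kd) {
  // free amount of A under 1:1 rapid-equilibrium binding with B
  double x = A - B - Kd;
  return 0.5 * (x + std::sqrt(x * x + 4.0 * Kd * A));
}

// inputs (doses constant within a window)
struct Inputs { double egf, ins, trail, meki, akti, etop; };

// quantities shared between RHS and the stochastic layer
struct Derived {
  double vol, theta, e4e_free, ap1, ppERK_n, eff_akt, p53, ierk, iakt,
    foxo_n, ccnd_gate, mek_free_u, raf_bound;
};

static void derive(const double *y, const Params &P, const ModelCtx &M,
                   const Inputs &U, Derived &D) {
  D.vol = std::max(y[RIB] / P.rib0, 0.05);
  double kd_be = P.bp1_Kd * D.vol;
  double bound = y[E4E_T] - quad_free(y[E4E_T], y[BP1_U], kd_be);
  D.e4e_free = std::max(y[E4E_T] - bound, 0.0);
  D.theta = P.theta_max * hill(D.e4e_free, P.theta_K * D.vol, P.theta_n);
  D.ap1 = (y[CFOS_P] / P.ap1_ref_fos) * (y[CJUN_P] / P.ap1_ref_jun) / D.vol;
  D.ppERK_n = y[ERK_PP] / (P.act_frac_ref * M.ref[CG_ERK]);
  double f_akti = P.K_akti / (P.K_akti + U.akti);
  D.eff_akt = y[AKT_PP] / (P.act_frac_ref * M.ref[CG_AKT]) * f_akti;
  D.p53 = y[P53];
  D.ierk = y[I_ERK]; D.iakt = y[I_AKT];
  D.foxo_n = y[FOXO_N];
  double f_ap1 = P.ccnd_f_basal +
    (1 - P.ccnd_f_basal) * hill(D.ap1, P.K_ap1_ccnd, P.n_ap1_ccnd);
  // cMyc arm: sustained AKT activity is required both for cMyc accumulation
  // and for its transcriptional competence; the product keeps the arm shut
  // under basal AKT although basal cMyc is high
  double myc_n = y[CMYC_P] / (P.myc_ref * D.vol);
  double g_myc = P.ccnd_g_basal +
    (1 - P.ccnd_g_basal) * hill(D.iakt * myc_n, P.K_myc_ccnd, 2.0);
  D.ccnd_gate = f_ap1 * g_myc;
  // Raf:MEK sequestration equilibrium (free unphosphorylated MEK)
  double raf_pool = y[CRAF_I] + y[BRAF_I];
  double Kd_m = P.raf_mek_Kd * D.vol;
  double Mf = y[MEK_U];
  for (int i = 0; i < 4; ++i)
    Mf = y[MEK_U] - raf_pool * Mf / (Kd_m + Mf);
  Mf = std::max(Mf, 0.0);
  D.mek_free_u = Mf;
  D.raf_bound = raf_pool * Mf / (Kd_m + Mf);
}

// per-gene transcription-rate multiplier (unnormalized)
static double gene_mult_raw(int drive, const Params &P, const Derived &D) {
  switch (drive) {
  case 1: // FOS handled additively elsewhere
    return 1.0;
  case 2:
    return 1.0 + P.w_jun_erk * hill(D.ierk, P.K_jun_erk, P.n_fos) +
      P.w_jun_ap1 * hill(D.ap1, P.K_jun_ap1, P.n_jun);
  case 3:
    return 1.0 + P.w_myc_akt * D.iakt / (P.K_myc_akt + D.iakt);
  case 4:
    // ultrasensitive FOXO dependence: contexts with high basal AKT (fast
    // basal FOXO turnover) show a strong BIM surge when AKT is inhibited
    return P.bim_foxo_basal + (1 - P.bim_foxo_basal) *
      hill(D.foxo_n, P.K_bim_foxo * D.vol, 2.0);
  case 5:
    return 1.0 + P.w_p53_puma * hill(D.p53, P.K_p53_tgt, P.n_p53_tgt);
  case 6:
    return 1.0 + P.w_p53_noxa * hill(D.p53, P.K_p53_tgt, P.n_p53_tgt);
  default:
    return 1.0;
  }
}

struct RhsOpts { bool expr_on; };

// S_c: per-conglomerate translation flux base (sum over genes of k_bp * m)
static void rhs(const double *y, double *dy, const Params &P,
                const ModelCtx &M, const Inputs &U,
                const std::vector<double> &S_c, const RhsOpts &opt) {
  for (int i = 0; i < N_STATE; ++i) dy[i] = 0.0;
  Derived D;
  derive(y, P, M, U, D);
  double vol = D.vol;
  double f_meki = P.K_meki / (P.K_meki + U.meki);

  // --- receptors
  {
    double act = (P.k_bind_egfr * U.egf / (P.K_egf + U.egf) + P.k_bas_egfr) * y[E_RS];
    double off = P.k_off_egfr * y[E_PRS];
    double internal = P.k_int_egfr * y[E_PRS];
    double rec = P.k_rec_egfr * y[E_PRI];
    dy[E_RS] += -act + off + rec;
    dy[E_PRS] += act - off - internal;
    dy[E_PRI] += internal - rec;
    if (opt.expr_on) dy[E_PRI] -= P.k_xdeg_egfr * y[E_PRI];
  }
  {
    double act = (P.k_bind_insr * U.ins / (P.K_ins + U.ins) + P.k_bas_insr) * y[I_RS];
    double off = P.k_off_insr * y[I_PRS];
    double internal = P.k_int_insr * y[I_PRS];
    double rec = P.k_rec_insr * y[I_PRI];
    dy[I_RS] += -act + off + rec;
    dy[I_PRS] += act - off - internal;
    dy[I_PRI] += internal - rec;
    if (opt.expr_on) dy[I_PRI] -= P.k_xdeg_insr * y[I_PRI];
  }
  double pE = (y[E_PRS] + y[E_PRI]) / M.ref[CG_EGFR];
  double pI = (y[I_PRS] + y[I_PRI]) / M.ref[CG_INSR];
  double S_erk = P.w_erk_egfr * pE + P.w_erk_insr * pI;
  double S_akt = P.w_akt_egfr * pE + P.w_akt_insr * pI;

  // --- Ras
  {
    double v = (P.k_ras_act * S_erk + P.k_ras_bas) * y[RAS_GDP] -
      P.k_ras_gap * y[RAS_GTP];
    dy[RAS_GDP] -= v; dy[RAS_GTP] += v;
  }

  // --- Raf isoforms (free inactive fraction set by MEK sequestration)
  double ras_n = y[RAS_GTP] / M.ref[CG_RAS];
  double Kd_m = P.raf_mek_Kd * vol;
  double frac_free = Kd_m / (Kd_m + D.mek_free_u);
  for (int iso = 0; iso < 2; ++iso) {
    int ii = iso == 0 ? CRAF_I : BRAF_I;
    int ia = iso == 0 ? CRAF_A : BRAF_A;
    int ifb = iso == 0 ? CRAF_FB : BRAF_FB;
    double free_i = y[ii] * frac_free;
    double act = P.k_raf_act * ras_n * free_i;
    double deact = P.k_raf_deact * y[ia];
    double fb = P.k_raf_fb * D.ppERK_n * (free_i + y[ia]);
    double rec = P.k_raf_rec * y[ifb];
    dy[ii] += -act + deact - P.k_raf_fb * D.ppERK_n * free_i + rec;
    dy[ia] += act - deact - P.k_raf_fb * D.ppERK_n * y[ia];
    dy[ifb] += fb - rec;
  }

  // --- MEK / ERK
  double raf_act_ref = P.act_frac_ref *
    (M.ref[CG_CRAF] + P.braf_potency * M.ref[CG_BRAF]);
  double A_raf = (y[CRAF_A] + P.braf_potency * y[BRAF_A]) / raf_act_ref;
  {
    double v = P.k_mek_cat * A_raf * D.mek_free_u /
      (P.K_mek_sat * vol + D.mek_free_u);
    double dep = P.k_mek_dep * y[MEK_PP];
    dy[MEK_U] += -v + dep; dy[MEK_PP] += v - dep;
  }
  {
    double ppmek_n = y[MEK_PP] / (P.act_frac_ref * M.ref[CG_MEK]);
    double v = P.k_erk_cat * ppmek_n * f_meki * y[ERK_U] /
      (P.K_erk_sat * vol + y[ERK_U]);
    double dep = P.k_erk_dep * y[ERK_PP];
    dy[ERK_U] += -v + dep; dy[ERK_PP] += v - dep;
  }

  // --- PI3K / PIP3 / AKT / mTOR
  double mtor_n = y[MTOR_A] / (P.mtor_ref_act * M.ref[CG_MTOR]);
  {
    double fb = P.K_fb_pi3k / (P.K_fb_pi3k + mtor_n);
    double v = (P.k_pi3k_act * S_akt * fb + P.k_pi3k_bas) * y[PI3K_I] -
      P.k_pi3k_deact * y[PI3K_A];
    dy[PI3K_I] -= v; dy[PI3K_A] += v;
  }
  dy[PIP3] += P.k_pip3_syn * y[PI3K_A] / M.ref[CG_PI3K] -
    P.k_pip3_deg * (P.pten_basal + (1 - P.pten_basal) * y[PTEN_P] / M.ref[CG_PTEN]) * y[PIP3];
  {
    double v = P.k_akt_cat * (y[PIP3] / (P.pip3_ref * vol)) * y[AKT_U] /
      (P.K_akt_sat * vol + y[AKT_U]);
    double dep = P.k_akt_dep * y[AKT_PP];
    dy[AKT_U] += -v + dep; dy[AKT_PP] += v - dep;
  }
  {
    // AKT-independent PI3K/PIP3 input keeps mTOR partially active under
    // catalytic AKT inhibition (insulin still drives PIP3)
    double pip3_n = y[PIP3] / (P.pip3_ref * vol);
    double v = P.k_mtor_act * (D.eff_akt + P.w_mtor_pip3 * pip3_n) * y[MTOR_I] -
      P.k_mtor_deact * y[MTOR_A];
    dy[MTOR_I] -= v; dy[MTOR_A] += v;
  }

  // --- 4E-BP1 phosphorylation (releases EIF4E via rapid equilibrium)
  {
    double v = P.k_bp1_phos * mtor_n * y[BP1_U] - P.k_bp1_dep * y[BP1_P];
    dy[BP1_U] -= v; dy[BP1_P] += v;
  }

  // --- FOXO shuttling
  {
    double v = P.k_foxo_phos * D.eff_akt * y[FOXO_N] - P.k_foxo_dep * y[FOXO_PC];
    dy[FOXO_N] -= v; dy[FOXO_PC] += v;
    if (opt.expr_on) dy[FOXO_PC] -= P.k_foxo_xdeg * y[FOXO_PC];
  }

  // --- leaky activity integrals
  dy[I_ERK] += (D.ppERK_n - y[I_ERK]) / P.tau_ierk;
  dy[I_AKT] += (D.eff_akt - y[I_AKT]) / P.tau_iakt;

  // --- cyclin D mRNA (deterministic link from AP1 x cMyc gate)
  dy[CYCD_M] += M.ccnd_kbm_gss * D.ccnd_gate / M.ccnd_mult_ref -
    M.ccnd_kdm * y[CYCD_M];

  // --- cell-cycle oscillator
  {
    double p21f = P.K_p21 / (P.K_p21 + y[P21]);
    double cd = y[CYCD] * p21f, ce = y[CYCE] * p21f, ca = y[CYCA] * p21f,
      cb = y[CYCB] * p21f;
    double fchk = P.K_chk / (P.K_chk + y[CHK1]);
    dy[CYCD] += P.k_sD * y[CYCD_M] / P.ccnd_m_ref - P.k_dD * y[CYCD];
    dy[E2F] += P.k_aE2F * hill(cd, P.K_DE, P.n_DE) * (1 - y[E2F]) -
      P.k_iE2F * (1 + P.w_iA * ca) * y[E2F];
    dy[CYCE] += P.k_sE * y[E2F] - P.k_dE * (1 + P.w_EA * ca) * y[CYCE];
    dy[CYCA] += P.k_sA * y[E2F] * fchk - P.k_dA * (1 + P.w_20 * y[CDC20]) * y[CYCA];
    // dead-zone thresholds (stoichiometric buffering of the mitotic
    // switch): no activation leak below the absolute threshold, which a
    // soft Hill would provide, stalling the relaxation oscillation
    dy[CYCB] += P.k_sB * hill(std::max(ca - P.cyca_thr, 0.0), P.K_AB, P.n_AB) * fchk -
      P.k_dB * (1 + P.w_20b * y[CDC20]) * y[CYCB];
    dy[CDC20] += P.k_a20 * hill(std::max(cb - P.cycb_thr, 0.0), P.K_B20, P.n_B20) *
      (1 - y[CDC20]) - P.k_i20 * y[CDC20];
    dy[P21] += P.k_sp21 * (1 + P.w_p53_p21 * y[P53]) - P.k_dp21 * y[P21];
    dy[CHK1] += P.k_aChk * ((y[D_DS] + 0.1 * y[D_SS]) / P.D_ref_chk) *
      (1 - y[CHK1]) - P.k_iChk * y[CHK1];
  }

  // --- DNA damage and p53
  {
    double p21f_dam = P.K_p21 / (P.K_p21 + y[P21]);
    double sph = (y[CYCE] + y[CYCA]) * p21f_dam;
    dy[D_SS] += P.k_ss_dam * U.etop -
      P.k_rep_ss * ((y[MSH6_P] + y[MGMT_P]) / (M.ref[CG_MSH6] + M.ref[CG_MGMT])) *
      y[D_SS] / (P.K_rep + y[D_SS]);
    dy[D_DS] += P.k_ds_dam * U.etop * hill(sph, P.K_sphase, P.n_sphase) -
      P.k_rep_ds * (y[BRCA2_P] / M.ref[CG_BRCA2]) * y[D_DS] / (P.K_rep + y[D_DS]);
    double wipf = 1.0 / (1.0 + P.w_wip1 * y[WIP1]);
    dy[ATM_A] += P.k_aATM * hill(y[D_DS], P.K_datm, P.n_atm) * (1 - y[ATM_A]) * wipf -
      P.k_iATM * y[ATM_A];
    dy[ATR_A] += P.k_aATR * hill(y[D_SS], P.K_datr, P.n_atr) * (1 - y[ATR_A]) * wipf -
      P.k_iATR * y[ATR_A];
    double stab = 1.0 / (1.0 + P.w_atm_53 * y[ATM_A] + P.w_atr_53 * y[ATR_A]);
    dy[P53] += P.k_s53 - P.k_d53 * y[P53] -
      P.k_d53_mdm2 * y[MDM2] * stab * y[P53] / (P.K_53 + y[P53]);
    double tgt = P.mdm2_m_bas + hill(y[P53], P.K_5m, P.n_5m);
    dy[MDM2_M] += P.k_smm * tgt - P.k_dmm * y[MDM2_M];
    dy[MDM2] += P.k_sm2 * y[MDM2_M] -
      P.k_dm2 * (1 + P.w_atm_mdm2 * y[ATM_A]) * y[MDM2];
    dy[WIP1_M] += P.k_swm * (P.wip1_m_bas + hill(y[P53], P.K_5m, P.n_5m)) -
      P.k_dwm * y[WIP1_M];
    dy[WIP1] += P.k_sw1 * y[WIP1_M] - P.k_dw1 * y[WIP1];
  }

  // --- apoptosis
  {
    double trail_n = U.trail / (P.K_trail + U.trail);
    double v = P.k_dr_act * trail_n * y[DR_S] - P.k_dr_deact * y[DR_A];
    dy[DR_S] -= v; dy[DR_A] += v;
    // XIAP-like stoichiometric buffer: only caspase-3 in excess of the
    // inhibitor pool is catalytically effective (zero-order ultrasensitivity)
    double c3eff = quad_free(y[C3_A], P.xiap_pool * vol, P.Kd_xiap * vol);
    double c3n = c3eff / P.c3_ref_a;
    double c8act = P.k_c8_bas + P.k_c8_dr * y[DR_A] / P.dr_ref_a +
      P.k_c8_fb * c3n;
    double v8 = c8act * y[C8_PRO] - P.k_iC8 * y[C8_A];
    dy[C8_PRO] -= v8; dy[C8_A] += v8;
    double c8n = y[C8_A] / P.c8_ref_a;
    double vb = P.k_bid * c8n * y[BID_U] - P.k_tbid_deg * y[BID_T];
    dy[BID_U] -= vb; dy[BID_T] += vb;

    double ACT = y[BID_T] + P.w_bim_act * y[BIM_U] + P.w_puma_act * y[PUMA_P];
    double b_avail = y[BCL2_P] *
      (P.K_noxa / (P.K_noxa + y[NOXA_P])) *
      (P.K_bad / (P.K_bad + P.w_bad_act * y[BAD_U]));
    double a_free = quad_free(ACT, b_avail, P.Kd_act);

    double vx = P.k_bax_act * (a_free / (P.A_ref * vol)) * y[BAX_C] -
      P.k_bax_deact * y[BAX_A];
    dy[BAX_C] -= vx; dy[BAX_A] += vx;
    // pore threshold scales with mitochondrial content (cell size)
    double momp = hill(y[BAX_A], P.K_momp * vol, P.n_momp);
    double c3act = P.k_c3_momp * momp + P.k_c3_c8 * c8n;
    double v3 = c3act * y[C3_PRO] - P.k_iC3 * y[C3_A];
    dy[C3_PRO] -= v3; dy[C3_A] += v3;
    dy[PARP_U] -= P.k_parp_cl * c3n * y[PARP_U];
    dy[PARP_C] += P.k_parp_cl * c3n * y[PARP_U];

    double vbim = P.k_bim_phos * D.ppERK_n * y[BIM_U] - P.k_bim_dep * y[BIM_P];
    dy[BIM_U] -= vbim; dy[BIM_P] += vbim;
    if (opt.expr_on) dy[BIM_P] -= P.k_pbim_xdeg * y[BIM_P];
    double vbad = P.k_bad_phos * (P.w_bad_erk * D.ppERK_n + P.w_bad_akt * D.eff_akt) *
      y[BAD_U] - P.k_bad_dep * y[BAD_P];
    dy[BAD_U] -= vbad; dy[BAD_P] += vbad;
  }

  // --- ribosome synthesis / growth
  {
    // size control: ribosome synthesis saturates as the cell grows, so an
    // undivided cell plateaus near twice its birth size
    double drive = hill(mtor_n, 0.5, 2.0);
    double size_brake = 1.0 / (1.0 + std::pow(vol / P.vol_max, 4.0));
    dy[RIB] += P.k_rib_syn * drive * size_brake +
      P.k_rib_deg * (P.rib0 - y[RIB]);
  }

  // --- gene expression fluxes
  if (opt.expr_on) {
    double trans = D.theta / M.theta_ref * (y[RIB] / P.rib0);
    for (int c = 0; c < N_CONG; ++c) {
      // translation-machinery mRNAs (TOP-like) escape cap-dependent control;
      // scaling them by theta would close an unstable global feedback loop
      double tr = (c == CG_EIF4E || c == CG_EIF4EBP1) ? (y[RIB] / P.rib0) : trans;
      if (S_c[c] > 0) dy[CG_BASE[c]] += S_c[c] * tr;
      double kd = M.kdp[c];
      if (kd > 0)
        for (size_t j = 0; j < CG_MEMBERS[c].size(); ++j)
          dy[CG_MEMBERS[c][j]] -= kd * y[CG_MEMBERS[c][j]];
    }
  }
}

// ---------------------------------------------------------------- integrator
static void rk4_step(double *y, double h, const Params &P, const ModelCtx &M,
                     const Inputs &U, const std::vector<double> &S_c,
                     const RhsOpts &opt) {
  static thread_local std::vector<double> k1(N_STATE), k2(N_STATE),
    k3(N_STATE), k4(N_STATE), tmp(N_STATE);
  rhs(y, k1.data(), P, M, U, S_c, opt);
  for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  rhs(tmp.data(), k2.data(), P, M, U, S_c, opt);
  for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  rhs(tmp.data(), k3.data(), P, M, U, S_c, opt);
  for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + h * k3[i];
  rhs(tmp.data(), k4.data(), P, M, U, S_c, opt);
  for (int i = 0; i < N_STATE; ++i) {
    y[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    if (y[i] < 0) y[i] = 0;
  }
}

// exact SSA for one gene over one window: telegraph switching + mRNA birth/death
static void ssa_gene(int &a, double &m, int g_total, double kgac, double kgin,
                     double kbm_eff, double kdm, double dt, Pcg32 &rng) {
  double t = 0.0;
  int mi = (int)std::lround(m);
  while (true) {
    double p_on = (g_total - a) * kgac;
    double p_off = a * kgin;
    double p_birth = a * kbm_eff;
    double p_death = mi * kdm;
    double tot = p_on + p_off + p_birth + p_death;
    if (tot <= 0) break;
    double tau = rng.expo(tot);
    if (t + tau > dt) break;
    t += tau;
    double u = rng.unif() * tot;
    if (u < p_on) a += 1;
    else if (u < p_on + p_off) a -= 1;
    else if (u < p_on + p_off + p_birth) mi += 1;
    else mi -= 1;
  }
  m = (double)mi;
}

static ModelCtx read_model(const List &model) {
  ModelCtx M;
  M.ref = as<std::vector<double> >(model["ref_totals"]);
  M.kdp = as<std::vector<double> >(model["kdp_cong"]);
  if ((int)M.ref.size() != N_CONG || (int)M.kdp.size() != N_CONG)
    stop("conglomerate vectors must have length %d", N_CONG);
  M.ccnd_kbm_gss = as<double>(model["ccnd_kbm_gss"]);
  M.ccnd_kdm = as<double>(model["ccnd_kdm"]);
  M.theta_ref = as<double>(model["theta_ref"]);
  M.ccnd_mult_ref = as<double>(model["ccnd_mult_ref"]);
  M.g_total = as<std::vector<int> >(model["g_total"]);
  M.cong = as<std::vector<int> >(model["cong_idx"]);
  M.drive = as<std::vector<int> >(model["drive"]);
  M.k_bm = as<std::vector<double> >(model["k_bm"]);
  M.k_bp = as<std::vector<double> >(model["k_bp"]);
  M.k_dm = as<std::vector<double> >(model["k_dm"]);
  M.mult_ref = as<std::vector<double> >(model["mult_ref"]);
  M.n_genes = M.g_total.size();
  return M;
}

// saved trajectory columns beyond time + conglomerate totals
static const char *EXTRA_NAMES[] = {
  "ppERK", "ppMEK", "ppAKT", "pEGFR", "pINSR", "RasGTP", "PIP3", "mTOR_a", "FOXO_n",
  "free_EIF4E", "theta", "I_ERK", "I_AKT", "AP1", "CycD_m", "CycD", "E2F",
  "CycE", "CycA", "CycB", "Cdc20", "p21", "Chk1", "Dss", "Dds", "ATM", "ATR",
  "p53", "MDM2", "WIP1", "BIM_active", "BAD_active", "tBID", "BAX_a", "C3_a",
  "cPARP", "cPARP_frac", "free_Raf", "RafMEK", "Rib", "Vol"
};
static const int N_EXTRA = sizeof(EXTRA_NAMES) / sizeof(EXTRA_NAMES[0]);

// [[Rcpp::export]]
CharacterVector cpp_traj_colnames() {
  CharacterVector out(1 + N_CONG + N_EXTRA);
  out[0] = "time_h";
  for (int c = 0; c < N_CONG; ++c) out[1 + c] = CONG_NAMES[c];
  for (int i = 0; i < N_EXTRA; ++i) out[1 + N_CONG + i] = EXTRA_NAMES[i];
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_cong_names() {
  CharacterVector out(N_CONG);
  for (int c = 0; c < N_CONG; ++c) out[c] = CONG_NAMES[c];
  return out;
}

// [[Rcpp::export]]
int cpp_n_state() { return N_STATE; }

static void save_row(double *row, double t, const double *y, const Params &P,
                     const ModelCtx &M, const Inputs &U) {
  Derived D;
  derive(y, P, M, U, D);
  row[0] = t;
  for (int c = 0; c < N_CONG; ++c) {
    double s = 0;
    for (size_t j = 0; j < CG_MEMBERS[c].size(); ++j) s += y[CG_MEMBERS[c][j]];
    row[1 + c] = s;
  }
  int k = 1 + N_CONG;
  double Kd_m = P.raf_mek_Kd * D.vol;
  double frac_free = Kd_m / (Kd_m + D.mek_free_u);
  double vals[N_EXTRA] = {
    y[ERK_PP], y[MEK_PP], y[AKT_PP], y[E_PRS] + y[E_PRI], y[I_PRS] + y[I_PRI],
    y[RAS_GTP], y[PIP3], y[MTOR_A], y[FOXO_N], D.e4e_free, D.theta, y[I_ERK], y[I_AKT], D.ap1, y[CYCD_M],
    y[CYCD], y[E2F], y[CYCE], y[CYCA], y[CYCB], y[CDC20], y[P21], y[CHK1],
    y[D_SS], y[D_DS], y[ATM_A], y[ATR_A], y[P53], y[MDM2], y[WIP1],
    y[BIM_U], y[BAD_U], y[BID_T], y[BAX_A], y[C3_A], y[PARP_C],
    y[PARP_C] / std::max(y[PARP_U] + y[PARP_C], 1e-12),
    (y[CRAF_I] + y[BRAF_I]) * frac_free + y[CRAF_A] + y[BRAF_A],
    D.raf_bound, y[RIB], y[RIB] / P.rib0
  };
  for (int i = 0; i < N_EXTRA; ++i) row[k + i] = vals[i];
}

// Simulate one cell for t_end hours.
// state: full ODE state (length N_STATE); mrna/active: per-gene.
// Returns trajectory, events, final state, and diagnostic references.
// [[Rcpp::export]]
List cpp_simulate_cell(NumericVector state, NumericVector mrna,
                       IntegerVector active, List model,
                       NumericVector params, NumericVector inputs,
                       List opts) {
  if (state.size() != N_STATE) stop("state must have length %d", N_STATE);
  Params P = read_params(params);
  ModelCtx M = read_model(model);
  if ((int)mrna.size() != M.n_genes || (int)active.size() != M.n_genes)
    stop("mrna/active length mismatch");

  Inputs U0;
  U0.egf = inputs["egf"]; U0.ins = inputs["ins"]; U0.trail = inputs["trail"];
  U0.meki = inputs["meki"]; U0.akti = inputs["akti"]; U0.etop = inputs["etop"];

  double t_end = as<double>(opts["t_end_h"]);
  bool stochastic = as<bool>(opts["stochastic"]);
  bool events_on = as<bool>(opts["events"]);
  bool expr_on = as<bool>(opts["expression"]);
  double stride_min = as<double>(opts["save_stride_min"]);
  uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  double dt_w = P.dt_window_s / 3600.0;
  if (opts.containsElementNamed("dt_window_s"))
    dt_w = as<double>(opts["dt_window_s"]) / 3600.0;
  int n_sub = (int)P.n_substeps;
  if (opts.containsElementNamed("n_substeps"))
    n_sub = as<int>(opts["n_substeps"]);

  int n_win = (int)std::ceil(t_end / dt_w - 1e-9);
  int save_every = std::max(1, (int)std::lround(stride_min * 60.0 / P.dt_window_s));
  if (opts.containsElementNamed("dt_window_s"))
    save_every = std::max(1, (int)std::lround(stride_min / 60.0 / dt_w));
  int n_save = n_win / save_every + 1;

  std::vector<double> y(state.begin(), state.end());
  std::vector<double> m(mrna.begin(), mrna.end());
  std::vector<int> a(active.begin(), active.end());
  Pcg32 rng(seed);

  NumericMatrix traj(n_save, 1 + N_CONG + N_EXTRA);
  std::vector<double> row(1 + N_CONG + N_EXTRA);
  RhsOpts ropt; ropt.expr_on = expr_on;

  bool dead = false;
  double t_death = NA_REAL;
  std::vector<double> div_times, s_times;
  double cycb_peak = 0.0;
  bool in_s = false;

  std::vector<double> S_c(N_CONG, 0.0);
  Inputs U = U0;

  int isave = 0;
  save_row(row.data(), 0.0, y.data(), P, M, U);
  for (int j = 0; j < (int)row.size(); ++j) traj(isave, j) = row[j];
  ++isave;

  double h = dt_w / n_sub;
  for (int w = 0; w < n_win; ++w) {
    double t0 = w * dt_w;
    if (!dead) {
      // ---- stochastic (or deterministic) expression layer
      Derived D;
      derive(y.data(), P, M, U, D);
      if (expr_on) {
        for (int g = 0; g < M.n_genes; ++g) {
          if (M.cong[g] < 0) continue;
          double mult = gene_mult_raw(M.drive[g], P, D) / M.mult_ref[g];
          double kbm_eff = M.k_bm[g] * mult;
          if (M.drive[g] == 1) // FOS: additive induction on top of zero basal
            kbm_eff = M.k_bm[g] + P.k_fos_ind * hill(D.ierk, P.K_fos_hill, P.n_fos);
          if (stochastic) {
            ssa_gene(a[g], m[g], M.g_total[g], P.k_gac, P.k_gin, kbm_eff,
                     M.k_dm[g], dt_w, rng);
          } else {
            // deterministic mRNA relaxation with promoter at its mean
            double gss = M.g_total[g] * P.k_gac / (P.k_gac + P.k_gin);
            if (M.k_dm[g] > 0) {
              double mss = kbm_eff * gss / M.k_dm[g];
              m[g] = mss + (m[g] - mss) * std::exp(-M.k_dm[g] * dt_w);
            }
          }
        }
        // translation flux base per conglomerate (mRNA frozen for the window)
        std::fill(S_c.begin(), S_c.end(), 0.0);
        for (int g = 0; g < M.n_genes; ++g)
          if (M.cong[g] >= 0) S_c[M.cong[g]] += M.k_bp[g] * m[g];
      }
      // ---- deterministic step with event detection on the fine grid
      for (int s = 0; s < n_sub; ++s) {
        rk4_step(y.data(), h, P, M, U, S_c, ropt);
        double tt = t0 + (s + 1) * h;
        if (events_on) {
          double ptot = y[PARP_U] + y[PARP_C];
          if (!dead && ptot > 0 && y[PARP_C] > P.death_frac * ptot) {
            dead = true; t_death = tt;
            break;
          }
          double sph = y[CYCE] + y[CYCA];
          if (!in_s && sph > P.s_entry_thresh) { in_s = true; s_times.push_back(tt); }
          if (in_s && sph < 0.5 * P.s_entry_thresh) in_s = false;
          if (y[CYCB] > cycb_peak) cycb_peak = y[CYCB];
          if (cycb_peak > P.cycb_peak_min && y[CYCB] < P.div_frac * cycb_peak) {
            div_times.push_back(tt);
            cycb_peak = 0.0;
            // symmetric division: split molecular content
            for (int i = 0; i <= BRCA2_P; ++i) y[i] *= 0.5;
            y[CYCD_M] *= 0.5; y[RIB] *= 0.5;
            y[D_SS] *= 0.5; y[D_DS] *= 0.5;
            y[E2F] = 0; y[CYCE] = 0; y[CYCA] = 0; y[CYCB] = 0; y[CDC20] = 0;
            in_s = false;
            if (stochastic) {
              for (int g = 0; g < M.n_genes; ++g)
                m[g] = (double)rng.binom_half((int)std::lround(m[g]));
            } else {
              for (int g = 0; g < M.n_genes; ++g) m[g] *= 0.5;
            }
            // translation flux follows the halved mRNA immediately
            if (expr_on) {
              std::fill(S_c.begin(), S_c.end(), 0.0);
              for (int g = 0; g < M.n_genes; ++g)
                if (M.cong[g] >= 0) S_c[M.cong[g]] += M.k_bp[g] * m[g];
            }
          }
        }
      }
    }
    if ((w + 1) % save_every == 0 && isave < n_save) {
      save_row(row.data(), (w + 1) * dt_w, y.data(), P, M, U);
      for (int j = 0; j < (int)row.size(); ++j) traj(isave, j) = row[j];
      ++isave;
    }
  }

  // unnormalized drive multipliers at the final state (used by initialization)
  Derived Df;
  derive(y.data(), P, M, U, Df);
  NumericVector mult_now(M.n_genes);
  for (int g = 0; g < M.n_genes; ++g)
    mult_now[g] = gene_mult_raw(M.drive[g], P, Df);

  return List::create(
    _["traj"] = traj,
    _["final_state"] = NumericVector(y.begin(), y.end()),
    _["final_mrna"] = NumericVector(m.begin(), m.end()),
    _["final_active"] = IntegerVector(a.begin(), a.end()),
    _["dead"] = dead,
    _["death_time"] = t_death,
    _["division_times"] = NumericVector(div_times.begin(), div_times.end()),
    _["s_entry_times"] = NumericVector(s_times.begin(), s_times.end()),
    _["mult_now"] = mult_now,
    _["theta_now"] = Df.theta,
    _["ccnd_gate_now"] = Df.ccnd_gate
  );
}

// Derivatives of the deterministic layer at a given state (oracle interface).
// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector state, List model, NumericVector params,
                      NumericVector inputs, NumericVector S_c, bool expr_on) {
  if (state.size() != N_STATE) stop("state must have length %d", N_STATE);
  Params P = read_params(params);
  ModelCtx M = read_model(model);
  Inputs U;
  U.egf = inputs["egf"]; U.ins = inputs["ins"]; U.trail = inputs["trail"];
  U.meki = inputs["meki"]; U.akti = inputs["akti"]; U.etop = inputs["etop"];
  std::vector<double> sc = as<std::vector<double> >(S_c);
  if ((int)sc.size() != N_CONG) stop("S_c must have length %d", N_CONG);
  RhsOpts opt; opt.expr_on = expr_on;
  NumericVector dy(N_STATE);
  std::vector<double> d(N_STATE);
  rhs(state.begin(), d.data(), P, M, U, sc, opt);
  std::copy(d.begin(), d.end(), dy.begin());
  return dy;
}

// One telegraph-switching window for a set of independent gene copies.
// [[Rcpp::export]]
IntegerVector cpp_step_telegraph(IntegerVector active, IntegerVector g_total,
                                 double k_gac, double k_gin, double dt,
                                 double seed) {
  Pcg32 rng((uint64_t)seed);
  IntegerVector out(active.size());
  for (int g = 0; g < active.size(); ++g) {
    int a = active[g];
    double m = 0.0;
    ssa_gene(a, m, g_total[g], k_gac, k_gin, 0.0, 0.0, dt, rng);
    out[g] = a;
  }
  return out;
}

// One mRNA birth-death window with the gene state frozen.
// [[Rcpp::export]]
IntegerVector cpp_step_mrna(IntegerVector mrna, IntegerVector active,
                            NumericVector k_bm, NumericVector k_dm,
                            double dt, double seed) {
  Pcg32 rng((uint64_t)seed);
  IntegerVector out(mrna.size());
  for (int g = 0; g < mrna.size(); ++g) {
    double m = mrna[g];
    int a = active[g];
    ssa_gene(a, m, a, 0.0, 0.0, k_bm[g], k_dm[g], dt, rng); // g_total=a: frozen
    out[g] = (int)std::lround(m);
  }
  return out;
}
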