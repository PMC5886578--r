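#' Default parameterization of the reduced mechanistic network
#'
#' Named list of every rate constant of the deterministic submodels, in units
#' of molecules and hours (doses in nM, ng/mL or uM as noted). The defaults are
#' the reference MCF10A-like parameterization: receptor trafficking makes
#' EGFR-class signaling transient and insulin-receptor-class signaling
#' sustained; basal futile cycling keeps starved ppERK/ppAKT a few percent of
#' stimulated maxima; AP1 and cMyc gate cyclin D multiplicatively; p53-MDM2-
#' WIP1 negative feedback pulses under damage; BAX-pore activation is
#' ultrasensitive so cleaved PARP accumulates as a switch-like spike.
#'
#' @return Named list of numeric parameters.
#' @export
default_network_params <- function() {
  list(
    ## promoter switching (global pair, 1/h)
    k_gac = 2, k_gin = 2,
    ## translation control: Hill of free EIF4E; 4E-BP1 sequestration
    theta_max = 2, theta_K = 8e4, theta_n = 2,
    bp1_Kd = 2e4, k_bp1_phos = 6, k_bp1_dep = 1,
    k_bp_fos = 350,
    ## ribosome synthesis / volume growth
    rib0 = 6e6, k_rib_syn = 5.5e5, rib_basal = 0.15, k_rib_deg = 0.01,
    mtor_ref_act = 0.5, vol_max = 2.5,
    ## receptors: EGFR-like (transient) and INSR/IGF1R-like (sustained)
    k_bind_egfr = 30, K_egf = 1, k_off_egfr = 6, k_int_egfr = 6,
    k_rec_egfr = 1.0, k_xdeg_egfr = 1.0, k_bas_egfr = 0.01,
    k_bind_insr = 20, K_ins = 100, k_off_insr = 6, k_int_insr = 1,
    k_rec_insr = 2, k_xdeg_insr = 0.1, k_bas_insr = 0.01,
    w_erk_egfr = 1, w_erk_insr = 0.005, w_akt_egfr = 0.9, w_akt_insr = 1,
    ## Ras GDP/GTP cycle
    k_ras_act = 30, k_ras_bas = 0.02, k_ras_gap = 30,
    ## Raf activation, ERK negative feedback, MEK sequestration
    k_raf_act = 40, k_raf_deact = 20, k_raf_fb = 30, k_raf_rec = 1,
    braf_potency = 6, raf_mek_Kd = 1.2e6, raf_mek_Kd_hi = 1.2e5,
    ## MEK -> ERK (enzyme-saturated in substrate)
    k_mek_cat = 7e5, K_mek_sat = 5e4, k_mek_dep = 6,
    k_erk_cat = 2e6, K_erk_sat = 1e5, k_erk_dep = 6,
    K_meki = 0.05, K_akti = 0.05,
    act_frac_ref = 0.3,
    ## PI3K / PIP3 / AKT with S6K-level negative feedback
    k_pi3k_act = 30, k_pi3k_bas = 0.02, k_pi3k_deact = 20, K_fb_pi3k = 0.5,
    k_pip3_syn = 3e6, k_pip3_deg = 30, pten_basal = 0.3, pip3_ref = 1e5,
    k_akt_cat = 4.2e5, K_akt_sat = 3e4, k_akt_dep = 6,
    k_mtor_act = 6, k_mtor_deact = 3, w_mtor_pip3 = 1.5,
    ## FOXO shuttling; phosphorylated (cytoplasmic) form degrades faster
    k_foxo_phos = 20, k_foxo_dep = 1, k_foxo_xdeg = 0.3,
    ## leaky time-integrals of pathway activity (h)
    tau_ierk = 2, tau_iakt = 2,
    ## immediate-early / cMyc transcriptional drives
    k_fos_ind = 90, K_fos_hill = 0.105, n_fos = 8,
    w_jun_erk = 5, K_jun_erk = 0.105, w_jun_ap1 = 20, K_jun_ap1 = 0.8,
    n_jun = 2,
    w_myc_akt = 3, K_myc_akt = 0.15,
    ap1_ref_fos = 3e4, ap1_ref_jun = 3e4,
    ## cyclin D expression: multiplicative AP1 x cMyc gate
    ccnd_f_basal = 0.15, K_ap1_ccnd = 1.6, n_ap1_ccnd = 3,
    ccnd_g_basal = 0.15, K_myc_ccnd = 0.25, myc_ref = 4.8e4,
    myc_basal_frac = 0.7, ccnd_m_ref = 120,
    ## cell-cycle relaxation oscillator (activities, dimensionless)
    k_sD = 1.2, k_dD = 1.2,
    k_aE2F = 1.5, K_DE = 0.6, n_DE = 4, k_iE2F = 0.3, w_iA = 5,
    k_sE = 0.45, k_dE = 0.3, w_EA = 2,
    k_sA = 0.18, k_dA = 0.115, w_20 = 60,
    k_sB = 16, K_AB = 0.15, n_AB = 4, k_dB = 0.6, w_20b = 10,
    k_a20 = 10, K_B20 = 0.3, n_B20 = 4, k_i20 = 1.5,
    cyca_thr = 0.4, cycb_thr = 1,
    K_p21 = 0.5, K_chk = 0.3,
    s_entry_thresh = 0.5, div_frac = 0.1, cycb_peak_min = 1,
    k_sp21 = 0.004, k_dp21 = 0.05, w_p53_p21 = 24,
    k_aChk = 2, D_ref_chk = 50, k_iChk = 0.5,
    ## DNA damage: etoposide requires S-phase cyclin activity
    k_ss_dam = 0.02, k_ds_dam = 2, K_sphase = 0.8, n_sphase = 2,
    k_rep_ss = 20, k_rep_ds = 20, K_rep = 10,
    k_aATM = 30, K_datm = 20, n_atm = 4, k_iATM = 3, w_wip1 = 40,
    k_aATR = 10, K_datr = 30, n_atr = 4, k_iATR = 2,
    ## p53 - MDM2 - WIP1 oscillator (p53 in dimensionless activity units)
    k_s53 = 0.6, k_d53 = 0.05, k_d53_mdm2 = 6, K_53 = 0.3,
    w_atm_53 = 8, w_atr_53 = 1.5,
    k_smm = 2.9, K_5m = 1.5, n_5m = 4, mdm2_m_bas = 0.5, k_dmm = 3.4,
    k_sm2 = 3.4, k_dm2 = 1.7, w_atm_mdm2 = 2,
    k_swm = 0.72, k_dwm = 1.7, k_sw1 = 1.7, k_dw1 = 0.85, wip1_m_bas = 0.02,
    w_p53_puma = 14, w_p53_noxa = 14, K_p53_tgt = 1.5, n_p53_tgt = 2,
    ## apoptosis: extrinsic arm
    K_trail = 60, k_dr_act = 10, k_dr_deact = 1,
    k_c8_bas = 5e-5, k_c8_dr = 0.6, dr_ref_a = 1e4, k_c8_fb = 6,
    c3_ref_a = 1e4, k_iC8 = 1,
    k_bid = 0.3, c8_ref_a = 3000, k_tbid_deg = 1,
    ## apoptosis: intrinsic arm (BCL2-pool buffering, BAX pore)
    w_puma_act = 1, K_noxa = 2500, K_bad = 8e3, Kd_act = 2000,
    k_bax_act = 2, A_ref = 1e4, k_bax_deact = 4,
    k_c3_momp = 30, K_momp = 5.6e4, n_momp = 6, k_c3_c8 = 0.05, k_iC3 = 3,
    k_parp_cl = 6, death_frac = 0.5, xiap_pool = 2e4, Kd_xiap = 500,
    ## survival-kinase control of BIM and BAD
    k_bim_phos = 10, k_bim_dep = 2, k_pbim_xdeg = 0.1,
    k_bad_phos = 10, w_bad_erk = 0.5, w_bad_akt = 1, k_bad_dep = 2,
    bim_foxo_basal = 0.1, K_bim_foxo = 6e4,
    ## hybrid scheme
    dt_window_s = 30, n_substeps = 4
  )
}

#' Validate a network parameter list against the reference schema
#'
#' Checks that exactly the expected parameter names are present, all values
#' are finite numbers, and rate constants are non-negative.
#'
#' @param params Named list or named numeric vector.
#' @return The validated params as a named list (invisibly usable downstream).
#' @export
validate_network_params <- function(params) {
  ref <- default_network_params()
  params <- as.list(params)
  missing <- setdiff(names(ref), names(params))
  extra <- setdiff(names(params), names(ref))
  if (length(missing)) stop("missing network parameters: ",
                            paste(missing, collapse = ", "))
  if (length(extra)) stop("unknown network parameters: ",
                          paste(extra, collapse = ", "))
  vals <- unlist(params[names(ref)])
  if (!all(is.finite(vals))) stop("non-finite parameter values")
  if (any(vals < 0)) stop("negative parameter values: ",
                          paste(names(vals)[vals < 0], collapse = ", "))
  params[names(ref)]
}

#' Read / write network parameters in `key = value` text format
#'
#' One parameter per line, `name = value`; `#` starts a comment.
#'
#' @param path File path.
#' @export
read_network_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed lines: ", paste(lines[bad], collapse = "; "))
  out <- stats::setNames(
    lapply(kv, function(x) as.numeric(x[[2]])),
    vapply(kv, `[[`, "", 1L))
  validate_network_params(out)
}

#' @rdname read_network_params
#' @param params Named list of parameters.
#' @export
write_network_params <- function(params, path) {
  params <- validate_network_params(params)
  writeLines(sprintf("%s = %.15g", names(params), unlist(params)), path)
  invisible(path)
}
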