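#' Canonical deterministic state names of the reduced network
#'
#' Order matches the compiled engine exactly (verified at load time).
#' @return Character vector of species names.
#' @export
state_names <- function() {
  c("EGFR_Rs", "EGFR_pRs", "EGFR_pRi",
    "INSR_Rs", "INSR_pRs", "INSR_pRi",
    "RasGDP", "RasGTP",
    "CRaf_i", "CRaf_a", "CRaf_fb",
    "BRaf_i", "BRaf_a", "BRaf_fb",
    "MEK_u", "ppMEK",
    "ERK_u", "ppERK",
    "PI3K_i", "PI3K_a",
    "PIP3",
    "AKT_u", "ppAKT",
    "mTOR_i", "mTOR_a",
    "BP1_u", "pBP1",
    "EIF4E_T",
    "FOXO_n", "pFOXO_c",
    "I_ERK", "I_AKT",
    "CFOS_p", "CJUN_p", "CMYC_p",
    "PTEN_p",
    "DR_s", "DR_a",
    "C8_pro", "C8_a",
    "C3_pro", "C3_a",
    "PARP", "cPARP",
    "BID", "tBID",
    "BAX_c", "BAX_a",
    "BIM_u", "pBIM",
    "BAD_u", "pBAD",
    "BCL2_p", "PUMA_p", "NOXA_p",
    "MSH6_p", "MGMT_p", "BRCA2_p",
    "CycD_m", "CycD", "E2F", "CycE", "CycA", "CycB", "Cdc20", "p21", "Chk1",
    "Dss", "Dds", "ATR_a", "ATM_a",
    "p53", "MDM2_m", "MDM2", "WIP1_m", "WIP1",
    "Rib")
}

#' Conglomerate names recognized by the engine
#' @return Character vector in engine order.
#' @export
conglomerate_names <- function() as.character(cpp_cong_names())

# base ODE state index (1-based) per conglomerate, engine order
cong_base_states <- function() {
  c(EGFR = "EGFR_Rs", INSR = "INSR_Rs", RAS = "RasGDP", CRAF = "CRaf_i",
    BRAF = "BRaf_i", MEK = "MEK_u", ERK = "ERK_u", PI3K = "PI3K_i",
    AKT = "AKT_u", MTOR = "mTOR_i", EIF4EBP1 = "BP1_u", EIF4E = "EIF4E_T",
    FOXO = "FOXO_n", CFOS = "CFOS_p", CJUN = "CJUN_p", CMYC = "CMYC_p",
    PTEN = "PTEN_p", DR = "DR_s", CASP8 = "C8_pro", CASP3 = "C3_pro",
    PARP = "PARP", BID = "BID", BAX = "BAX_c", BIM = "BIM_u", BAD = "BAD_u",
    BCL2 = "BCL2_p", PUMA = "PUMA_p", NOXA = "NOXA_p", MSH6 = "MSH6_p",
    MGMT = "MGMT_p", BRCA2 = "BRCA2_p")
}

#' States belonging to each conglomerate's conserved moiety
#' @return Named list: conglomerate -> character vector of state names.
#' @export
cong_member_states <- function() {
  list(EGFR = c("EGFR_Rs", "EGFR_pRs", "EGFR_pRi"),
       INSR = c("INSR_Rs", "INSR_pRs", "INSR_pRi"),
       RAS = c("RasGDP", "RasGTP"),
       CRAF = c("CRaf_i", "CRaf_a", "CRaf_fb"),
       BRAF = c("BRaf_i", "BRaf_a", "BRaf_fb"),
       MEK = c("MEK_u", "ppMEK"),
       ERK = c("ERK_u", "ppERK"),
       PI3K = c("PI3K_i", "PI3K_a"),
       AKT = c("AKT_u", "ppAKT"),
       MTOR = c("mTOR_i", "mTOR_a"),
       EIF4EBP1 = c("BP1_u", "pBP1"),
       EIF4E = "EIF4E_T",
       FOXO = c("FOXO_n", "pFOXO_c"),
       CFOS = "CFOS_p", CJUN = "CJUN_p", CMYC = "CMYC_p", PTEN = "PTEN_p",
       DR = c("DR_s", "DR_a"),
       CASP8 = c("C8_pro", "C8_a"),
       CASP3 = c("C3_pro", "C3_a"),
       PARP = c("PARP", "cPARP"),
       BID = c("BID", "tBID"),
       BAX = c("BAX_c", "BAX_a"),
       BIM = c("BIM_u", "pBIM"),
       BAD = c("BAD_u", "pBAD"),
       BCL2 = "BCL2_p", PUMA = "PUMA_p", NOXA = "NOXA_p",
       MSH6 = "MSH6_p", MGMT = "MGMT_p", BRCA2 = "BRCA2_p")
}

drive_codes <- function() {
  c(FOS = 1L, JUN = 2L, MYC = 3L, BCL2L11 = 4L, BBC3 = 5L, PMAIP1 = 6L)
}

#' Assemble a simulation model from a tailored gene table
#'
#' Couples the per-gene expression parameters to the mechanistic network:
#' conglomerate membership indices, amount-weighted protein degradation rates
#' per conglomerate, reference (average-cell) moiety totals used to normalize
#' catalytic rate laws, and the cyclin D mRNA link (cyclin D is integrated
#' deterministically and is not part of the stochastic layer).
#'
#' @param genes A tailored `gene_table`.
#' @param params Network parameters ([default_network_params()]).
#' @param ref_totals Optional named vector of reference conglomerate totals;
#'   defaults to the table's own conglomerate protein sums. When re-tailoring
#'   to a different context, pass the base context's totals to keep network
#'   rate laws unchanged.
#' @return An object of class `sf_model`.
#' @export
build_model <- function(genes, params = default_network_params(),
                        ref_totals = NULL) {
  stopifnot(inherits(genes, "gene_table"))
  params <- validate_network_params(params)
  cn <- conglomerate_names()
  totals <- vapply(cn, function(cg)
    sum(genes$p_ss[genes$conglomerate_id == cg]), 0)
  if (is.null(ref_totals)) ref_totals <- totals
  ref_totals <- ref_totals[cn]
  if (anyNA(ref_totals)) stop("ref_totals must cover every conglomerate")
  ref_totals <- pmax(ref_totals, 1) # avoid zero-division for empty pools

  # amount-weighted protein degradation rate per conglomerate
  kdp <- vapply(cn, function(cg) {
    sel <- genes$conglomerate_id == cg
    if (!any(sel) || sum(genes$p_ss[sel]) == 0)
      return(mean(genes$k_dp[sel], na.rm = TRUE))
    sum(genes$k_dp[sel] * genes$p_ss[sel]) / sum(genes$p_ss[sel])
  }, 0)
  kdp[!is.finite(kdp)] <- log(2) / 46

  # purely induced genes (no basal mRNA) cannot inherit a translation rate
  # from the steady-state inversion; cFos uses the configured rate instead
  k_bp <- genes$k_bp
  k_bp[genes$gene_id == "FOS"] <- params$k_bp_fos

  cong_idx <- match(genes$conglomerate_id, cn) - 1L
  cong_idx[is.na(cong_idx)] <- -1L
  dc <- drive_codes()
  drive <- unname(dc[genes$gene_id])
  drive[is.na(drive)] <- 0L

  ccnd <- genes[genes$gene_id == "CCND1", , drop = FALSE]
  if (nrow(ccnd) == 1) {
    ccnd_kbm_gss <- ccnd$k_bm * ccnd$g_ss
    ccnd_kdm <- ccnd$k_dm
  } else {
    ccnd_kbm_gss <- 0; ccnd_kdm <- log(2)
  }

  structure(list(
    genes = genes,
    params = params,
    ref_totals = unname(ref_totals),
    kdp_cong = unname(kdp),
    cong_idx = as.integer(cong_idx),
    drive = as.integer(drive),
    g_total = as.integer(genes$g_total),
    k_bm = genes$k_bm,
    k_bp = k_bp,
    k_dm = genes$k_dm,
    mult_ref = rep(1, nrow(genes)),
    theta_ref = 1,
    ccnd_mult_ref = 1,
    ccnd_kbm_gss = ccnd_kbm_gss,
    ccnd_kdm = ccnd_kdm
  ), class = "sf_model")
}

# list passed to the compiled engine
model_ctx <- function(model) {
  list(ref_totals = model$ref_totals, kdp_cong = model$kdp_cong,
       ccnd_kbm_gss = model$ccnd_kbm_gss, ccnd_kdm = model$ccnd_kdm,
       theta_ref = model$theta_ref, ccnd_mult_ref = model$ccnd_mult_ref,
       g_total = model$g_total, cong_idx = model$cong_idx,
       drive = model$drive, k_bm = model$k_bm, k_bp = model$k_bp,
       k_dm = model$k_dm, mult_ref = model$mult_ref)
}

#' Construct the pre-initialization average-cell state
#'
#' All protein mass sits in the unmodified base state of each conglomerate;
#' cycle/damage species start at quiescent source-model-like values; the
#' ribosome pool starts at its average-cell value. The deterministic
#' initialization relaxes this state to the serum-starved steady state.
#'
#' @param model An `sf_model`.
#' @return A `cell_state` list with elements `state`, `mrna`, `active`.
#' @export
average_cell_state <- function(model) {
  sn <- state_names()
  y <- stats::setNames(numeric(length(sn)), sn)
  genes <- model$genes
  base <- cong_base_states()
  for (cg in names(base)) {
    tot <- sum(genes$p_ss[genes$conglomerate_id == cg])
    y[base[[cg]]] <- tot
  }
  ccnd <- genes[genes$gene_id == "CCND1", , drop = FALSE]
  y["CycD_m"] <- if (nrow(ccnd) == 1) ccnd$m_ss else 0
  y["p21"] <- 0.05
  # p53 axis starts near its basal fixed point: a cold start (MDM2 far below
  # steady state) produces a spurious p53 pulse that can latch apoptosis
  y["p53"] <- 0.05; y["MDM2_m"] <- 0.45; y["MDM2"] <- 1.0
  y["WIP1_m"] <- 0.2; y["WIP1"] <- 0.4
  y["Rib"] <- model$params$rib0
  structure(list(state = y,
                 mrna = genes$m_ss,
                 active = as.integer(round(genes$g_ss))),
            class = "cell_state")
}

default_inputs <- function() {
  c(egf = 0, ins = 0, trail = 0, meki = 0, akti = 0, etop = 0)
}

#' Advance a single cell through the hybrid simulation loop
#'
#' Low-level wrapper around the compiled engine: stochastic (or deterministic)
#' expression update and a deterministic network step alternate on the
#' exchange window.
#'
#' @param model An `sf_model`.
#' @param cell A `cell_state`.
#' @param t_end_h Duration, hours.
#' @param inputs Named dose vector (`egf` nM, `ins` nM, `trail` ng/mL,
#'   `meki` uM, `akti` uM, `etop` uM); missing entries are zero.
#' @param stochastic Use stochastic gene expression (else deterministic mean).
#' @param events Detect death/division/S-entry events.
#' @param expression Couple gene-expression fluxes (disable for
#'   signaling-only conservation analyses).
#' @param save_stride_min Trajectory save stride, minutes.
#' @param seed Integer RNG seed for this cell's stream.
#' @param dt_window_s Exchange window, seconds (default from `model$params`).
#' @param n_substeps Deterministic substeps per window.
#' @return List: `traj` (matrix with canonical column names), `cell` (final
#'   `cell_state`), `dead`, `death_time`, `division_times`, `s_entry_times`,
#'   plus drive diagnostics.
#' @export
simulate_cell <- function(model, cell, t_end_h, inputs = NULL,
                          stochastic = TRUE, events = TRUE, expression = TRUE,
                          save_stride_min = 6, seed = 1,
                          dt_window_s = NULL, n_substeps = NULL) {
  u <- default_inputs()
  if (!is.null(inputs)) u[names(inputs)] <- inputs
  opts <- list(t_end_h = t_end_h, stochastic = stochastic, events = events,
               expression = expression, save_stride_min = save_stride_min,
               seed = as.double(seed))
  if (!is.null(dt_window_s)) opts$dt_window_s <- dt_window_s
  if (!is.null(n_substeps)) opts$n_substeps <- as.integer(n_substeps)
  res <- cpp_simulate_cell(unname(cell$state), cell$mrna, cell$active,
                           model_ctx(model), unlist(model$params), u, opts)
  colnames(res$traj) <- as.character(cpp_traj_colnames())
  fs <- stats::setNames(as.numeric(res$final_state), state_names())
  list(traj = res$traj,
       cell = structure(list(state = fs, mrna = as.numeric(res$final_mrna),
                             active = as.integer(res$final_active)),
                        class = "cell_state"),
       dead = res$dead, death_time = res$death_time,
       division_times = as.numeric(res$division_times),
       s_entry_times = as.numeric(res$s_entry_times),
       mult_now = as.numeric(res$mult_now),
       theta_now = res$theta_now, ccnd_gate_now = res$ccnd_gate_now)
}

#' Deterministic network derivatives at a state (oracle access)
#'
#' Exposes the engine's right-hand side for a given state, dose vector and
#' per-conglomerate translation flux; used for fixed-point and conservation
#' analyses with an external integrator.
#'
#' @inheritParams simulate_cell
#' @param state Named state vector (see [state_names()]).
#' @param S_c Per-conglomerate translation flux base (sum of `k_bp * m`),
#'   engine conglomerate order; defaults to zero.
#' @param expression Include synthesis/degradation fluxes.
#' @return Named derivative vector, 1/h.
#' @export
network_rhs <- function(model, state, inputs = NULL, S_c = NULL,
                        expression = FALSE) {
  u <- default_inputs()
  if (!is.null(inputs)) u[names(inputs)] <- inputs
  if (is.null(S_c)) S_c <- numeric(length(conglomerate_names()))
  dy <- cpp_rhs(unname(state), model_ctx(model), unlist(model$params), u,
                S_c, expression)
  stats::setNames(as.numeric(dy), state_names())
}

#' Translation-control multiplier from free EIF4E
#'
#' Hill function of free cap-binding factor:
#' `theta = theta_max * E^n / (K^n + E^n)`; `theta(0) = 0` and
#' `theta -> theta_max` as E grows. Mirrors the engine's rate law.
#'
#' @param free_eif4e Free EIF4E molecules (>= 0).
#' @param theta_max Saturating multiplier.
#' @param hill_k Half-saturation constant, molecules.
#' @param hill_n Hill exponent.
#' @return Multiplier in [0, theta_max).
#' @export
translation_theta <- function(free_eif4e, theta_max = 2, hill_k = 8e4,
                              hill_n = 2) {
  stopifnot(all(free_eif4e >= 0))
  r <- (free_eif4e / hill_k)^hill_n
  theta_max * r / (1 + r)
}

#' Sum a trajectory's conserved-moiety columns
#' @param traj Trajectory matrix from [simulate_cell()].
#' @return Matrix of per-conglomerate totals over time.
#' @export
moiety_totals <- function(traj) {
  traj[, conglomerate_names(), drop = FALSE]
}
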