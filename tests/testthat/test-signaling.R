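test_that("signaling-only integration conserves every closed moiety", {
  init <- cached_init()
  r <- simulate_cell(init$model, init$cell, t_end_h = 2, inputs = DOSE_GF,
                     stochastic = FALSE, events = FALSE, expression = FALSE,
                     save_stride_min = 30, seed = 0, n_substeps = 8)
  tot <- moiety_totals(r$traj)
  for (cg in c("EGFR", "INSR", "RAS", "CRAF", "BRAF", "MEK", "ERK", "PI3K",
               "AKT", "MTOR", "FOXO", "EIF4E", "EIF4EBP1", "CASP8", "CASP3",
               "PARP", "BID", "BAX", "BIM", "BAD", "DR")) {
    drift <- max(abs(tot[, cg] - tot[1, cg])) / max(tot[1, cg], 1)
    expect_lt(drift, 1e-8)
  }
})

test_that("EGF-class receptor activation is transient, insulin-class sustained", {
  init <- cached_init()
  r <- simulate_cell(init$model, init$cell, 8, inputs = DOSE_GF,
                     stochastic = FALSE, events = FALSE, save_stride_min = 5,
                     seed = 0)
  pE <- r$traj[, "pEGFR"]; pI <- r$traj[, "pINSR"]; tt <- r$traj[, "time_h"]
  peak_t <- tt[which.max(pE)]
  expect_lt(peak_t, 0.5)                               # peak within minutes
  plateau <- mean(pE[tt > 6])
  expect_gt(max(pE) / plateau, 2)                      # decline to a lower plateau
  expect_gt(mean(pI[tt > 6]) / max(pI), 0.6)           # sustained
})

test_that("basal futile cycling is nonzero but far below stimulated maxima", {
  init <- cached_init()
  basal_erk <- init$cell$state["ppERK"]
  basal_akt <- init$cell$state["ppAKT"]
  expect_gt(basal_erk, 0); expect_gt(basal_akt, 0)
  r <- simulate_cell(init$model, init$cell, 4, inputs = DOSE_GF,
                     stochastic = FALSE, events = FALSE, save_stride_min = 5,
                     seed = 0)
  expect_lt(basal_erk / max(r$traj[, "ppERK"]), 0.05)
  expect_lt(basal_akt / max(r$traj[, "ppAKT"]), 0.05)
})

test_that("saturating MEK inhibition abolishes ppERK; dose-response is monotone", {
  init <- cached_init()
  ss_pperk <- function(meki) {
    r <- simulate_cell(init$model, init$cell, 6,
                       inputs = c(DOSE_GF, meki = meki), stochastic = FALSE,
                       events = FALSE, save_stride_min = 60, seed = 0)
    r$traj[nrow(r$traj), "ppERK"]
  }
  doses <- c(0, 0.03, 0.3, 3, 30)
  resp <- vapply(doses, ss_pperk, 0)
  expect_true(all(diff(resp) < 1e-9))
  expect_lt(resp[length(resp)] / resp[1], 0.02)        # near-complete at 30 uM
})

test_that("ERK pathway dynamics match the mitogen-comparison pattern", {
  init <- cached_init()
  r_egf <- simulate_cell(init$model, init$cell, 12, inputs = DOSE_EGF,
                         stochastic = FALSE, events = FALSE,
                         save_stride_min = 30, seed = 0)
  r_gf <- simulate_cell(init$model, init$cell, 12, inputs = DOSE_GF,
                        stochastic = FALSE, events = FALSE,
                        save_stride_min = 30, seed = 0)
  tt <- r_egf$traj[, "time_h"]
  late <- tt > 1
  # ppERK(EGF) ~= ppERK(EGF+ins) pointwise within 10%
  rel <- abs(r_gf$traj[late, "ppERK"] - r_egf$traj[late, "ppERK"]) /
    pmax(r_egf$traj[late, "ppERK"], 1)
  expect_lt(max(rel), 0.10)
  # ppAKT(EGF+ins) >> ppAKT(EGF) once the EGF transient has passed
  late4 <- tt > 4
  expect_gt(min(r_gf$traj[late4, "ppAKT"] / pmax(r_egf$traj[late4, "ppAKT"], 1)),
            3)
})

test_that("Hill fitting recovers binding-cooperativity structure", {
  doses <- 10^seq(-2, 2, length.out = 12)
  # self-consistency on generated Hill data
  y <- doses / (1 + doses)
  fit <- fit_hill(doses, y, fix_range = TRUE)
  expect_equal(fit$ec50, 1, tolerance = 0.01)
  expect_equal(fit$n_hill, 1, tolerance = 0.01)
  # law-of-mass-action oracle: 1:1 equilibrium binding gives n_H ~ 1
  y11 <- binding_equilibrium_simple(doses, Kd = 0.7)
  fit11 <- fit_hill(doses, y11, fix_range = TRUE)
  expect_equal(fit11$n_hill, 1, tolerance = 0.05)
  # dimerizing receptor: n_H deviates from 1, stably across parameter jitter
  for (jit in c(1, 1.3, 0.8)) {
    yd <- binding_equilibrium_dimer(doses, R_total = 1 * jit, Kd1 = 1,
                                    Kd2 = 0.5 * jit)
    fd <- fit_hill(doses, yd / max(yd), fix_range = TRUE)
    expect_gt(fd$n_hill, 1.1)
  }
  # non-monotone data warn but still return a fit
  expect_warning(fit_hill(c(doses, 200), c(y, 0.2), fix_range = TRUE),
                 "non-monotone")
})

test_that("AP1 responds more sharply to integrated ERK than cMyc to AKT", {
  init <- cached_init()
  probe <- function(u) {
    r <- simulate_cell(init$model, init$cell, 10, inputs = u,
                       stochastic = FALSE, events = FALSE,
                       save_stride_min = 60, seed = 0)
    x <- r$traj[nrow(r$traj), ]
    c(ap1 = unname(x["AP1"]), myc = unname(x["CMYC"]),
      ierk = unname(x["I_ERK"]), iakt = unname(x["I_AKT"]))
  }
  # pathway feedback flattens the dose-response, so activities are titrated
  # with sub-saturating inhibitor doses instead of ligand doses
  e_lo <- probe(c(DOSE_GF, meki = 0.02))
  e_hi <- probe(DOSE_GF)
  a_lo <- probe(c(DOSE_GF, akti = 0.02))
  a_hi <- probe(DOSE_GF)
  resp_ap1 <- (log(e_hi["ap1"]) - log(e_lo["ap1"])) /
    (log(e_hi["ierk"]) - log(e_lo["ierk"]))
  resp_myc <- (log(a_hi["myc"]) - log(a_lo["myc"])) /
    (log(a_hi["iakt"]) - log(a_lo["iakt"]))
  expect_gt(resp_ap1, resp_myc)
})

test_that("cyclin D induction needs both pathway arms (AND gate)", {
  init <- cached_init()
  gate <- function(u) {
    r <- simulate_cell(init$model, init$cell, 16, inputs = u,
                       stochastic = FALSE, events = FALSE,
                       save_stride_min = 120, seed = 0)
    r$traj[nrow(r$traj), "CycD_m"]
  }
  basal <- gate(NULL)
  both <- gate(DOSE_GF)
  egf <- gate(DOSE_EGF)
  ins <- gate(DOSE_INS)
  expect_gt(both / basal, 3)
  expect_gt(both, egf)
  expect_gt(both, ins)
  # single arms fall far short of the dual-arm product
  expect_lt(max(egf, ins) / both, 0.75)
})

test_that("MEK sequesters Raf: overexpression raises the complex, not ppERK", {
  init <- cached_init()
  base_model <- init$model

  gt2 <- base_model$genes
  sel <- gt2$gene_id %in% c("MAP2K1", "MAP2K2")
  gt2$m_ss[sel] <- gt2$m_ss[sel] * 10
  gt2$p_ss[sel] <- gt2$p_ss[sel] * 10
  gt2 <- compute_rate_constants(gt2)
  ref <- base_model$ref_totals; names(ref) <- conglomerate_names()
  init2 <- initialize_average_cell(build_model(gt2, base_model$params,
                                               ref_totals = ref))
  expect_true(init2$report$converged)

  # more Raf:MEK complex and less free Raf at t = 0
  expect_gt(init2$cell$state["MEK_u"], 5 * init$cell$state["MEK_u"])
  r0 <- simulate_cell(init$model, init$cell, 24, inputs = DOSE_GF,
                      stochastic = FALSE, events = FALSE,
                      save_stride_min = 60, seed = 0)
  r2 <- simulate_cell(init2$model, init2$cell, 24, inputs = DOSE_GF,
                      stochastic = FALSE, events = FALSE,
                      save_stride_min = 60, seed = 0)
  expect_gt(r2$traj[1, "RafMEK"], r0$traj[1, "RafMEK"])
  expect_lt(r2$traj[1, "free_Raf"], r0$traj[1, "free_Raf"])
  # time-averaged ppERK does not increase under MEK overexpression
  avg <- function(tr) mean(tr[, "ppERK"])
  expect_lte(avg(r2$traj), avg(r0$traj) * 1.02)
})
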