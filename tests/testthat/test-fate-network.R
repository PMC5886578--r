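test_that("the cycle rests at G0 without drive and fires in cyclin order with it", {
  init <- cached_init()
  r0 <- simulate_cell(init$model, init$cell, 100, stochastic = FALSE,
                      events = TRUE, save_stride_min = 120, seed = 0)
  expect_equal(length(r0$division_times), 0)
  expect_lt(max(r0$traj[, "CycB"]), 0.2)

  r <- simulate_cell(init$model, init$cell, 30, inputs = DOSE_GF,
                     stochastic = FALSE, events = TRUE, save_stride_min = 10,
                     seed = 0)
  tt_act <- activation_times(r$traj)
  expect_true(tt_act["D"] < tt_act["E"] && tt_act["E"] < tt_act["A"] &&
                tt_act["A"] < tt_act["B"])
})

test_that("deterministic division takes about one day with ~doubled ribosomes", {
  init <- cached_init()
  r <- simulate_cell(init$model, init$cell, 35, inputs = DOSE_GF,
                     stochastic = FALSE, events = TRUE, save_stride_min = 60,
                     seed = 0)
  expect_gt(length(r$division_times), 0)
  expect_gt(r$division_times[1], 20 * 0.85)
  expect_lt(r$division_times[1], 20 * 1.15)
})

test_that("cyclin ordering is invariant across random super-threshold drives", {
  init <- cached_init()
  set.seed(5)
  drives <- exp(runif(100, log(2), log(20)))
  ok <- vapply(drives, function(f) {
    m2 <- init$model
    m2$ccnd_kbm_gss <- m2$ccnd_kbm_gss * f
    r <- simulate_cell(m2, init$cell, 30, inputs = DOSE_GF,
                       stochastic = FALSE, events = TRUE,
                       save_stride_min = 20, seed = 0)
    ta <- activation_times(r$traj)
    isTRUE(ta["D"] < ta["E"] && ta["E"] < ta["A"] && ta["A"] < ta["B"])
  }, logical(1))
  expect_true(all(ok))
})

test_that("PARP moiety is conserved and the death latch never reverts", {
  init <- cached_init()
  r <- simulate_cell(init$model, init$cell, 12, inputs = c(trail = 300),
                     stochastic = FALSE, events = FALSE, expression = FALSE,
                     save_stride_min = 30, seed = 0, n_substeps = 8)
  ptot <- r$traj[, "PARP"]
  expect_lt(max(abs(ptot - ptot[1])) / ptot[1], 1e-8)

  rr <- simulate_cell(init$model, init$cell, 30, inputs = c(trail = 300),
                      stochastic = FALSE, events = TRUE, save_stride_min = 30,
                      seed = 0)
  expect_true(rr$dead)
  # frozen after death: state stops evolving
  tr <- rr$traj
  after <- tr[, "time_h"] > rr$death_time + 1
  expect_lt(max(abs(diff(tr[after, "cPARP"]))), 1e-9)
})

test_that("protected cells never spike cPARP over 100 h", {
  init <- cached_init()
  r <- simulate_cell(init$model, init$cell, 100, inputs = DOSE_GF,
                     stochastic = FALSE, events = TRUE, save_stride_min = 240,
                     seed = 0)
  expect_false(r$dead)
  expect_lt(max(r$traj[, "cPARP_frac"]), 0.25)
})

test_that("TRAIL shortens time-to-death exponentially with dose", {
  init <- cached_init()
  doses <- c(2, 10, 30, 100, 300)
  ttd <- vapply(doses, function(d) {
    r <- simulate_cell(init$model, init$cell, 60, inputs = c(trail = d),
                       stochastic = FALSE, events = TRUE,
                       save_stride_min = 360, seed = 0)
    if (r$dead) r$death_time else NA_real_
  }, 0)
  expect_true(all(is.finite(ttd)))
  expect_true(all(diff(ttd) < 0))           # monotone decreasing in dose
  fit <- minpack.lm::nlsLM(ttd ~ a * exp(-b * doses) + c0,
                           start = list(a = max(ttd) - min(ttd), b = 0.05,
                                        c0 = min(ttd)),
                           lower = c(0, 1e-4, 0))
  r2 <- 1 - sum(residuals(fit)^2) / sum((ttd - mean(ttd))^2)
  expect_gt(r2, 0.9)                        # decaying exponential shape
})

test_that("p53 pulse count rises with damage at stable amplitude and width", {
  init <- cached_init()
  pulse_stats <- function(d0, repair = TRUE, hours = 48) {
    m <- init$model
    if (!repair) m$params$k_rep_ds <- 0
    cs <- init$cell
    cs$state["Dds"] <- d0
    r <- simulate_cell(m, cs, hours, stochastic = FALSE, events = FALSE,
                       save_stride_min = 10, seed = 0)
    p <- r$traj[, "p53"]; tt <- r$traj[, "time_h"]
    pk <- which(diff(sign(diff(p))) == -2) + 1
    pk <- pk[p[pk] > 0.4]
    # width of the first pulse at 90% of its peak (later inter-pulse troughs
    # ride above half-max, so only the first pulse has a clean baseline)
    widths <- vapply(pk[1], function(i) {
      thr <- 0.9 * p[i]
      lo <- max(which(p[seq_len(i)] < thr))
      hi_candidates <- which(p[seq(i, length(p))] < thr)
      hi <- if (length(hi_candidates)) i + hi_candidates[1] - 1 else length(p)
      tt[hi] - tt[lo]
    }, 0)
    list(n = length(pk), heights = p[pk], widths = widths,
         final_p53 = p[length(p)])
  }
  a <- pulse_stats(100); b <- pulse_stats(300); c <- pulse_stats(600)
  expect_true(a$n <= b$n && b$n <= c$n && c$n > a$n)
  hh <- c(b$heights, c$heights)
  expect_lt(max(abs(hh - mean(hh))) / mean(hh), 0.2)   # amplitude within 20%
  # compare like with like: the first (complete) pulse at each dose
  expect_lt(abs(b$widths[1] - c$widths[1]) / c$widths[1], 0.2)
  # amplitude CV across pulses within one cell is small
  expect_lt(sd(c$heights) / mean(c$heights), 0.2)
  # repair returns p53 to baseline; without repair pulsing persists >= 3x longer
  rep_on <- pulse_stats(150, repair = TRUE)
  rep_off <- pulse_stats(150, repair = FALSE)
  expect_lt(rep_on$final_p53, 0.4)
  expect_gt(rep_off$n, 3 * max(rep_on$n, 1) - 1)
})

test_that("etoposide without cycling produces neither lesions nor p53 pulses", {
  init <- cached_init()
  r <- simulate_cell(init$model, init$cell, 48, inputs = c(etop = 100),
                     stochastic = FALSE, events = TRUE, save_stride_min = 60,
                     seed = 0)
  expect_lt(max(r$traj[, "Dds"]), 5)
  expect_lt(max(r$traj[, "p53"]), 0.5)
})

test_that("dual-inhibitor death acts mostly through the BIM arm", {
  init <- cached_init()
  pop <- cached_population(40)
  cfg <- experiment_config("combo72", egf_ngml = 20, ins_ugml = 10,
                           meki_um = 10, akti_um = 10, duration_h = 72,
                           n_cells = 40, base_seed = 101,
                           save_stride_min = 240, readout_times = 72)
  dead_at_end <- function(model) {
    ex <- run_experiment(model, pop, cfg, keep_traj = FALSE)
    ex$summary$percent_dead[1]
  }
  m_ref <- init$model
  m_bim_off <- m_ref; m_bim_off$params$w_bim_act <- 0
  m_bad_off <- m_ref; m_bad_off$params$w_bad_act <- 0
  ref <- dead_at_end(m_ref)
  no_bim <- dead_at_end(m_bim_off)
  no_bad <- dead_at_end(m_bad_off)
  # removing the BIM arm suppresses death far more than removing the BAD arm
  expect_lt(no_bim, no_bad)
  expect_lte(no_bim, ref * 0.5 + 2)
})

test_that("blunting p53-to-p21 induction increases etoposide death", {
  init <- cached_init()
  pop <- cached_population(24, base_seed = 131)
  cfg <- experiment_config("gf_etop", egf_ngml = 20, ins_ugml = 10,
                           etop_um = 100, duration_h = 72, n_cells = 24,
                           base_seed = 131, save_stride_min = 360,
                           readout_times = 72)
  ex_ref <- run_experiment(init$model, pop, cfg, keep_traj = FALSE)
  m2 <- init$model
  m2$params$w_p53_p21 <- m2$params$w_p53_p21 * 0.2
  ex_blunt <- run_experiment(m2, pop, cfg, keep_traj = FALSE)
  expect_gt(ex_blunt$summary$percent_dead[1], ex_ref$summary$percent_dead[1])
})
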