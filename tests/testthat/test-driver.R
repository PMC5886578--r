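test_that("average-cell initialization converges, is quiescent, and is idempotent", {
  init <- cached_init()
  rep <- init$report
  expect_true(rep$converged)
  expect_lt(rep$max_rel_error, 0.011)
  expect_false(rep$cycling)
  expect_false(rep$apoptotic)
  expect_lt(rep$residual_drift, 0.01)
  expect_gt(rep$basal_pperk_frac, 0)
  expect_lt(rep$basal_pperk_frac, 0.05)
  # re-running initialization on its own output converges immediately
  re <- initialize_average_cell(init$model, probe = FALSE, cell = init$cell)
  expect_true(re$report$max_rel_error <= 0.011)
  expect_lte(re$report$iterations, 2)
})

test_that("population spawning is deterministic, unbiased, and live", {
  init <- cached_init()
  p1 <- spawn_population(init$model, init$cell, 5, base_seed = 77)
  p2 <- spawn_population(init$model, init$cell, 5, base_seed = 77)
  expect_identical(p1[[3]]$state, p2[[3]]$state)
  expect_identical(p1[[3]]$mrna, p2[[3]]$mrna)
  p3 <- spawn_population(init$model, init$cell, 5, base_seed = 78)
  expect_false(identical(p1[[1]]$mrna, p3[[1]]$mrna))

  # stochasticity disabled: the cell stays the average cell
  pd <- spawn_population(init$model, init$cell, 1, base_seed = 1,
                         stochastic = FALSE)
  members <- cong_member_states()
  for (cg in c("ERK", "BIM", "BCL2", "CRAF")) {
    a <- sum(pd[[1]]$state[members[[cg]]])
    b <- sum(init$cell$state[members[[cg]]])
    expect_lt(abs(a - b) / b, 0.02)
  }

  # population protein means sit near the average-cell values
  pop <- cached_population(40)
  members <- cong_member_states()
  for (cg in c("ERK", "BCL2", "BAX", "AKT")) {
    vals <- vapply(pop, function(c) sum(c$state[members[[cg]]]), 0)
    mu0 <- sum(init$cell$state[members[[cg]]])
    expect_lt(abs(mean(vals) - mu0), 3 * sd(vals) / sqrt(length(vals)) + 0.02 * mu0)
  }
})

test_that("a zero-stimulus deterministic run keeps every species flat", {
  init <- cached_init()
  r <- simulate_cell(init$model, init$cell, 48, stochastic = FALSE,
                     events = TRUE, save_stride_min = 240, seed = 0)
  expect_false(r$dead)
  tot <- moiety_totals(r$traj)
  expect_lt(max(abs(t(tot) - tot[1, ]) / pmax(tot[1, ], 1)), 0.02)
})

test_that("population summaries count events correctly and clamp", {
  ev <- data.frame(cell_id = c(1, 2, 3, 4),
                   event = c("death", "death", "death", "s_entry"),
                   time_h = c(10, 20, 48, 30))
  s <- summarize_population(ev, n = 10, readout_times = c(24, 48))
  expect_equal(s$percent_dead, c(20, 30))
  expect_equal(s$percent_sphase, c(0, 10))
  # control subtraction clamps at zero
  ctrl <- data.frame(cell_id = 1:5, event = "s_entry", time_h = 1)
  s2 <- summarize_population(ev, 10, 48, control_events = ctrl, control_n = 5)
  expect_equal(s2$percent_proliferating, 0)
  expect_error(summarize_population(ev, 10, 48, control_events = ctrl),
               "control_n")
  empty <- summarize_population(ev[0, ], 10, 24)
  expect_equal(empty$percent_dead, 0)
  # percent_dead is nondecreasing in time
  expect_true(all(diff(s$percent_dead) >= 0))
})

test_that("experiment summaries report monotone death and frozen dead cells", {
  init <- cached_init()
  pop <- cached_population(40)
  cfg <- experiment_config("starved", duration_h = 72, n_cells = 40,
                           base_seed = 101, save_stride_min = 360)
  ex <- run_experiment(init$model, pop, cfg, keep_traj = FALSE)
  expect_true(all(diff(ex$summary$percent_dead) >= 0))
  d <- ex$events[ex$events$event == "death", ]
  expect_equal(anyDuplicated(d$cell_id), 0)  # one death per cell, ever
})

test_that("mitogen synergy and inhibitor blockade shape proliferation", {
  init <- cached_init()
  pop <- cached_population(40)
  run24 <- function(cfg) {
    cfg$duration_h <- 24; cfg$readout_times <- 24; cfg$save_stride_min <- 360
    run_experiment(init$model, pop, cfg, keep_traj = FALSE)$summary
  }
  cfgs <- make_experiment_configs(n_cells = 40, base_seed = 101)
  s_gf <- run24(cfgs$gf); s_egf <- run24(cfgs$egf)
  s_ins <- run24(cfgs$insulin); s_starv <- run24(cfgs$starved)
  s_meki <- run24(cfgs$gf_meki); s_akti <- run24(cfgs$gf_akti)
  prolif <- function(s) max(0, s$percent_sphase - s_starv$percent_sphase)
  expect_gt(prolif(s_gf), prolif(s_egf) + prolif(s_ins))  # synergy
  expect_lt(prolif(s_ins), 10)                            # insulin alone ~ none
  expect_lt(prolif(s_meki), 5)                            # either inhibitor
  expect_lt(prolif(s_akti), 5)                            #   abolishes cycling
})

test_that("inhibitor death synergy exceeds additivity at 48 h", {
  init <- cached_init()
  pop <- cached_population(40)
  dead48 <- function(cfg) {
    cfg$duration_h <- 48; cfg$readout_times <- 48; cfg$save_stride_min <- 360
    run_experiment(init$model, pop, cfg, keep_traj = FALSE)$summary$percent_dead
  }
  cfgs <- make_experiment_configs(n_cells = 40, base_seed = 101)
  d_combo <- dead48(cfgs$gf_meki_akti)
  d_meki <- dead48(cfgs$gf_meki)
  d_akti <- dead48(cfgs$gf_akti)
  d_gf <- dead48(cfgs$gf)
  expect_gt(d_combo, d_meki + d_akti - d_gf)
})

test_that("trajectory and event writers emit the documented long formats", {
  init <- cached_init()
  pop <- cached_population(40)[1:3]
  attr(pop, "seeds") <- 101 + 1:3
  cfg <- experiment_config("mini", egf_ngml = 20, ins_ugml = 10,
                           duration_h = 6, n_cells = 3, base_seed = 101,
                           save_stride_min = 60, readout_times = 6)
  ex <- run_experiment(init$model, pop, cfg)
  tf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_trajectories(ex, tf, species = c("ERK", "BIM"))
  write_events(ex, ef)
  tr <- utils::read.csv(tf)
  expect_setequal(names(tr), c("cell_id", "time_h", "species", "amount"))
  expect_setequal(unique(tr$species), c("ERK", "BIM"))
  expect_equal(length(unique(tr$cell_id)), 3)
  evf <- utils::read.csv(ef)
  expect_true(all(c("cell_id", "event", "time_h") %in% names(evf)))
})
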