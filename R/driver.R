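#' Initialize the serum-starved average cell
#'
#' Relaxes the deterministic model (stochasticity off, events off) to its
#' zero-stimulus steady state, then iteratively rescales each gene's effective
#' translation rate constant by target/simulated conserved-moiety total until
#' every conglomerate matches its omics-derived target within `tolerance`.
#' Transcriptional-drive and translation-control reference values are captured
#' at the same fixed point so that all drive multipliers equal one in the
#' starved state. Finally verifies that the fixed point is non-cycling and
#' non-apoptotic over a 100-h probe.
#'
#' @param model An `sf_model`.
#' @param tolerance Max relative moiety error (default 0.01).
#' @param max_iter Maximum rescaling iterations.
#' @param t_relax_h Relaxation horizon per iteration, hours.
#' @param probe Run the 100-h non-cycling/non-apoptotic probe.
#' @param cell Optional starting `cell_state` (defaults to the naive
#'   average-cell construction); pass a previously converged cell to verify
#'   idempotence cheaply.
#' @return List: `model` (with adjusted `k_bp` and drive references),
#'   `cell` (average `cell_state` at steady state), `report`
#'   (`initialization_report`).
#' @export
initialize_average_cell <- function(model, tolerance = 0.01, max_iter = 50,
                                    t_relax_h = 150, probe = TRUE,
                                    cell = NULL) {
  cn <- conglomerate_names()
  genes <- model$genes
  # a gene whose translation is knocked out cannot hold protein mass
  p_target <- ifelse(model$k_bp > 0, genes$p_ss, 0)
  targets <- vapply(cn, function(cg)
    sum(p_target[genes$conglomerate_id == cg]), 0)
  if (is.null(cell)) cell <- average_cell_state(model)
  iterations <- 0L
  err <- Inf
  errs <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    cell <- reset_execution_arm(cell)
    res <- simulate_cell(model, cell, t_end_h = t_relax_h, stochastic = FALSE,
                         events = FALSE, save_stride_min = 60,
                         seed = 0)
    cell <- res$cell
    totals <- colSums_last(res$traj, cn)
    # capture drive references at the current fixed point
    model$theta_ref <- res$theta_now
    model$ccnd_mult_ref <- res$ccnd_gate_now
    model$mult_ref <- pmax(res$mult_now, 1e-12)
    errs <- ifelse(targets > 0, abs(totals - targets) / targets, 0)
    err <- max(errs)
    if (err <= tolerance) break
    # damped update: global translation control couples all pools, so a full
    # Newton-like correction overshoots and oscillates
    ratio <- ifelse(targets > 0 & totals > 0, sqrt(targets / totals), 1)
    scale_per_gene <- ratio[match(genes$conglomerate_id, cn)]
    scale_per_gene[is.na(scale_per_gene)] <- 1
    model$k_bp <- model$k_bp * scale_per_gene
  }

  # residual drift over a further 20 h at the converged point
  res2 <- simulate_cell(model, cell, t_end_h = 20, stochastic = FALSE,
                        events = FALSE, save_stride_min = 60, seed = 0)
  tot_a <- colSums_last(res2$traj, cn, row = 1)
  tot_b <- colSums_last(res2$traj, cn)
  drift <- max(abs(tot_b - tot_a) / pmax(tot_a, 1))
  cell <- res2$cell

  cycling <- FALSE; apoptotic <- FALSE
  if (probe) {
    pr <- simulate_cell(model, cell, t_end_h = 100, stochastic = FALSE,
                        events = TRUE, save_stride_min = 60, seed = 0)
    cycling <- length(pr$division_times) > 0 || max(pr$traj[, "CycB"]) > 0.5
    apoptotic <- pr$dead
  }

  sref <- model$params$act_frac_ref
  report <- structure(list(
    converged = err <= tolerance && !cycling && !apoptotic,
    iterations = iterations,
    max_rel_error = err,
    rel_errors = stats::setNames(errs, cn),
    residual_drift = drift,
    cycling = cycling, apoptotic = apoptotic,
    basal_pperk_frac = unname(cell$state["ppERK"] / sum(cell$state[c("ERK_u", "ppERK")])),
    basal_ppakt_frac = unname(cell$state["ppAKT"] / sum(cell$state[c("AKT_u", "ppAKT")])),
    act_frac_ref = sref
  ), class = "initialization_report")

  list(model = model, cell = cell, report = report)
}

colSums_last <- function(traj, cols, row = nrow(traj)) {
  traj[row, cols]
}

# fold apoptosis execution activation back into the zymogen pools; used
# between initialization iterations so transients of a not-yet-converged
# parameter set cannot latch the (bistable) death switch in the average cell
reset_execution_arm <- function(cell) {
  s <- cell$state
  s["PARP"] <- s["PARP"] + s["cPARP"]; s["cPARP"] <- 0
  s["C3_pro"] <- s["C3_pro"] + s["C3_a"]; s["C3_a"] <- 0
  s["C8_pro"] <- s["C8_pro"] + s["C8_a"]; s["C8_a"] <- 0
  s["BID"] <- s["BID"] + s["tBID"]; s["tBID"] <- 0
  s["BAX_c"] <- s["BAX_c"] + s["BAX_a"]; s["BAX_a"] <- 0
  cell$state <- s
  cell
}

#' @export
print.initialization_report <- function(x, ...) {
  cat("Average-cell initialization:",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  iterations: %d, max moiety error: %.3g, drift: %.3g\n",
              x$iterations, x$max_rel_error, x$residual_drift))
  cat(sprintf("  basal ppERK %.2f%%, basal ppAKT %.2f%% of pool\n",
              100 * x$basal_pperk_frac, 100 * x$basal_ppakt_frac))
  if (x$cycling) cat("  WARNING: cycling at steady state\n")
  if (x$apoptotic) cat("  WARNING: apoptotic at steady state\n")
  invisible(x)
}

#' Spawn a stochastic population from the average cell
#'
#' Runs each cell's own seeded stochastic stream for 24 h in the absence of
#' stimuli, randomizing mRNA and protein levels around the average-cell state.
#' A cell that (rarely) commits to apoptosis during this pre-run is resampled
#' with a fresh seed so the experiment starts with `n` live cells.
#'
#' @param model Initialized `sf_model`.
#' @param cell Average `cell_state` from [initialize_average_cell()].
#' @param n Population size.
#' @param base_seed Base seed; cell i uses `base_seed + i`.
#' @param hours Pre-run duration (default 24).
#' @param stochastic Set FALSE to replicate the average cell (testing).
#' @return List of `cell_state` objects with attribute `seeds`.
#' @export
spawn_population <- function(model, cell, n, base_seed = 1L, hours = 24,
                             stochastic = TRUE) {
  cells <- vector("list", n)
  seeds <- integer(n)
  extra <- 0L
  for (i in seq_len(n)) {
    seed_i <- base_seed + i
    repeat {
      res <- simulate_cell(model, cell, t_end_h = hours,
                           stochastic = stochastic, events = TRUE,
                           save_stride_min = hours * 60, seed = seed_i)
      if (!res$dead) break
      extra <- extra + 1L
      seed_i <- base_seed + n + 7919L * extra
      if (extra > 50 * n) stop("population spawn failed: pervasive pre-run death")
    }
    cells[[i]] <- res$cell
    seeds[i] <- seed_i
  }
  attr(cells, "seeds") <- seeds
  attr(cells, "resampled") <- extra
  cells
}

#' Run a virtual experiment on a population
#'
#' Advances every cell through the hybrid loop under the config's stimulus,
#' logging trajectories at the save stride and fate events on the integrator's
#' fine grid. Dead cells are frozen at their death state.
#'
#' @param model Initialized `sf_model`.
#' @param population List of `cell_state` objects from [spawn_population()].
#' @param config An `experiment_config`.
#' @param stochastic Stochastic expression during the experiment.
#' @param keep_traj Keep per-cell trajectory matrices (memory-heavy for large
#'   populations; events and summaries never require dropping them).
#' @return List of class `sf_experiment`: `trajectories`, `events`
#'   (data.frame cell_id/event/time_h), `summary` ([summarize_population()]
#'   without control subtraction), `config`.
#' @export
run_experiment <- function(model, population, config, stochastic = TRUE,
                           keep_traj = TRUE) {
  validate_config(config)
  u <- config_inputs(config)
  n <- length(population)
  seeds <- attr(population, "seeds")
  if (is.null(seeds)) seeds <- config$base_seed + seq_len(n)
  trajs <- if (keep_traj) vector("list", n) else NULL
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    res <- simulate_cell(model, population[[i]], t_end_h = config$duration_h,
                         inputs = u, stochastic = stochastic, events = TRUE,
                         save_stride_min = config$save_stride_min,
                         seed = seeds[i] + 1000003)
    if (keep_traj) trajs[[i]] <- res$traj
    ev <- data.frame(cell_id = integer(), event = character(),
                     time_h = numeric(), stringsAsFactors = FALSE)
    if (res$dead)
      ev <- rbind(ev, data.frame(cell_id = i, event = "death",
                                 time_h = res$death_time))
    if (length(res$division_times))
      ev <- rbind(ev, data.frame(cell_id = i, event = "division",
                                 time_h = res$division_times))
    if (length(res$s_entry_times))
      ev <- rbind(ev, data.frame(cell_id = i, event = "s_entry",
                                 time_h = res$s_entry_times))
    ev_list[[i]] <- ev
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events) || nrow(events) == 0)
    events <- data.frame(cell_id = integer(), event = character(),
                         time_h = numeric(), stringsAsFactors = FALSE)
  summary <- summarize_population(events, n, config$readout_times)
  structure(list(trajectories = trajs, events = events, summary = summary,
                 config = config, n_cells = n),
            class = "sf_experiment")
}

#' Population fate summary at readout times
#'
#' Percent dead is the cumulative fraction of cells with a death event;
#' percent proliferating is the fraction that entered S phase (or beyond) by
#' the readout, minus the matched control fraction when supplied, clamped at
#' zero. Percent divided counts cells with at least one division event.
#'
#' @param events Event log data.frame (`cell_id`, `event`, `time_h`).
#' @param n Number of cells in the population.
#' @param readout_times Hours.
#' @param control_events Optional event log of the matched serum-starved
#'   control for the proliferation subtraction.
#' @param control_n Control population size (required with `control_events`).
#' @return Data.frame: time_h, percent_dead, percent_sphase,
#'   percent_proliferating, percent_divided.
#' @export
summarize_population <- function(events, n, readout_times,
                                 control_events = NULL, control_n = NULL) {
  stopifnot(n >= 1)
  if (!is.null(control_events) && is.null(control_n))
    stop("control_n required when control_events given")
  frac <- function(ev, nn, type, t) {
    if (is.null(ev) || nrow(ev) == 0) return(0)
    sel <- ev$event == type & ev$time_h <= t
    100 * length(unique(ev$cell_id[sel])) / nn
  }
  out <- lapply(readout_times, function(t) {
    dead <- frac(events, n, "death", t)
    sph <- frac(events, n, "s_entry", t)
    div <- frac(events, n, "division", t)
    prolif <- sph
    if (!is.null(control_events))
      prolif <- max(0, sph - frac(control_events, control_n, "s_entry", t))
    data.frame(time_h = t, percent_dead = dead, percent_sphase = sph,
               percent_proliferating = prolif, percent_divided = div)
  })
  do.call(rbind, out)
}

#' Write trajectories in long format (cell_id, time_h, species, amount)
#' @param experiment An `sf_experiment` with kept trajectories.
#' @param path CSV path.
#' @param species Columns to write (default: conglomerate totals).
#' @export
write_trajectories <- function(experiment, path,
                               species = conglomerate_names()) {
  stopifnot(!is.null(experiment$trajectories))
  rows <- lapply(seq_along(experiment$trajectories), function(i) {
    tr <- experiment$trajectories[[i]]
    do.call(rbind, lapply(species, function(sp)
      data.frame(cell_id = i, time_h = tr[, "time_h"], species = sp,
                 amount = tr[, sp])))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the fate event log as CSV
#' @param experiment An `sf_experiment`.
#' @param path CSV path.
#' @export
write_events <- function(experiment, path) {
  utils::write.csv(experiment$events, path, row.names = FALSE)
  invisible(path)
}
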