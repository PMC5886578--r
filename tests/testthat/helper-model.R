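# shared fixtures: a tailored model initialized once per test run, plus a
# small serum-starved population reused across tests
.cache <- new.env(parent = emptyenv())

cached_init <- function() {
  if (is.null(.cache$init)) {
    gt <- reference_gene_table()
    .cache$init <- initialize_average_cell(build_model(gt))
  }
  .cache$init
}

cached_population <- function(n = 40, base_seed = 101) {
  key <- sprintf("pop_%d_%d", n, base_seed)
  if (is.null(.cache[[key]])) {
    init <- cached_init()
    .cache[[key]] <- spawn_population(init$model, init$cell, n,
                                      base_seed = base_seed)
  }
  .cache[[key]]
}

# dose vectors used throughout
DOSE_GF <- c(egf = 20 / 6.2, ins = 10000 / 5.808)
DOSE_EGF <- c(egf = 20 / 6.2)
DOSE_INS <- c(ins = 10000 / 5.808)

moiety_cols <- function() conglomerate_names()

# long-run statistics of the telegraph process via repeated window stepping
telegraph_series <- function(g_total, k_gac, k_gin, dt, n_windows, seed = 1) {
  a <- integer(n_windows)
  cur <- 0L
  for (i in seq_len(n_windows)) {
    cur <- stochfate:::cpp_step_telegraph(cur, as.integer(g_total), k_gac, k_gin, dt,
                              seed + i)[1]
    a[i] <- cur
  }
  a
}

mrna_series <- function(active, k_bm, k_dm, dt, n_windows, m0 = 0, seed = 1) {
  m <- integer(n_windows)
  cur <- as.integer(m0)
  for (i in seq_len(n_windows)) {
    cur <- stochfate:::cpp_step_mrna(cur, as.integer(active), k_bm, k_dm, dt,
                         7e5 + seed + i)[1]
    m[i] <- cur
  }
  m
}


# mechanistic activation times of the cyclin sequence: first crossing of each
# module threshold (CycD past the E2F threshold, CycA past the CycB dead-zone,
# CycB past the Cdc20 dead-zone)
activation_times <- function(tr) {
  tt <- tr[, "time_h"]
  fc <- function(sp, thr) {
    i <- which(tr[, sp] > thr)[1]
    if (is.na(i)) Inf else tt[i]
  }
  c(D = fc("CycD", 0.5), E = fc("CycE", 0.25), A = fc("CycA", 0.4),
    B = fc("CycB", 1.0))
}
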