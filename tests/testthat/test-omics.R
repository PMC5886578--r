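test_that("quantile normalization forces a common distribution and is idempotent", {
  # hand-executed rank/mean algorithm: both sorted columns are (1,2,3), so
  # the reference distribution is (1,2,3) and values map back by rank
  tab <- omics_table(c("a", "b", "c"),
                     cbind(rep1 = c(1, 2, 3), rep2 = c(3, 2, 1)), "mRNA")
  qn <- quantile_normalize(tab)
  v <- as.matrix(qn[, c("rep1", "rep2")])
  expect_equal(unname(v), cbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(sort(v[, 1]), sort(v[, 2]))
  # asymmetric example where normalization actually changes values
  tab2 <- omics_table(c("a", "b", "c"),
                      cbind(c(2, 4, 6), c(30, 20, 10)), "mRNA")
  v2 <- as.matrix(quantile_normalize(tab2)[, -1])
  expect_equal(unname(v2), cbind(c(6, 12, 18), c(18, 12, 6)))

  set.seed(4)
  big <- omics_table(sprintf("g%02d", 1:30),
                     matrix(rexp(90, 1 / 50), 30, 3), "protein")
  qn1 <- quantile_normalize(big)
  v1 <- as.matrix(qn1[, -1])
  expect_lt(diff(range(colMeans(v1))), 1e-9)      # identical column means
  for (j in 2:3)
    expect_equal(sort(v1[, 1]), sort(v1[, j]))    # identical sorted multisets
  qn2 <- quantile_normalize(qn1)
  expect_equal(as.matrix(qn2[, -1]), v1)          # idempotent

  same <- omics_table(c("a", "b"), cbind(c(5, 1), c(5, 1)), "mRNA")
  expect_equal(as.matrix(quantile_normalize(same)[, -1]),
               as.matrix(same[, -1]))             # fixed point
  one <- omics_table("a", matrix(3), "mRNA")
  expect_warning(quantile_normalize(one), "single")
})

test_that("molecules-per-cell conversion is a share of the fixed pool", {
  pool <- pool_constants()
  solo <- omics_table("only", matrix(42), "protein")
  expect_equal(unname(to_molecules_per_cell(solo, pool)), 3.08e9)

  tab <- omics_table(c("g", "rest"), matrix(c(10, 990), 2, 1), "mRNA")
  x <- to_molecules_per_cell(tab, pool)
  expect_equal(unname(x["g"]), 4000)              # 10/1000 of 400,000
  expect_equal(sum(x), 4e5)

  scaled <- omics_table(c("g", "rest"), matrix(c(10, 990) * 17.3, 2, 1), "mRNA")
  expect_equal(to_molecules_per_cell(scaled, pool), x)  # scale invariance
  zero <- omics_table("g", matrix(0), "mRNA")
  expect_error(to_molecules_per_cell(zero, pool), "all-zero")
})

test_that("bulk-RNA-mass conversion reproduces the canonical mRNA count", {
  got <- total_mrna_from_rna_mass(26, 0.03, 2000, 339.5)
  expect_lt(abs(got - 691891) / 691891, 0.002)
  expect_equal(total_mrna_from_rna_mass(52, 0.03, 2000, 339.5), 2 * got)
  # independent unit-by-unit dimensional analysis
  grams_mrna <- 26e-12 * 0.03
  mol_mrna <- grams_mrna / (2000 * 339.5)
  expect_lt(abs(got - mol_mrna * 6.02214076e23) / got, 1e-3)
})

test_that("pool averaging lands on the rounding grid", {
  expect_equal(pool_constant_from_sources(c(173921, 360000, 691891), 1e5), 4e5)
  expect_equal(pool_constant_from_sources(123, 1), 123)
  expect_equal(pool_constant_from_sources(c(90, 110), 10), 100)
  expect_error(pool_constant_from_sources(numeric(0)), "at least one")
})

test_that("half-life inversion matches simulated exponential decay", {
  expect_equal(half_life_to_rate(log(2)), 1)
  expect_equal(half_life_to_rate(9), log(2) / 9, tolerance = 1e-12)
  expect_error(half_life_to_rate(-1))
  skip_if_not_installed("deSolve")
  k <- half_life_to_rate(9)
  out <- deSolve::ode(c(x = 100), seq(0, 9, 0.5),
                      function(t, y, p) list(-k * y), NULL)
  expect_equal(unname(out[nrow(out), "x"]), 50, tolerance = 1e-5)
})

test_that("telegraph steady state matches the stochastic long-run average", {
  expect_equal(steady_state_active_gene(2, 1, 1), 1)
  expect_equal(steady_state_active_gene(2, 0.3, 0), 2)
  expect_error(steady_state_active_gene(2, 0, 0))
  a <- telegraph_series(2, 0.5, 1.5, dt = 0.25, n_windows = 20000, seed = 11)
  m <- mean(a)
  # effective-sample-size correction via integrated autocorrelation
  rho <- acf(a, plot = FALSE, lag.max = 200)$acf[-1]
  ess <- length(a) / (1 + 2 * sum(pmax(rho, 0)))
  expect_lt(abs(m - 0.5), 3 * sd(a) / sqrt(ess))
})

test_that("rate-constant inversion makes the tailored values a fixed point", {
  g <- data.frame(gene_id = c("z", "g1"), g_total = c(2, 2),
                  k_gac = 2, k_gin = 2, t_half_mrna = 9, t_half_protein = 46,
                  m_ss = c(0, 17), p_ss = c(0, 9000))
  g <- compute_rate_constants(g)
  expect_equal(g$k_bm[1], 0); expect_equal(g$k_bp[1], 0)
  expect_equal(g$k_bm[2], (log(2) / 9) * 17 / 1, tolerance = 1e-12)
  expect_equal(g$k_bm[2], 1.309, tolerance = 1e-3)
  bad <- g; bad$g_total <- 0; bad$m_ss <- c(5, 5)
  expect_error(compute_rate_constants(bad), "zero gene copies")

  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) with(as.list(c(y, p)),
    list(c(k_bm * gss - k_dm * m, k_bp * m - k_dp * p)))
  pars <- c(k_bm = g$k_bm[2], k_dm = g$k_dm[2], k_bp = g$k_bp[2],
            k_dp = g$k_dp[2], gss = g$g_ss[2])
  out <- deSolve::ode(c(m = g$m_ss[2], p = g$p_ss[2]), c(0, 100), rhs, pars,
                      rtol = 1e-10, atol = 1e-10)
  expect_lt(abs(out[2, "m"] - g$m_ss[2]) / g$m_ss[2], 1e-6)
  expect_lt(abs(out[2, "p"] - g$p_ss[2]) / g$p_ss[2], 1e-6)
})

test_that("conglomerate aggregation sums and conserves totals", {
  per_gene <- c(MAPK1 = 746463, MAPK3 = 76314, PTEN = 60000)
  map <- data.frame(gene_id = names(per_gene),
                    conglomerate_id = c("ERK", "ERK", "PTEN"))
  agg <- aggregate_conglomerates(per_gene, map)
  expect_equal(unname(agg["ERK"]), 822777)
  expect_equal(unname(agg["PTEN"]), 60000)
  expect_equal(sum(agg), sum(per_gene))
  expect_error(aggregate_conglomerates(c(per_gene, XX = 1), map), "XX")
})

test_that("tailoring subsets to mapped genes and imputes one-sided measurements", {
  fx <- make_omics_fixture(fixture_spec(replicate_cv = 0, seed = 3))
  gt <- tailor_gene_table(fx$mrna, fx$protein, fx$copies, fx$half_lives, fx$map)
  expect_setequal(gt$gene_id, fx$map$gene_id)
  expect_equal(gt$k_dm, log(2) / gt$t_half_mrna, tolerance = 1e-12)
  # remove one gene from the protein table -> imputed via median ratio
  pt <- fx$protein[fx$protein$gene_id != "BAX", ]
  class(pt) <- class(fx$protein); attr(pt, "species_class") <- "protein"
  expect_warning(
    gt2 <- tailor_gene_table(fx$mrna, pt, fx$copies, fx$half_lives, fx$map),
    "imputing protein")
  expect_gt(gt2$p_ss[gt2$gene_id == "BAX"], 0)
})

test_that("re-tailoring swaps mRNA, keeps ratios, and zeroes knockouts", {
  fx <- make_omics_fixture(fixture_spec(replicate_cv = 0, seed = 5))
  base <- tailor_gene_table(fx$mrna, fx$protein, fx$copies, fx$half_lives, fx$map)
  same <- retailor(base, fx$mrna, character())
  expect_equal(same$m_ss, base$m_ss, tolerance = 1e-9)
  expect_equal(same$p_ss, base$p_ss, tolerance = 1e-9)

  vals <- as.matrix(fx$mrna[, -1])
  i <- match("BAX", fx$mrna$gene_id)
  vals[i, ] <- vals[i, ] * 2
  doubled <- omics_table(fx$mrna$gene_id, vals, "mRNA")
  rt <- retailor(base, doubled, knockouts = "PTEN")
  j <- match("BAX", rt$gene_id)
  ratio_preserved <- rt$p_ss[j] / rt$m_ss[j]
  expect_equal(ratio_preserved, base$p_ss[j] / base$m_ss[j], tolerance = 1e-6)
  expect_gt(rt$m_ss[j] / base$m_ss[j], 1.9)   # share shifts slightly below 2x
  expect_equal(rt$k_bp[rt$gene_id == "PTEN"], 0)
  expect_error(retailor(base, fx$mrna, knockouts = "NOPE"), "NOPE")
})

test_that("knocked-out protein decays away in simulation", {
  init <- cached_init()
  model <- init$model
  ko <- which(model$genes$gene_id == "PTEN")
  model$k_bp[ko] <- 0
  r <- simulate_cell(model, init$cell, t_end_h = 5 * 30, stochastic = FALSE,
                     events = FALSE, save_stride_min = 600, seed = 0)
  frac <- r$cell$state["PTEN_p"] / init$cell$state["PTEN_p"]
  expect_lt(frac, 0.05)  # < 5% after five half-lives (30 h each)
})
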