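#' Reference gene set of the reduced pan-cancer network
#'
#' One row per modeled gene: conglomerate membership, gene copies (MCF10A-like,
#' predominantly diploid; CDKN2A carries the homozygous deletion typical of
#' this line), anchored molecules-per-cell abundances, and mRNA/protein
#' half-lives (hours). Protein abundances of the signaling and apoptosis
#' hubs are the measured serum-starved MCF10A values (e.g. MAPK1 746,463;
#' MAP2K2 377,540; C-Raf 29,000; B-Raf 2,800; BAD 14,000; BCL2 pool 61,000;
#' cMyc 48,000; cFos 0; cJun 3,000); the remainder are realistic defaults.
#'
#' @return Data.frame with columns `gene_id`, `conglomerate_id`, `copies`,
#'   `m_ss`, `p_ss`, `t_half_mrna_h`, `t_half_protein_h`.
#' @export
reference_genome <- function() {
  g <- function(id, cong, cp, m, p, thm, thp)
    data.frame(gene_id = id, conglomerate_id = cong, copies = cp, m_ss = m,
               p_ss = p, t_half_mrna_h = thm, t_half_protein_h = thp,
               stringsAsFactors = FALSE)
  rbind(
    g("EGFR",     "EGFR",     2,  60, 150000, 6,    12),
    g("INSR",     "INSR",     2,  20,  30000, 9,    24),
    g("IGF1R",    "INSR",     2,  10,  15000, 9,    24),
    g("KRAS",     "RAS",      2,  30,  30000, 9,    40),
    g("NRAS",     "RAS",      2,  20,  20000, 9,    40),
    g("HRAS",     "RAS",      2,  15,  15000, 9,    40),
    g("RAF1",     "CRAF",     2,   5,  29000, 8,    36),
    g("BRAF",     "BRAF",     2,   2,   2800, 8,    30),
    g("MAP2K1",   "MEK",      2,  40, 147250, 9,    46),
    g("MAP2K2",   "MEK",      2,  80, 377540, 9,    46),
    g("MAPK1",    "ERK",      2, 120, 746463, 9,    60),
    g("MAPK3",    "ERK",      2,  15,  76314, 9,    60),
    g("PIK3CA",   "PI3K",     2,  25,  40000, 9,    30),
    g("PTEN",     "PTEN",     2,  40,  60000, 9,    30),
    g("AKT1",     "AKT",      2,  35,  74762, 9,    36),
    g("AKT2",     "AKT",      2,  35,  81476, 9,    36),
    g("MTOR",     "MTOR",     2,  20,  30000, 9,    40),
    g("EIF4E",    "EIF4E",    2,  50, 200000, 9,    40),
    g("EIF4EBP1", "EIF4EBP1", 2,  40, 150000, 9,    30),
    g("FOXO3",    "FOXO",     2,  10,  20000, 6,     8),
    g("FOS",      "CFOS",     2,   0,      0, 0.5,   2),
    g("JUN",      "CJUN",     2,  10,   3000, 1,     3),
    g("MYC",      "CMYC",     2,  25,  48000, 0.75,  1),
    g("BCL2",     "BCL2",     2,  20,  61000, 9,    24),
    g("BAD",      "BAD",      2,   8,  14000, 9,    12),
    g("BCL2L11",  "BIM",      2,   4,   8000, 4,     3),
    g("BBC3",     "PUMA",     2,   2,   2500, 3,   2.5),
    g("PMAIP1",   "NOXA",     2,   2,   2000, 3,     2),
    g("BAX",      "BAX",      2,  30, 100000, 9,    48),
    g("BID",      "BID",      2,  15,  30000, 9,    40),
    g("CASP8",    "CASP8",    2,  15,  30000, 9,    40),
    g("CASP3",    "CASP3",    2,  20,  50000, 9,    40),
    g("PARP1",    "PARP",     2,  50, 200000, 9,    60),
    g("TNFRSF10B","DR",       2,   8,  10000, 9,    20),
    g("BRCA2",    "BRCA2",    2,   3,   2000, 6,    20),
    g("MSH6",     "MSH6",     2,  12,  20000, 9,    30),
    g("MGMT",     "MGMT",     2,   8,  10000, 9,    40),
    g("CCND1",    "CCND1",    2,   6,   5000, 1,   0.5),
    g("CDKN2A",   "CDKN2A",   0,   0,      0, 9,    24)
  )
}

#' Specification of a synthetic omics fixture
#'
#' @param genome Data.frame as returned by [reference_genome()].
#' @param n_background Number of unmodeled background genes carrying the rest
#'   of the cellular mRNA/protein pools (log-uniform abundance prior).
#' @param replicate_cv Log-normal coefficient of variation of replicate noise.
#' @param n_replicates Replicate columns per table.
#' @param seed Integer seed; fixtures are byte-reproducible given the seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(genome = reference_genome(), n_background = 400,
                         replicate_cv = 0.2, n_replicates = 3, seed = 1L) {
  stopifnot(n_background >= 1, replicate_cv >= 0, n_replicates >= 1)
  structure(list(genome = genome, n_background = n_background,
                 replicate_cv = replicate_cv, n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_fixture_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate synthetic omics tables for the reduced gene set
#'
#' Builds raw-unit replicate tables (UMI-like for mRNA, iBAQ-like for protein)
#' whose quantile-normalized, pooled conversion recovers the genome's anchored
#' molecules-per-cell values in the noiseless expectation. Background genes
#' absorb the remaining pool mass with log-uniform abundances; replicate noise
#' is multiplicative log-normal with median equal to the true value.
#'
#' @param spec A [fixture_spec()].
#' @param pool A [pool_constants()] object.
#' @return List with elements `mrna`, `protein` ([omics_table()]s including
#'   background genes), `copies`, `half_lives`, `map` (modeled genes only).
#' @export
make_omics_fixture <- function(spec = fixture_spec(), pool = pool_constants()) {
  stopifnot(inherits(spec, "fixture_spec"))
  gen <- spec$genome
  with_fixture_seed(spec$seed, {
    nb <- spec$n_background
    bg_id <- sprintf("BG%04d", seq_len(nb))

    draw_bg <- function(total_left, lo, hi) {
      w <- exp(stats::runif(nb, log(lo), log(hi)))
      w / sum(w) * total_left
    }
    m_bg <- draw_bg(pool$total_mrna_per_cell - sum(gen$m_ss), 1, 1e3)
    p_bg <- draw_bg(pool$total_protein_per_cell - sum(gen$p_ss), 1e2, 1e7)

    # raw units: arbitrary linear scale (alpha), different per species class
    make_table <- function(x_true, ids, alpha, cls) {
      a_true <- x_true * alpha
      sig <- if (spec$replicate_cv > 0) sqrt(log(1 + spec$replicate_cv^2)) else 0
      reps <- vapply(seq_len(spec$n_replicates), function(r)
        a_true * exp(stats::rnorm(length(a_true), 0, sig)),
        numeric(length(a_true)))
      omics_table(ids, reps, cls)
    }
    ids <- c(gen$gene_id, bg_id)
    mrna <- make_table(c(gen$m_ss, m_bg), ids, alpha = 2.5, cls = "mRNA")
    protein <- make_table(c(gen$p_ss, p_bg), ids, alpha = 1e-3, cls = "protein")

    copies <- data.frame(gene_id = gen$gene_id, copies = gen$copies,
                         stringsAsFactors = FALSE)
    half_lives <- data.frame(gene_id = gen$gene_id,
                             t_half_mrna_h = gen$t_half_mrna_h,
                             t_half_protein_h = gen$t_half_protein_h,
                             stringsAsFactors = FALSE)
    map <- gen[, c("gene_id", "conglomerate_id")]
    list(mrna = mrna, protein = protein, copies = copies,
         half_lives = half_lives, map = map)
  })
}

#' Tailored gene table for the reference MCF10A-like context
#'
#' Convenience wrapper: noiseless fixture -> full tailoring pipeline. With
#' `noiseless = TRUE` (default) the anchored abundances are recovered exactly.
#'
#' @param seed Fixture seed (background gene draw).
#' @param noiseless Generate replicates without measurement noise.
#' @return A tailored `gene_table`.
#' @export
reference_gene_table <- function(seed = 1L, noiseless = TRUE) {
  spec <- fixture_spec(replicate_cv = if (noiseless) 0 else 0.2, seed = seed)
  fx <- make_omics_fixture(spec)
  tailor_gene_table(fx$mrna, fx$protein, fx$copies, fx$half_lives, fx$map)
}

#' Write all fixture tables to a directory as plain-text TSV
#' @param fx Output of [make_omics_fixture()].
#' @param dir Output directory (created if needed).
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(as.data.frame(x), file.path(dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(fx$mrna, "mrna.tsv"); wt(fx$protein, "protein.tsv")
  wt(fx$copies, "copies.tsv"); wt(fx$half_lives, "half_lives.tsv")
  wt(fx$map, "conglomerates.tsv")
  invisible(dir)
}
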