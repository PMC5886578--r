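#' Default oncogene/suppressor classification of the modeled gene set
#'
#' Used by [transformation_scan()]: oncogene mRNA is raised, tumor-suppressor
#' mRNA lowered. Genes with purely structural/readout roles are omitted.
#'
#' @return Named character vector gene_id -> `"oncogene"` / `"suppressor"`.
#' @export
transformation_classes <- function() {
  onc <- c("EGFR", "INSR", "IGF1R", "KRAS", "NRAS", "HRAS", "RAF1", "BRAF",
           "MAP2K1", "MAP2K2", "MAPK1", "MAPK3", "PIK3CA", "AKT1", "AKT2",
           "MTOR", "EIF4E", "FOS", "JUN", "MYC", "CCND1", "BCL2")
  sup <- c("PTEN", "EIF4EBP1", "FOXO3", "BCL2L11", "BAD", "BBC3", "PMAIP1")
  stats::setNames(c(rep("oncogene", length(onc)), rep("suppressor", length(sup))),
                  c(onc, sup))
}

#' Virtual transformation scan over single-gene expression changes
#'
#' For each gene, multiplies its steady-state mRNA by `fold_change` (oncogene)
#' or divides it (suppressor), re-derives the expression rate constants,
#' re-initializes the average cell, simulates the mitogen response
#' (EGF + insulin) for `duration_h`, and records percent proliferating cells
#' (S-phase entry by the readout). The wild-type baseline is included and the
#' output is sorted by proliferation.
#'
#' @param genes Tailored `gene_table`.
#' @param params Network parameters.
#' @param fold_change Expression fold change (default 10).
#' @param classes Gene classification ([transformation_classes()]); genes
#'   absent from it are skipped.
#' @param n_cells Population size per variant (deterministic if 1).
#' @param duration_h Simulated stimulus duration (default 24).
#' @param base_seed RNG seed.
#' @return Data.frame `gene_id`, `class`, `percent_proliferating`, `failed`,
#'   sorted descending; wild type appears as gene_id `"WT"`.
#' @export
transformation_scan <- function(genes, params = default_network_params(),
                                fold_change = 10,
                                classes = transformation_classes(),
                                n_cells = 20, duration_h = 24,
                                base_seed = 1) {
  base_model <- build_model(genes, params)
  base_ref <- base_model$ref_totals
  names(base_ref) <- conglomerate_names()
  cfg <- experiment_config("transform", egf_ngml = 20, ins_ugml = 10,
                           duration_h = duration_h, n_cells = n_cells,
                           base_seed = base_seed, save_stride_min = 360,
                           readout_times = duration_h)

  run_variant <- function(g2, label, cls) {
    res <- tryCatch({
      model <- build_model(g2, params, ref_totals = base_ref)
      init <- initialize_average_cell(model)
      if (!init$report$converged) stop("initialization did not converge")
      if (n_cells == 1) {
        r <- simulate_cell(init$model, init$cell, duration_h,
                           inputs = config_inputs(cfg), stochastic = FALSE,
                           events = TRUE, save_stride_min = 360, seed = 0)
        100 * as.numeric(length(r$s_entry_times) > 0)
      } else {
        pop <- spawn_population(init$model, init$cell, n_cells,
                                base_seed = base_seed)
        ex <- run_experiment(init$model, pop, cfg, keep_traj = FALSE)
        ex$summary$percent_sphase[1]
      }
    }, error = function(e) NA_real_)
    data.frame(gene_id = label, class = cls,
               percent_proliferating = res, failed = is.na(res),
               stringsAsFactors = FALSE)
  }

  rows <- list(run_variant(genes, "WT", "wild_type"))
  scan_genes <- intersect(genes$gene_id, names(classes))
  for (gid in scan_genes) {
    cls <- classes[[gid]]
    g2 <- genes
    i <- match(gid, g2$gene_id)
    fc <- if (cls == "oncogene") fold_change else 1 / fold_change
    g2$m_ss[i] <- g2$m_ss[i] * fc
    g2$p_ss[i] <- g2$p_ss[i] * fc
    g2 <- compute_rate_constants(g2)
    rows[[length(rows) + 1]] <- run_variant(g2, gid, cls)
  }
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$percent_proliferating), -1,
                    out$percent_proliferating)), , drop = FALSE]
}

#' Synthetic U87-like glioma expression context
#'
#' Builds a gene table for a PTEN-deficient glioma-like context by re-tailoring
#' the reference table: the mRNA abundances of a few PI3K-axis genes are
#' shifted (synthetic stand-ins for measured U87 levels: AKT and EGFR up,
#' FOXO up), PTEN is knocked out (translation zeroed), and protein steady
#' states are recomputed from the reference protein-to-mRNA ratios.
#'
#' @param seed Fixture seed.
#' @return A re-tailored `gene_table`.
#' @export
u87_gene_table <- function(seed = 1L) {
  fx <- make_omics_fixture(fixture_spec(replicate_cv = 0, seed = seed))
  base <- tailor_gene_table(fx$mrna, fx$protein, fx$copies, fx$half_lives, fx$map)
  mr <- fx$mrna
  vals <- as.matrix(mr[, setdiff(colnames(mr), "gene_id")])
  shift <- c(AKT1 = 2.2, AKT2 = 2.2, EGFR = 1.4, FOXO3 = 2.0)
  for (gid in names(shift)) {
    i <- match(gid, mr$gene_id)
    vals[i, ] <- vals[i, ] * shift[[gid]]
  }
  new_mrna <- omics_table(mr$gene_id, vals, "mRNA")
  retailor(base, new_mrna, knockouts = "PTEN")
}
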