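#' Pool-size constants for molecules-per-cell conversion
#'
#' Total molecule counts per average mammalian cell used to convert linear
#' omics measurements (UMI counts, iBAQ scores) into absolute copy numbers.
#' Defaults: 400,000 mRNA molecules, 3.08e9 protein molecules, and 6e6
#' ribosomes per cell.
#'
#' @param total_mrna_per_cell Total mRNA molecules per cell.
#' @param total_protein_per_cell Total protein molecules per cell.
#' @param ribosomes_per_cell Ribosome copies per cell.
#' @return An object of class `pool_constants`.
#' @export
pool_constants <- function(total_mrna_per_cell = 4e5,
                           total_protein_per_cell = 3.08e9,
                           ribosomes_per_cell = 6e6) {
  stopifnot(total_mrna_per_cell > 0, total_protein_per_cell > 0,
            ribosomes_per_cell > 0)
  structure(list(total_mrna_per_cell = total_mrna_per_cell,
                 total_protein_per_cell = total_protein_per_cell,
                 ribosomes_per_cell = ribosomes_per_cell),
            class = "pool_constants")
}

#' Construct a gene-level omics table
#'
#' A thin container for linear-unit abundance measurements: one row per gene,
#' one column per biological replicate. Values must be non-negative and in
#' units linearly proportional to molecule counts (UMI counts for mRNA, iBAQ
#' scores for protein).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param values Numeric matrix (genes x replicates) of non-negative values.
#' @param species_class Either `"mRNA"` or `"protein"`.
#' @return An object of class `omics_table` (a data.frame with attributes).
#' @export
omics_table <- function(gene_id, values, species_class = c("mRNA", "protein")) {
  species_class <- match.arg(species_class)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  stopifnot(length(gene_id) == nrow(values), ncol(values) >= 1)
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique")
  if (any(values < 0) || anyNA(values)) stop("values must be non-negative and non-missing")
  out <- data.frame(gene_id = as.character(gene_id), values,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "species_class") <- species_class
  class(out) <- c("omics_table", "data.frame")
  out
}

ot_values <- function(table) {
  as.matrix(table[, setdiff(colnames(table), "gene_id"), drop = FALSE])
}

#' Quantile normalize replicate columns
#'
#' Forces every replicate column onto the same distribution: each column's
#' sorted values are replaced by the row-wise mean of all sorted columns, and
#' values are assigned back by within-column rank (ties averaged).
#'
#' @param table An [omics_table()] with at least two replicate columns.
#' @return An `omics_table` of identical shape. Single-column input is passed
#'   through with a warning.
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  v <- ot_values(table)
  if (ncol(v) < 2) {
    warning("quantile_normalize: single replicate column, returning input unchanged")
    return(table)
  }
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    # ties get the mean of the reference values they span
    r <- rank(col, ties.method = "average")
    stats::approx(x = seq_len(length(ref)), y = ref, xout = r,
                  rule = 2)$y
  })
  dimnames(out) <- dimnames(v)
  omics_table(table$gene_id, out, attr(table, "species_class"))
}

#' Collapse replicate columns to one gene-level value
#'
#' Arithmetic mean across replicate columns (after quantile normalization the
#' columns share a distribution, so the mean is a natural collapse).
#'
#' @param table An [omics_table()].
#' @return Named numeric vector of per-gene values.
#' @export
collapse_replicates <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  v <- rowMeans(ot_values(table))
  names(v) <- table$gene_id
  v
}

#' Convert linear measurements to molecules per cell
#'
#' Measurements `A_i` that are linearly proportional to copy number `X_i`
#' satisfy `A_i / sum(A) = X_i / sum(X)`, so each gene's share of total signal
#' times the per-cell pool size gives its absolute copy number.
#'
#' @param table An [omics_table()] or a named numeric vector of collapsed
#'   gene-level values.
#' @param pool A [pool_constants()] object.
#' @param species_class Required when `table` is a bare vector.
#' @return Named numeric vector: molecules per cell per gene; sums exactly to
#'   the relevant pool constant.
#' @export
to_molecules_per_cell <- function(table, pool = pool_constants(),
                                  species_class = NULL) {
  if (inherits(table, "omics_table")) {
    species_class <- attr(table, "species_class")
    a <- collapse_replicates(table)
  } else {
    a <- table
    stopifnot(!is.null(species_class))
  }
  total <- sum(a)
  if (total <= 0) stop("all-zero table: molecule shares are undefined")
  pool_total <- switch(species_class,
                       mRNA = pool$total_mrna_per_cell,
                       protein = pool$total_protein_per_cell,
                       stop("unknown species_class: ", species_class))
  a / total * pool_total
}

#' Total mRNA per cell from bulk RNA mass
#'
#' Dimensional conversion of the total RNA mass of a typical mammalian cell to
#' an mRNA molecule count: mass in picograms times the mRNA fraction, divided
#' by the mean transcript mass (length times per-nucleotide molar mass),
#' times Avogadro's number.
#'
#' @param total_rna_pg Total cellular RNA, picograms (typical value 26).
#' @param mrna_fraction Fraction of total RNA that is mRNA (typical 0.03).
#' @param mean_transcript_nt Mean transcript length in nucleotides (typical 2000).
#' @param nt_mass_g_per_mol Mean molar mass of one nucleotide, g/mol (typical 339.5).
#' @return mRNA molecules per cell.
#' @export
total_mrna_from_rna_mass <- function(total_rna_pg, mrna_fraction,
                                     mean_transcript_nt, nt_mass_g_per_mol) {
  stopifnot(total_rna_pg > 0, mrna_fraction > 0, mean_transcript_nt > 0,
            nt_mass_g_per_mol > 0)
  avogadro <- 6.02214076e23
  total_rna_pg * 1e-12 * mrna_fraction /
    (mean_transcript_nt * nt_mass_g_per_mol) * avogadro
}

#' Average independent pool-size estimates onto a rounding grid
#'
#' @param estimates Numeric vector of molecule-count estimates (length >= 1).
#' @param rounding_grid Round the mean to the nearest multiple of this value.
#' @return Grid-rounded arithmetic mean.
#' @export
pool_constant_from_sources <- function(estimates, rounding_grid = 1e5) {
  if (length(estimates) < 1) stop("need at least one estimate")
  stopifnot(rounding_grid > 0)
  round(mean(estimates) / rounding_grid) * rounding_grid
}

#' First-order rate constant from a half-life
#'
#' @param t_half Half-life in hours (> 0); vectorized.
#' @return Rate constant `ln(2) / t_half` in 1/h.
#' @export
half_life_to_rate <- function(t_half) {
  if (any(t_half <= 0)) stop("half-lives must be positive")
  log(2) / t_half
}

#' Steady-state active gene copies of the telegraph promoter
#'
#' For a two-state promoter switching on at `k_gac` and off at `k_gin`, the
#' expected number of active copies is `k_gac * g_total / (k_gac + k_gin)`.
#'
#' @param g_total Total gene copies (0 encodes homozygous deletion).
#' @param k_gac Activation rate constant, 1/h.
#' @param k_gin Inactivation rate constant, 1/h.
#' @return Expected active copies (real-valued).
#' @export
steady_state_active_gene <- function(g_total, k_gac, k_gin) {
  if (any(k_gac + k_gin <= 0)) stop("k_gac + k_gin must be positive")
  k_gac * g_total / (k_gin + k_gac)
}

#' Fill transcription/translation rate constants of a gene table
#'
#' Inverts the steady state of the two-stage expression model: the
#' transcription rate constant is `k_bm = k_dm * m_ss / g_ss_active` and the
#' translation rate constant is `k_bp = k_dp * p_ss / m_ss`. Genes with zero
#' copies get `k_bm = 0`; genes with zero mRNA get `k_bm = k_bp = 0`.
#'
#' @param genes A `gene_table` data.frame with columns `gene_id`, `g_total`,
#'   `k_gac`, `k_gin`, `t_half_mrna`, `t_half_protein`, `m_ss`, `p_ss`.
#' @return The table with `k_dm`, `k_dp`, `g_ss`, `k_bm`, `k_bp` filled.
#' @export
compute_rate_constants <- function(genes) {
  stopifnot(all(c("gene_id", "g_total", "k_gac", "k_gin",
                  "t_half_mrna", "t_half_protein", "m_ss", "p_ss") %in%
                  names(genes)))
  bad <- genes$m_ss > 0 & genes$g_total == 0
  if (any(bad))
    stop("genes with measured mRNA but zero gene copies: ",
         paste(genes$gene_id[bad], collapse = ", "))
  genes$k_dm <- half_life_to_rate(genes$t_half_mrna)
  genes$k_dp <- half_life_to_rate(genes$t_half_protein)
  genes$g_ss <- steady_state_active_gene(genes$g_total, genes$k_gac, genes$k_gin)
  genes$k_bm <- ifelse(genes$g_ss > 0 & genes$m_ss > 0,
                       genes$k_dm * genes$m_ss / pmax(genes$g_ss, .Machine$double.eps),
                       0)
  genes$k_bp <- ifelse(genes$m_ss > 0, genes$k_dp * genes$p_ss / genes$m_ss, 0)
  genes
}

#' Sum per-gene molecule counts into signaling conglomerates
#'
#' Functionally redundant gene products (e.g. MAPK1 + MAPK3) are lumped into a
#' single model species ("conglomerate"); totals are conserved exactly.
#'
#' @param per_gene Named numeric vector, molecules per gene.
#' @param map Data.frame with columns `gene_id`, `conglomerate_id` covering
#'   every gene in `per_gene`.
#' @return Named numeric vector, molecules per conglomerate.
#' @export
aggregate_conglomerates <- function(per_gene, map) {
  stopifnot(all(c("gene_id", "conglomerate_id") %in% names(map)))
  missing <- setdiff(names(per_gene), map$gene_id)
  if (length(missing))
    stop("genes missing from conglomerate map: ", paste(missing, collapse = ", "))
  cid <- map$conglomerate_id[match(names(per_gene), map$gene_id)]
  out <- tapply(per_gene, cid, sum)
  v <- as.numeric(out)
  names(v) <- names(out)
  v
}

#' Tailor a gene table from omics inputs
#'
#' The "PREP" phase: quantile-normalize replicate tables, collapse them,
#' convert to molecules per cell, join copy numbers and half-lives, and derive
#' transcription/translation rate constants. Genes measured in only one of the
#' two species classes are imputed via the cohort-median protein-to-mRNA ratio
#' (with a warning).
#'
#' @param mrna,protein [omics_table()] objects of replicate measurements.
#' @param copies Data.frame `gene_id`, `copies` (integer gene copies).
#' @param half_lives Data.frame `gene_id`, `t_half_mrna_h`, `t_half_protein_h`.
#' @param map Conglomerate map data.frame (`gene_id`, `conglomerate_id`).
#' @param pool A [pool_constants()] object.
#' @param k_gac,k_gin Global promoter switching rates, 1/h.
#' @return A `gene_table` data.frame with all expression parameters filled and
#'   attribute `conglomerate_map`.
#' @export
tailor_gene_table <- function(mrna, protein, copies, half_lives, map,
                              pool = pool_constants(),
                              k_gac = 2, k_gin = 2) {
  m_mol <- to_molecules_per_cell(quantile_normalize(mrna), pool)
  p_mol <- to_molecules_per_cell(quantile_normalize(protein), pool)

  # pool shares use the full measured tables; the model keeps mapped genes only
  all_genes <- union(names(m_mol), names(p_mol))
  all_genes <- intersect(all_genes, map$gene_id)
  missing_meas <- setdiff(map$gene_id, union(names(m_mol), names(p_mol)))
  if (length(missing_meas))
    stop("mapped genes absent from both omics tables: ",
         paste(missing_meas, collapse = ", "))
  m_full <- stats::setNames(m_mol[match(all_genes, names(m_mol))], all_genes)
  p_full <- stats::setNames(p_mol[match(all_genes, names(p_mol))], all_genes)

  both <- !is.na(m_full) & !is.na(p_full) & m_full > 0
  ratio_med <- stats::median(p_full[both] / m_full[both], na.rm = TRUE)
  if (anyNA(m_full)) {
    warning("imputing mRNA for genes measured only at protein level: ",
            paste(all_genes[is.na(m_full)], collapse = ", "))
    m_full[is.na(m_full)] <- p_full[is.na(m_full)] / ratio_med
  }
  if (anyNA(p_full)) {
    warning("imputing protein for genes measured only at mRNA level: ",
            paste(all_genes[is.na(p_full)], collapse = ", "))
    p_full[is.na(p_full)] <- m_full[is.na(p_full)] * ratio_med
  }

  g <- data.frame(gene_id = all_genes,
                  g_total = copies$copies[match(all_genes, copies$gene_id)],
                  k_gac = k_gac, k_gin = k_gin,
                  t_half_mrna = half_lives$t_half_mrna_h[match(all_genes, half_lives$gene_id)],
                  t_half_protein = half_lives$t_half_protein_h[match(all_genes, half_lives$gene_id)],
                  m_ss = as.numeric(m_full), p_ss = as.numeric(p_full),
                  stringsAsFactors = FALSE)
  if (anyNA(g$g_total)) stop("missing copy number for: ",
                             paste(g$gene_id[is.na(g$g_total)], collapse = ", "))
  if (anyNA(g$t_half_mrna) || anyNA(g$t_half_protein))
    stop("missing half-lives for some genes")
  # a deleted gene cannot carry measured transcripts
  g$m_ss[g$g_total == 0] <- 0
  g$p_ss[g$g_total == 0] <- 0
  g <- compute_rate_constants(g)
  g$conglomerate_id <- map$conglomerate_id[match(g$gene_id, map$gene_id)]
  if (anyNA(g$conglomerate_id))
    stop("genes missing from conglomerate map: ",
         paste(g$gene_id[is.na(g$conglomerate_id)], collapse = ", "))
  class(g) <- c("gene_table", "data.frame")
  g
}

#' Re-tailor a gene table to a new expression context
#'
#' Swaps in a new mRNA table (molecules per cell recomputed from it), keeps the
#' base context's gene-specific protein-to-mRNA ratios to recompute protein
#' steady states, and zeroes the translation rate constants of knocked-out
#' genes. All other parameters are untouched.
#'
#' @param base A tailored `gene_table`.
#' @param new_mrna An [omics_table()] of replicate mRNA measurements for the
#'   new context.
#' @param knockouts Character vector of gene_ids whose translation is removed.
#' @param pool A [pool_constants()] object.
#' @return A re-tailored `gene_table`.
#' @export
retailor <- function(base, new_mrna, knockouts = character(),
                     pool = pool_constants()) {
  stopifnot(inherits(base, "gene_table"))
  unknown <- setdiff(knockouts, base$gene_id)
  if (length(unknown))
    stop("knockout genes not in model: ", paste(unknown, collapse = ", "))
  tbl <- if (ncol(ot_values(new_mrna)) >= 2) quantile_normalize(new_mrna) else new_mrna
  m_new <- to_molecules_per_cell(tbl, pool)
  idx <- match(base$gene_id, names(m_new))
  if (anyNA(idx))
    stop("new mRNA table missing genes: ",
         paste(base$gene_id[is.na(idx)], collapse = ", "))
  out <- base
  ratio <- ifelse(base$m_ss > 0, base$p_ss / base$m_ss, 0)
  out$m_ss <- as.numeric(m_new[idx])
  out$m_ss[out$g_total == 0] <- 0
  out$p_ss <- ratio * out$m_ss
  out <- compute_rate_constants(out)
  ko <- out$gene_id %in% knockouts
  out$k_bp[ko] <- 0
  out$p_ss[ko] <- 0   # no translation: the protein is removed from the system
  out
}

#' Write / read a tailored gene table as TSV
#' @param genes A `gene_table`.
#' @param path Output file path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(g) <- c("gene_table", "data.frame")
  g
}
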