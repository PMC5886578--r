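#' Build a per-cell feature matrix of conserved-moiety totals
#'
#' Predictors are the total observable amount of each protein (sum over all
#' modification states and complexes, i.e. the conserved moiety), either at
#' the experiment start or trapezoid-time-averaged over a window intersected
#' with each cell's lifetime.
#'
#' @param experiment An `sf_experiment` with kept trajectories.
#' @param mode One of `"initial"`, `"mean_8h"`, `"mean_40h"`, `"until_death"`.
#' @param species Moieties to include (default all conglomerates).
#' @return Matrix (cells x species) with attribute `death_time` (Inf for
#'   survivors) and `division_time` (first division, Inf if none).
#' @export
build_features <- function(experiment,
                           mode = c("initial", "mean_8h", "mean_40h",
                                    "until_death"),
                           species = conglomerate_names()) {
  mode <- match.arg(mode)
  stopifnot(!is.null(experiment$trajectories))
  n <- experiment$n_cells
  ev <- experiment$events
  death_time <- rep(Inf, n)
  d <- ev[ev$event == "death", ]
  death_time[d$cell_id] <- d$time_h
  division_time <- rep(Inf, n)
  dv <- ev[ev$event == "division", ]
  if (nrow(dv)) {
    first <- tapply(dv$time_h, dv$cell_id, min)
    division_time[as.integer(names(first))] <- first
  }
  tmax <- switch(mode, initial = 0, mean_8h = 8, mean_40h = 40,
                 until_death = Inf)
  feat <- t(vapply(seq_len(n), function(i) {
    tr <- experiment$trajectories[[i]]
    if (mode == "initial") return(tr[1, species])
    tend <- min(tmax, death_time[i], max(tr[, "time_h"]))
    keep <- tr[, "time_h"] <= tend + 1e-9
    if (sum(keep) < 2) return(tr[1, species])
    tt <- tr[keep, "time_h"]
    vapply(species, function(sp) {
      x <- tr[keep, sp]
      sum(diff(tt) * (x[-length(x)] + x[-1]) / 2) / (tt[length(tt)] - tt[1])
    }, 0)
  }, numeric(length(species))))
  colnames(feat) <- species
  attr(feat, "death_time") <- death_time
  attr(feat, "division_time") <- division_time
  feat
}

#' Binary fate labels from event times
#'
#' Death label: died before `death_cutoff_h` (default 40 h). Proliferation
#' label: first division within `division_cutoff_h` (default 30 h).
#'
#' @param features Output of [build_features()] (carries event times).
#' @param rule `"death"` or `"division"`.
#' @param cutoff_h Override the default cutoff.
#' @return Logical vector.
#' @export
fate_labels <- function(features, rule = c("death", "division"),
                        cutoff_h = NULL) {
  rule <- match.arg(rule)
  if (is.null(cutoff_h)) cutoff_h <- if (rule == "death") 40 else 30
  tm <- attr(features, if (rule == "death") "death_time" else "division_time")
  tm < cutoff_h
}

#' Lasso feature selection with stratified cross-validation
#'
#' L1-penalized logistic fit of the binary fate label with the penalty chosen
#' by k-fold cross-validation (folds stratified by class, seeded); returns the
#' features with nonzero coefficients at `lambda.min`, ranked by absolute
#' standardized coefficient.
#'
#' @param features Numeric matrix (cells x predictors).
#' @param labels Logical or 0/1 vector.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @return Data.frame `feature`, `coefficient`, sorted by |coefficient|;
#'   attribute `lambda` carries the selected penalty.
#' @export
lasso_select <- function(features, labels, cv_folds = 5, seed = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("labels are single-class")
  if (min(table(labels)) < 2) stop("need at least 2 cells per class")
  # stratified, seeded fold assignment
  foldid <- integer(length(labels))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(features, factor(labels), family = "binomial",
                          foldid = foldid, standardize = TRUE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  sds <- apply(features, 2, stats::sd)
  std_co <- co * sds
  nz <- std_co[co != 0]
  out <- data.frame(feature = names(nz), coefficient = unname(nz),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- cv$lambda.min
  out
}

#' ROC curve points and trapezoid AUC from a continuous score
#'
#' Thresholds sweep all observed score values; ties in the score are handled
#' by the rank construction so the trapezoid AUC equals the Mann-Whitney
#' statistic exactly.
#'
#' @param score Numeric vector (higher = more positive).
#' @param labels Logical vector.
#' @return List: `points` (data.frame fpr/tpr, nondecreasing), `auc`.
#' @export
roc_curve <- function(score, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both classes for a ROC curve")
  ord <- order(score, decreasing = TRUE)
  lab <- labels[ord]; sc <- score[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  # collapse tied scores to single operating points
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  pts <- data.frame(fpr = c(0, fp[last_of_tie] / n0),
                    tpr = c(0, tp[last_of_tie] / n1))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Mann-Whitney AUC (rank statistic; independent of the ROC construction)
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(score, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a linear max-margin classifier and evaluate held-out ROC
#'
#' Standardizes predictors by the training-split mean/SD, trains a linear
#' support vector machine on the training cells, and computes the ROC curve
#' and AUC of the decision values on the held-out cells.
#'
#' @param features Matrix (cells x predictors), restricted to the selected
#'   feature set.
#' @param labels Logical fate labels.
#' @param train_n,valid_n Split sizes (default 200/200).
#' @param seed Seed for the split.
#' @param cost SVM cost parameter.
#' @return A `fate_report` list: `features`, `train_idx`, `valid_idx`,
#'   `roc` (points), `auc`, `auc_rank`, `svm_weights`.
#' @export
train_and_roc <- function(features, labels, train_n = 200, valid_n = 200,
                          seed = 1, cost = 1) {
  labels <- as.logical(labels)
  n <- nrow(features)
  if (n < train_n + valid_n)
    stop("need at least train_n + valid_n labeled cells")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # class-stratified split: both halves carry the population class balance
  pos <- sample(which(labels)); neg <- sample(which(!labels))
  frac <- train_n / n
  n_pos_tr <- round(length(pos) * frac); n_neg_tr <- train_n - n_pos_tr
  if (n_pos_tr < 1 || n_neg_tr < 1 || n_pos_tr >= length(pos) ||
      n_neg_tr >= length(neg))
    stop("could not find a split containing both classes")
  train_idx <- c(pos[seq_len(n_pos_tr)], neg[seq_len(n_neg_tr)])
  valid_idx <- setdiff(c(pos, neg), train_idx)[seq_len(valid_n)]
  mu <- colMeans(features[train_idx, , drop = FALSE])
  sd <- apply(features[train_idx, , drop = FALSE], 2, stats::sd)
  sd[sd == 0] <- 1
  z <- sweep(sweep(features, 2, mu), 2, sd, "/")
  fit <- e1071::svm(z[train_idx, , drop = FALSE],
                    factor(labels[train_idx], levels = c(FALSE, TRUE)),
                    kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(stats::predict(fit, z[valid_idx, , drop = FALSE],
                            decision.values = TRUE), "decision.values")[, 1]
  # orient the score so larger means "TRUE", using the training split
  dv_train <- attr(stats::predict(fit, z[train_idx, , drop = FALSE],
                                  decision.values = TRUE),
                   "decision.values")[, 1]
  if (auc_rank(dv_train, labels[train_idx]) < 0.5) dv <- -dv
  roc <- roc_curve(dv, labels[valid_idx])
  w <- drop(t(fit$coefs) %*% fit$SV)
  structure(list(features = colnames(features),
                 train_idx = train_idx, valid_idx = valid_idx,
                 train_n = train_n, valid_n = valid_n,
                 roc = roc$points, auc = roc$auc,
                 auc_rank = auc_rank(dv, labels[valid_idx]),
                 svm_weights = w),
            class = "fate_report")
}

#' @export
print.fate_report <- function(x, ...) {
  cat("Linear max-margin fate classifier\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  split: %d train / %d validation\n", x$train_n, x$valid_n))
  cat(sprintf("  held-out AUC: %.3f\n", x$auc))
  invisible(x)
}

#' Correlation screen of initial protein levels against time-to-death
#'
#' Pearson correlation per moiety with a permutation p-value; cells that
#' never die are excluded.
#'
#' @param features Initial-mode feature matrix from [build_features()].
#' @param n_perm Number of permutations.
#' @param seed Permutation seed.
#' @return Data.frame `feature`, `r`, `p_perm`, sorted by |r|.
#' @export
correlation_screen <- function(features, n_perm = 1000, seed = 1) {
  dt <- attr(features, "death_time")
  sel <- is.finite(dt)
  if (sum(sel) < 5) stop("too few dying cells for a correlation screen")
  y <- dt[sel]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perms <- replicate(n_perm, sample(y))
  out <- do.call(rbind, lapply(colnames(features), function(sp) {
    x <- features[sel, sp]
    if (stats::sd(x) == 0) return(data.frame(feature = sp, r = 0, p_perm = 1))
    r <- stats::cor(x, y)
    rnull <- apply(perms, 2, function(yp) stats::cor(x, yp))
    data.frame(feature = sp, r = r,
               p_perm = (1 + sum(abs(rnull) >= abs(r))) / (1 + n_perm),
               stringsAsFactors = FALSE)
  }))
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Latin-hypercube sensitivity of death response to degradation rates
#'
#' Samples protein degradation rate constants around the tailored values
#' (log-normal Latin hypercube: a normal LHS in log10 space with standard
#' deviation `log10(sd_fold)`, so `sd_fold = 3.16` spans roughly 2-4 fold),
#' re-initializes the average cell for every set (sets failing initialization
#' are discarded and reported), simulates the dual-inhibitor + mitogen
#' experiment, and records death percentages at 24/48/72 h.
#'
#' @param genes Tailored `gene_table`.
#' @param params Network parameters.
#' @param n_sets Number of parameter sets.
#' @param sd_fold Spread parameter (default 3.16, i.e. half a decade).
#' @param n_cells Cells per population (default 25).
#' @param base_seed RNG seed for sampling and populations.
#' @param linear_space Sample in linear space instead of log space.
#' @return List: `death` (data.frame set, t24, t48, t72), `discarded`,
#'   `samples` (matrix of sampled k_dp per gene), `summary` (median and IQR
#'   per readout).
#' @export
lhs_degradation_sensitivity <- function(genes, params = default_network_params(),
                                        n_sets = 8, sd_fold = 3.16,
                                        n_cells = 25, base_seed = 1,
                                        linear_space = FALSE) {
  stopifnot(n_sets >= 2)
  ng <- nrow(genes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(base_seed)
  u <- lhs::randomLHS(n_sets, ng)
  base_kdp <- genes$k_dp
  samples <- if (linear_space) {
    s <- stats::qnorm(u, mean = rep(base_kdp, each = n_sets), sd = sd_fold)
    pmax(s, 0.2 * matrix(base_kdp, n_sets, ng, byrow = TRUE))
  } else {
    z <- stats::qnorm(u, 0, log10(sd_fold) / 2)
    matrix(base_kdp, n_sets, ng, byrow = TRUE) * 10^z
  }
  colnames(samples) <- genes$gene_id

  cfg <- experiment_config("lhs_combo", egf_ngml = 20, ins_ugml = 10,
                           meki_um = 10, akti_um = 10, duration_h = 72,
                           n_cells = n_cells, base_seed = base_seed,
                           save_stride_min = 360)
  rows <- list(); discarded <- integer()
  for (s in seq_len(n_sets)) {
    g2 <- genes
    g2$k_dp <- samples[s, ]
    g2$t_half_protein <- log(2) / g2$k_dp
    g2$k_bp <- ifelse(g2$m_ss > 0, g2$k_dp * g2$p_ss / g2$m_ss, 0)
    model <- build_model(g2, params)
    init <- tryCatch(initialize_average_cell(model, probe = TRUE),
                     error = function(e) NULL)
    if (is.null(init) || !init$report$converged) {
      discarded <- c(discarded, s)
      next
    }
    pop <- spawn_population(init$model, init$cell, n_cells,
                            base_seed = base_seed)
    ex <- run_experiment(init$model, pop, cfg, keep_traj = FALSE)
    sm <- ex$summary
    rows[[length(rows) + 1]] <-
      data.frame(set = s, t24 = sm$percent_dead[sm$time_h == 24],
                 t48 = sm$percent_dead[sm$time_h == 48],
                 t72 = sm$percent_dead[sm$time_h == 72])
  }
  if (!length(rows)) stop("all LHS parameter sets failed initialization")
  death <- do.call(rbind, rows)
  summ <- vapply(c("t24", "t48", "t72"), function(cl)
    c(median = stats::median(death[[cl]]), iqr = stats::IQR(death[[cl]])), numeric(2))
  list(death = death, discarded = discarded, samples = samples,
       summary = summ)
}

#' Write a fate report as JSON / ROC points as CSV
#' @param report A `fate_report`.
#' @param json_path,roc_csv_path Output paths (either may be NULL).
#' @export
write_fate_report <- function(report, json_path = NULL, roc_csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- report[c("features", "train_n", "valid_n", "auc", "auc_rank")]
    out$svm_weights <- as.list(stats::setNames(as.numeric(report$svm_weights),
                                               report$features))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(roc_csv_path))
    utils::write.csv(report$roc, roc_csv_path, row.names = FALSE)
  invisible(report)
}
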