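# log2 counts-per-million with pseudocount 1; zero-library cells are the
# caller's responsibility
logcpm_matrix <- function(counts, lib = Matrix::colSums(counts)) {
  as.matrix(log2(sweep(as.matrix(counts), 2L, lib / 1e6, "/") + 1))
}

#' Per-gene summary metrics
#'
#' Mean and variance of log2 CPM across cells and the fraction of zero
#' raw counts, per gene.  Cells with zero library size carry no CPM and
#' are excluded with a warning.
#'
#' @param dataset A `SingleCellExperiment`.
#' @return `data.frame(gene_id, mean_logcpm, var_logcpm, frac_zero)`.
#' @export
gene_level_metrics <- function(dataset) {
  counts <- dataset_counts(dataset)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    warning(sum(lib == 0), " zero-library cell(s) excluded from metrics")
    counts <- counts[, lib > 0, drop = FALSE]
    lib <- lib[lib > 0]
  }
  lc <- logcpm_matrix(counts, lib)
  data.frame(gene_id = rownames(counts),
             mean_logcpm = rowMeans(lc),
             var_logcpm = matrixStats::rowVars(lc),
             frac_zero = Matrix::rowSums(counts == 0) / ncol(counts),
             row.names = NULL)
}

#' Per-cell summary metrics
#'
#' Fraction of zero counts and log (natural) library size per cell;
#' zero-library cells are excluded with a warning.
#'
#' @param dataset A `SingleCellExperiment`.
#' @return `data.frame(cell_id, frac_zero, log_lib)`.
#' @export
cell_level_metrics <- function(dataset) {
  counts <- dataset_counts(dataset)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    warning(sum(lib == 0), " zero-library cell(s) excluded from metrics")
    counts <- counts[, lib > 0, drop = FALSE]
    lib <- lib[lib > 0]
  }
  data.frame(cell_id = colnames(counts),
             frac_zero = Matrix::colSums(counts == 0) / nrow(counts),
             log_lib = log(lib),
             row.names = NULL)
}

#' Two-sample Kolmogorov-Smirnov statistic (univariate)
#'
#' Sup-norm distance between the two empirical CDFs.
#'
#' @param a,b Non-empty numeric vectors.
#' @return `D` in \[0, 1\].
#' @examples
#' ks_statistic_1d(c(1, 2, 3), c(1.5, 2.5, 3.5))  # 1/3
#' @export
ks_statistic_1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input")
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  max(abs(Fa - Fb))
}

#' Two-sample Kolmogorov-Smirnov statistic (bivariate)
#'
#' Quadrant-based two-sample statistic in the Fasano-Franceschini
#' style: at every observed point of either sample, and for each of
#' the four quadrant orientations anchored there, the absolute
#' difference between the two samples' quadrant fractions is computed;
#' the statistic is the maximum over all points and orientations.
#' Inputs larger than `max_points` rows are subsampled (deterministic
#' given the RNG state) to bound the quadratic cost.
#'
#' @param a,b Two-column numeric matrices (points in the plane).
#' @param max_points Per-sample cap before subsampling (default 2000).
#' @return `D` in \[0, 1\].
#' @export
ks_statistic_2d <- function(a, b, max_points = 2000L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("empty input")
  if (ncol(a) != 2L || ncol(b) != 2L) stop("inputs must be 2-column")
  if (nrow(a) > max_points) a <- a[sample.int(nrow(a), max_points), ]
  if (nrow(b) > max_points) b <- b[sample.int(nrow(b), max_points), ]
  pts <- rbind(a, b)
  d <- 0
  for (p in seq_len(nrow(pts))) {
    px <- pts[p, 1L]; py <- pts[p, 2L]
    ax <- a[, 1L] > px; ay <- a[, 2L] > py
    bx <- b[, 1L] > px; by <- b[, 2L] > py
    d <- max(d,
             abs(mean(ax & ay) - mean(bx & by)),
             abs(mean(!ax & ay) - mean(!bx & by)),
             abs(mean(ax & !ay) - mean(bx & !by)),
             abs(mean(!ax & !ay) - mean(!bx & !by)))
  }
  d
}

#' Silhouette widths of cells under a label grouping
#'
#' PCA on log2 CPM (top `n_pcs` components), Euclidean distances, and
#' the standard silhouette width of every cell against the given
#' grouping (sample or subject).  Near 1 means tight label clustering,
#' near 0 means full mixing.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param label `"sample"` or `"subject"`.
#' @param n_pcs Number of principal components (default 10).
#' @return List with `widths` (per cell) and `mean`.
#' @export
silhouette_by_label <- function(dataset, label = c("sample", "subject"),
                                n_pcs = 10L) {
  label <- match.arg(label)
  cd <- dataset_cells(dataset)
  grp <- factor(if (label == "sample") cd$sample_id else cd$subject_id)
  if (nlevels(grp) < 2L)
    stop("silhouette undefined with a single ", label, " label")
  lc <- logcpm_matrix(dataset_counts(dataset))
  n_pcs <- min(n_pcs, ncol(lc) - 1L, nrow(lc))
  pcs <- stats::prcomp(t(lc), center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  sil <- cluster::silhouette(as.integer(grp), stats::dist(pcs))
  widths <- sil[, "sil_width"]
  list(widths = widths, mean = mean(widths))
}

#' Subject- and sample-level intraclass correlation per gene
#'
#' Fits, gene by gene, a linear mixed model on log2 CPM with nested
#' random intercepts for subject and sample (REML via `lme4`), and
#' converts the variance components to intraclass correlations:
#' the subject ICC is the correlation of two cells from the same
#' subject at different timepoints, and the sample ICC the correlation
#' of two cells from the same sample (so it includes the subject
#' component and is never smaller).  Non-convergence falls back to a
#' method-of-moments decomposition, flagged in the output.
#'
#' @param dataset A `SingleCellExperiment` with >= 2 subjects and >= 2
#'   samples per subject.
#' @param genes_subset Optional gene ids (default: all genes).
#' @param values Optional pre-transformed genes x cells matrix to fit
#'   on instead of the dataset's log2 CPM (any variance-stabilized
#'   scale).
#' @return `data.frame(gene_id, icc_subject, icc_sample, method)`.
#' @export
variance_components_icc <- function(dataset, genes_subset = NULL,
                                    values = NULL) {
  cd <- dataset_cells(dataset)
  if (length(unique(cd$subject_id)) < 2L)
    stop("ICC needs at least 2 subjects")
  counts <- dataset_counts(dataset)
  if (!is.null(genes_subset)) {
    missing <- setdiff(genes_subset, rownames(counts))
    if (length(missing))
      stop("genes_subset contains unknown genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    counts <- counts[genes_subset, , drop = FALSE]
  }
  lc <- if (is.null(values)) logcpm_matrix(counts) else {
    stopifnot(ncol(values) == ncol(counts))
    if (!is.null(genes_subset)) values[genes_subset, , drop = FALSE]
    else values
  }
  if (is.null(rownames(lc))) rownames(lc) <- rownames(counts)
  subj <- factor(cd$subject_id)
  samp <- factor(cd$sample_id)
  subj_of_sample <- factor(tapply(as.character(subj), samp,
                                  function(s) s[1L])[levels(samp)])
  cbar <- mean(table(samp))
  nbar <- mean(table(subj_of_sample))
  fit_one <- function(yv) {
    res <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(yv ~ 1 + (1 | subj) + (1 | samp), REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4)))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      u <- vc$vcov[vc$grp == "subj"]
      v <- vc$vcov[vc$grp == "samp"]
      e <- vc$vcov[vc$grp == "Residual"]
      c(u, v, e, 0)
    }, error = function(err) NULL)
    if (is.null(res)) {
      # method-of-moments fallback on the nested means
      e <- mean(tapply(yv, samp, stats::var), na.rm = TRUE)
      if (!is.finite(e)) e <- 0
      sm <- tapply(yv, samp, mean)[levels(samp)]
      v_raw <- mean(tapply(sm, subj_of_sample, stats::var), na.rm = TRUE)
      v <- if (is.finite(v_raw)) max(v_raw - e / cbar, 0) else 0
      s_subj <- tapply(sm, subj_of_sample, mean)
      u <- max(stats::var(s_subj) - v / nbar - e / (nbar * cbar), 0)
      res <- c(u, v, e, 1)
    }
    res
  }
  comp <- t(apply(lc, 1L, fit_one))
  u <- pmax(comp[, 1L], 0); v <- pmax(comp[, 2L], 0)
  e <- pmax(comp[, 3L], 0)
  tot <- u + v + e
  tot[tot == 0] <- 1
  data.frame(gene_id = rownames(counts),
             icc_subject = u / tot,
             icc_sample = (u + v) / tot,
             method = ifelse(comp[, 4L] == 1, "moments", "reml"),
             row.names = NULL)
}

#' Compare an empirical and a simulated dataset
#'
#' Runs the full fidelity battery: univariate KS statistics for the
#' three gene-level metrics and two cell-level metrics, bivariate KS
#' for the three gene-metric pairs and the cell-metric pair, mean
#' silhouette widths at the sample and subject level for both
#' datasets, and (optionally) gene-wise subject/sample ICC
#' distributions with their own KS statistics.  Genes are paired by
#' shared ids; if the datasets share none, genes are matched by rank
#' of mean expression (closest-mean pairing) when
#' `config$match_genes = "mean"`.
#'
#' @param empirical,simulated `SingleCellExperiment` objects; the
#'   first is labelled the reference in the report.
#' @param config List of options: `n_pcs` (10), `do_silhouette`
#'   (TRUE), `do_icc` (TRUE), `icc_max_genes` (100, subsampled for
#'   speed), `match_genes` (`"id"` or `"mean"`), `icc_genes` (explicit
#'   ids overriding the default non-DE choice).
#' @return Object of class `fidelity_report`: `ks` long table plus the
#'   underlying metric tables.
#' @export
compare_datasets <- function(empirical, simulated, config = list()) {
  cfg <- utils::modifyList(
    list(n_pcs = 10L, do_silhouette = TRUE, do_icc = TRUE,
         icc_max_genes = 100L, match_genes = "id", icc_genes = NULL),
    config)
  ge <- gene_level_metrics(empirical)
  gs <- gene_level_metrics(simulated)
  shared <- intersect(ge$gene_id, gs$gene_id)
  if (!length(shared)) {
    if (!identical(cfg$match_genes, "mean"))
      stop("no overlapping gene ids; set config$match_genes = 'mean' ",
           "to pair genes by mean expression")
    ge <- ge[order(ge$mean_logcpm), ]
    gs <- gs[order(gs$mean_logcpm), ]
    k <- min(nrow(ge), nrow(gs))
    ge <- ge[seq_len(k), ]; gs <- gs[seq_len(k), ]
  } else {
    ge <- ge[match(shared, ge$gene_id), ]
    gs <- gs[match(shared, gs$gene_id), ]
  }
  ce <- cell_level_metrics(empirical)
  cs <- cell_level_metrics(simulated)

  ks <- data.frame(level = character(), metric = character(),
                   type = character(), statistic = numeric())
  add <- function(level, metric, type, stat)
    rbind(ks, data.frame(level = level, metric = metric, type = type,
                         statistic = stat))
  ks <- add("gene", "mean_logcpm", "univariate",
            ks_statistic_1d(ge$mean_logcpm, gs$mean_logcpm))
  ks <- add("gene", "var_logcpm", "univariate",
            ks_statistic_1d(ge$var_logcpm, gs$var_logcpm))
  ks <- add("gene", "frac_zero", "univariate",
            ks_statistic_1d(ge$frac_zero, gs$frac_zero))
  ks <- add("cell", "frac_zero", "univariate",
            ks_statistic_1d(ce$frac_zero, cs$frac_zero))
  ks <- add("cell", "log_lib", "univariate",
            ks_statistic_1d(ce$log_lib, cs$log_lib))
  ks <- add("gene", "frac_zero~mean_logcpm", "bivariate",
            ks_statistic_2d(cbind(ge$frac_zero, ge$mean_logcpm),
                            cbind(gs$frac_zero, gs$mean_logcpm)))
  ks <- add("gene", "frac_zero~var_logcpm", "bivariate",
            ks_statistic_2d(cbind(ge$frac_zero, ge$var_logcpm),
                            cbind(gs$frac_zero, gs$var_logcpm)))
  ks <- add("gene", "mean_logcpm~var_logcpm", "bivariate",
            ks_statistic_2d(cbind(ge$mean_logcpm, ge$var_logcpm),
                            cbind(gs$mean_logcpm, gs$var_logcpm)))
  ks <- add("cell", "frac_zero~log_lib", "bivariate",
            ks_statistic_2d(cbind(ce$frac_zero, ce$log_lib),
                            cbind(cs$frac_zero, cs$log_lib)))

  sil <- NULL
  if (cfg$do_silhouette) {
    sil <- list()
    for (lab in c("sample", "subject")) {
      se <- tryCatch(silhouette_by_label(empirical, lab, cfg$n_pcs),
                     error = function(e) NULL)
      ss <- tryCatch(silhouette_by_label(simulated, lab, cfg$n_pcs),
                     error = function(e) NULL)
      if (!is.null(se) && !is.null(ss)) {
        sil[[lab]] <- list(reference = se, simulated = ss)
        ks <- add(lab, "silhouette_width", "univariate",
                  ks_statistic_1d(se$widths, ss$widths))
      }
    }
  }

  icc <- NULL
  if (cfg$do_icc) {
    pick_genes <- function(ds, shared_ids) {
      ids <- shared_ids
      truth <- dataset_truth(ds)
      if (!is.null(truth) && any(truth$de_flag))
        ids <- intersect(ids, rownames(truth$log2fc)[!truth$de_flag])
      ids
    }
    ids <- if (!is.null(cfg$icc_genes)) cfg$icc_genes else {
      ids0 <- if (length(shared)) pick_genes(simulated, shared) else NULL
      if (!is.null(ids0) && length(ids0) > cfg$icc_max_genes)
        ids0 <- sample(ids0, cfg$icc_max_genes)
      ids0
    }
    if (!is.null(ids) && length(ids) >= 2L) {
      ie <- tryCatch(variance_components_icc(empirical, ids),
                     error = function(e) NULL)
      is_ <- tryCatch(variance_components_icc(simulated, ids),
                      error = function(e) NULL)
      if (!is.null(ie) && !is.null(is_)) {
        icc <- list(reference = ie, simulated = is_)
        ks <- add("subject", "icc", "univariate",
                  ks_statistic_1d(ie$icc_subject, is_$icc_subject))
        ks <- add("sample", "icc", "univariate",
                  ks_statistic_1d(ie$icc_sample, is_$icc_sample))
      }
    }
  }

  structure(list(ks = ks,
                 gene_metrics = list(reference = ge, simulated = gs),
                 cell_metrics = list(reference = ce, simulated = cs),
                 silhouette = sil, icc = icc,
                 reference = "empirical"),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("Fidelity report (reference =", x$reference, ")\n")
  print(x$ks, row.names = FALSE)
  invisible(x)
}

#' Write a fidelity report to disk
#'
#' @param report A `fidelity_report`.
#' @param out_dir Output directory.
#' @return Named vector of files written.
#' @export
write_fidelity_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  wt <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  manifest <- c(report = wt(report$ks, "report.tsv"),
                gene_ref = wt(report$gene_metrics$reference,
                              "gene_metrics_reference.tsv"),
                gene_sim = wt(report$gene_metrics$simulated,
                              "gene_metrics_simulated.tsv"),
                cell_ref = wt(report$cell_metrics$reference,
                              "cell_metrics_reference.tsv"),
                cell_sim = wt(report$cell_metrics$simulated,
                              "cell_metrics_simulated.tsv"))
  if (!is.null(report$icc)) {
    manifest <- c(manifest,
                  icc_ref = wt(report$icc$reference, "icc_reference.tsv"),
                  icc_sim = wt(report$icc$simulated, "icc_simulated.tsv"))
  }
  manifest
}
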