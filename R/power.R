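#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: sorted descending, `p * n / rank`
#' cummin-ed, capped at 1.  `NA` inputs are excluded from the ranking
#' and propagated as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (!n) return(out)
  o <- ok[order(p[ok], decreasing = TRUE)]
  out[o] <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  out
}

#' Remove genes dominated by zeros
#'
#' Drops genes whose fraction of zero counts is strictly greater than
#' `cutoff` (default 0.90), the usual pre-filter before single-cell DE
#' testing; the removed ids are kept so power denominators stay
#' defined.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param cutoff Zero-fraction threshold, strict inequality.
#' @return List: `dataset` (filtered), `removed` (gene ids dropped).
#' @export
filter_high_zero_genes <- function(dataset, cutoff = 0.90) {
  counts <- dataset_counts(dataset)
  zf <- Matrix::rowSums(counts == 0) / ncol(counts)
  drop <- zf > cutoff
  if (all(drop)) stop("all genes exceed the zero-fraction cutoff")
  out <- dataset[!drop, ]
  md <- S4Vectors::metadata(out)
  if (!is.null(md$truth_log2fc))
    S4Vectors::metadata(out)$truth_log2fc <-
      md$truth_log2fc[!drop, , drop = FALSE]
  list(dataset = out, removed = rownames(counts)[drop])
}

#' Paired pseudobulk differential-expression test
#'
#' Sums counts to one pseudobulk library per sample, computes log2
#' CPM, takes within-subject differences between the first and last
#' timepoint, and tests each gene's mean difference with a one-sample
#' t statistic.  By default the per-gene variances are moderated by
#' empirical-Bayes shrinkage toward their common prior
#' (`limma::squeezeVar`), adding prior degrees of freedom to the test.
#' This is a deliberately simple, well-calibrated sample-level test --
#' not a cell-level hurdle model.
#'
#' @param dataset A `SingleCellExperiment` with >= 2 subjects having
#'   both endpoint timepoints.
#' @param moderate Apply empirical-Bayes variance moderation (default
#'   TRUE).
#' @return `data.frame(gene_id, statistic, p_value)`; `NA` rows when a
#'   gene is untestable.
#' @export
pseudobulk_paired_test <- function(dataset, moderate = TRUE) {
  cd <- dataset_cells(dataset)
  counts <- dataset_counts(dataset)
  st <- sample_table(dataset)
  samp <- factor(cd$sample_id, levels = st$sample_id)
  Msum <- Matrix::sparseMatrix(i = seq_along(samp), j = as.integer(samp),
                               x = 1, dims = c(ncol(counts), nrow(st)))
  pb <- as.matrix(counts %*% Msum)
  colnames(pb) <- st$sample_id
  lib <- colSums(pb)
  lc <- log2(sweep(pb, 2L, lib / 1e6, "/") + 1)
  lev <- levels(cd$timepoint)
  first <- lev[1L]; last <- lev[length(lev)]
  subj <- unique(st$subject_id)
  pairs <- vapply(subj, function(s) {
    f <- st$sample_id[st$subject_id == s & st$timepoint == first]
    l <- st$sample_id[st$subject_id == s & st$timepoint == last]
    if (length(f) == 1L && length(l) == 1L) c(f, l) else c(NA, NA)
  }, character(2L))
  ok <- !is.na(pairs[1L, ])
  n <- sum(ok)
  gene_ids <- rownames(counts)
  if (n < 2L) {
    warning("fewer than 2 complete first/last pairs: no test possible")
    return(data.frame(gene_id = gene_ids, statistic = NA_real_,
                      p_value = NA_real_, row.names = NULL))
  }
  diffs <- lc[, pairs[2L, ok], drop = FALSE] -
    lc[, pairs[1L, ok], drop = FALSE]
  dbar <- rowMeans(diffs)
  s2 <- matrixStats::rowVars(diffs)
  df <- n - 1L
  if (moderate) {
    sq <- limma::squeezeVar(s2, df = df)
    s2_use <- sq$var.post
    df_tot <- df + sq$df.prior
  } else {
    s2_use <- s2
    df_tot <- df
  }
  tstat <- dbar / sqrt(s2_use / n)
  tstat[!is.finite(tstat)] <- sign(dbar[!is.finite(tstat)]) * 1e8
  tstat[is.na(tstat)] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = df_tot)
  data.frame(gene_id = gene_ids, statistic = tstat, p_value = p,
             row.names = NULL)
}

#' Define a design scenario
#'
#' @param name Scenario label.
#' @param n_subjects,n_timepoints Design sizes after down-sampling.
#' @param cells_mean Desired average cells per sample; actual counts
#'   are drawn uniformly within `cells_mean +/- cells_jitter`, clamped
#'   at 10.
#' @param cells_jitter Half-width of the cells-per-sample draw
#'   (default 100).
#' @return Object of class `power_scenario`.
#' @examples
#' scenario("baseline", 5, 2, 200)
#' @export
scenario <- function(name, n_subjects, n_timepoints, cells_mean,
                     cells_jitter = 100L) {
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 cells_mean = as.integer(cells_mean),
                 cells_jitter = as.integer(cells_jitter)),
            class = "power_scenario")
}

# draw per-sample cell targets for a scenario, clamped to >= 10 and to
# what the master dataset actually has
scenario_cell_targets <- function(sc, available) {
  lo <- sc$cells_mean - sc$cells_jitter
  hi <- sc$cells_mean + sc$cells_jitter
  tgt <- sample(seq(lo, hi), length(available), replace = TRUE)
  if (any(tgt < 10L)) {
    warning("cell target(s) below 10 clamped")
    tgt <- pmax(tgt, 10L)
  }
  if (any(tgt > available)) tgt <- pmin(tgt, available)
  tgt
}

# run one DE backend invocation; backend is "builtin_pseudobulk", a
# function(dataset) -> data.frame(gene_id, p_value), or a command string
# called as: cmd <counts_dir> <metadata.tsv> <contrast.json> <out.tsv>
run_de_backend <- function(dataset, de_backend) {
  if (is.function(de_backend)) return(de_backend(dataset))
  if (identical(de_backend, "builtin_pseudobulk")) {
    res <- pseudobulk_paired_test(dataset)
    return(res[, c("gene_id", "p_value")])
  }
  if (is.character(de_backend)) {
    # command backend: first element the executable, the rest fixed args
    dir <- tempfile("de_adapter_")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    write_simulated(dataset, file.path(dir, "data"), format = "mtx_dir")
    lev <- levels(dataset_cells(dataset)$timepoint)
    jsonlite::write_json(
      list(contrast = "first_vs_last", first = lev[1L],
           last = lev[length(lev)]),
      file.path(dir, "contrast.json"), auto_unbox = TRUE)
    out <- file.path(dir, "pvalues.tsv")
    status <- system2(de_backend[1L],
                      c(de_backend[-1L],
                        file.path(dir, "data"),
                        file.path(dir, "data", "cell_metadata.tsv"),
                        file.path(dir, "contrast.json"), out))
    if (status != 0L || !file.exists(out))
      stop("external DE adapter failed (exit ", status, ")")
    res <- utils::read.delim(out)
    if (!all(c("gene_id", "p_value") %in% names(res)))
      stop("adapter output must have columns gene_id, p_value")
    return(res)
  }
  stop("unknown DE backend")
}

# filter, test, and score one down-sampled dataset against its truth
score_dataset <- function(dataset, de_backend, alpha) {
  flt <- filter_high_zero_genes(dataset)
  ds <- flt$dataset
  truth <- dataset_truth(ds)
  if (is.null(truth)) stop("dataset carries no truth annotation")
  res <- run_de_backend(ds, de_backend)
  res <- res[match(rownames(ds), res$gene_id), ]
  tested <- is.finite(res$p_value)
  de <- truth$de_flag & tested
  null <- !truth$de_flag & tested
  adj <- bh_adjust(res$p_value)
  rej <- tested & !is.na(adj) & adj < alpha
  power <- if (sum(de)) sum(rej & de) / sum(de) else NA_real_
  fdr <- sum(rej & null) / max(1L, sum(rej))
  t1e <- if (sum(null)) sum(null & res$p_value < alpha) / sum(null)
         else NA_real_
  data.frame(power = power, fdr = fdr, t1e = t1e,
             n_tested = sum(tested), n_filtered = length(flt$removed))
}

#' Estimate power, FDR and type-I error for one scenario
#'
#' Repeatedly simulates a dataset at the scenario's design (cells per
#' sample drawn uniformly around the scenario mean), filters
#' high-zero genes, runs the DE backend, adjusts p-values by
#' Benjamini-Hochberg and scores against the simulation truth:
#' power over truth-DE genes surviving the filter (adjusted p <
#' `alpha`), FDR over rejections, and type-I error over truth-null
#' genes at unadjusted `alpha`.
#'
#' @param params A [sim_params()] with a non-null `de_spec` (otherwise
#'   power is `NA` and only T1E is informative).
#' @param sc A [scenario()].
#' @param de_backend `"builtin_pseudobulk"`, a function, or an adapter
#'   command (see [run_power_grid()]).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param replicates Number of replicate simulations (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @return `data.frame`, one row per replicate, class `power_result`.
#' @export
evaluate_scenario <- function(params, sc, de_backend = "builtin_pseudobulk",
                              seed = 1L, replicates = 10L, alpha = 0.05) {
  stopifnot(inherits(sc, "power_scenario"))
  rows <- lapply(seq_len(replicates), function(r) {
    p <- update_params(params,
                       n_subjects = sc$n_subjects,
                       n_timepoints = sc$n_timepoints,
                       timepoint_labels = paste0("t", seq_len(sc$n_timepoints)),
                       cells_per_sample = cells_uniform(
                         max(sc$cells_mean - sc$cells_jitter, 10L),
                         sc$cells_mean + sc$cells_jitter))
    ds <- simulate_dataset(p, seed = seed + r)
    cbind(scenario = sc$name, replicate = r,
          score_dataset(ds, de_backend, alpha))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_result", class(out))
  out
}

#' Run a power grid with a shared master simulation
#'
#' Replicates the simulate-then-down-sample design: per replicate, one
#' master dataset is simulated at the grid envelope (maximum subjects,
#' timepoints and cells over all scenarios), then each scenario is
#' carved out of the same master by down-sampling subjects, timepoints
#' and cells, so scenarios share truth labels and differ only in
#' design size.  Each carved dataset is filtered, tested and scored as
#' in [evaluate_scenario()].
#'
#' An optional `var_shift` adds the given amount (e.g. `+log(1.5)` or
#' `-log(1.5)`) to both the subject- and sample-level variance
#' log-means before simulating, reproducing low/high-variance
#' conditions.
#'
#' @param params Base [sim_params()] (its `de_spec` provides ground
#'   truth).
#' @param scenarios List of [scenario()] objects.
#' @param de_backend As in [evaluate_scenario()].
#' @param seed Base seed.
#' @param replicates Replicates per scenario (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @param var_shift Added to both variance log-means (default 0).
#' @return `data.frame` (class `power_result`): scenario x replicate
#'   rows with `power`, `fdr`, `t1e`, `n_tested`, `n_filtered`.
#' @examples
#' \dontrun{
#' grid <- list(scenario("baseline", 5, 2, 200),
#'              scenario("2x_subjects", 10, 2, 200),
#'              scenario("2x_timepoints", 5, 4, 200),
#'              scenario("2x_cells", 5, 2, 400))
#' res <- run_power_grid(p, grid, seed = 1)
#' }
#' @export
run_power_grid <- function(params, scenarios, de_backend = "builtin_pseudobulk",
                           seed = 1L, replicates = 10L, alpha = 0.05,
                           var_shift = 0) {
  stopifnot(all(vapply(scenarios, inherits, TRUE, "power_scenario")))
  m_max <- max(vapply(scenarios, `[[`, 1L, "n_subjects"))
  n_max <- max(vapply(scenarios, `[[`, 1L, "n_timepoints"))
  c_max <- max(vapply(scenarios, `[[`, 1L, "cells_mean"))
  jit <- max(vapply(scenarios, `[[`, 1L, "cells_jitter"))
  master_params <- update_params(
    params,
    n_subjects = m_max, n_timepoints = n_max,
    timepoint_labels = paste0("t", seq_len(n_max)),
    cells_per_sample = cells_uniform(max(c_max - jit, 10L), c_max + jit),
    subj_var_logmean = params$subj_var_logmean + var_shift,
    samp_var_logmean = params$samp_var_logmean + var_shift)
  rows <- list()
  for (r in seq_len(replicates)) {
    master_seed <- as.integer(seed) + r
    master <- simulate_dataset(master_params, seed = master_seed)
    for (s in seq_along(scenarios)) {
      sc <- scenarios[[s]]
      set.seed(master_seed + 7919L * s)  # matched master, scenario-specific cut
      ds <- master
      if (sc$n_subjects < m_max)
        ds <- downsample_dataset(ds, n_subjects = sc$n_subjects)
      if (sc$n_timepoints < n_max)
        ds <- downsample_dataset(ds, n_timepoints = sc$n_timepoints)
      avail <- sample_table(ds)$n_cells
      ds <- downsample_dataset(
        ds, cells_per_sample = scenario_cell_targets(sc, avail))
      rows[[length(rows) + 1L]] <-
        cbind(scenario = sc$name, replicate = r,
              score_dataset(ds, de_backend, alpha))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_result", class(out))
  out
}

#' @export
summary.power_result <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(object, object$scenario), function(d) {
    data.frame(scenario = d$scenario[1L],
               replicates = nrow(d),
               mean_power = mean(d$power, na.rm = TRUE),
               sd_power = stats::sd(d$power, na.rm = TRUE),
               mean_fdr = mean(d$fdr, na.rm = TRUE),
               mean_t1e = mean(d$t1e, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  agg
}

#' @export
print.power_result <- function(x, ...) {
  cat("Power/FDR/T1E results (", nrow(x), " scenario x replicate rows)\n",
      sep = "")
  print(summary(x), row.names = FALSE)
  invisible(x)
}
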