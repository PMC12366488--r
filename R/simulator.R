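#' Mean-one factors from a scaled symmetric Dirichlet
#'
#' Draws `w ~ Dirichlet(alpha, ..., alpha)` of dimension `k` and
#' returns `k * w`, a positive vector that sums to `k` (mean 1) whose
#' component variance equals the target `v`.  The concentration
#' follows from the symmetric-Dirichlet variance identity:
#' `alpha = (k - v - 1) / (k * v)`, valid for `0 < v < k - 1`.
#' `v` at or below the floor `1e-8` returns exact ones; `v >= k - 1`
#' is clamped to `(k - 1) * 0.999` with a warning.
#'
#' @param k Dimension (>= 1).
#' @param v Target component variance (>= 0).
#' @return Numeric vector of length `k`, strictly positive, sum `k`.
#' @examples
#' f <- scaled_dirichlet_factors(5, 0.5)
#' sum(f)  # exactly 5
#' @export
scaled_dirichlet_factors <- function(k, v) {
  drop(dirichlet_factor_matrix(k, v))
}

# Row-wise version: one scaled symmetric Dirichlet draw per entry of v.
# Returns length(v) x k matrix; rows sum to k exactly.
dirichlet_factor_matrix <- function(k, v) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("dimension k must be a positive integer")
  if (any(v < 0)) stop("target variance must be non-negative")
  G <- length(v)
  out <- matrix(1, G, k)
  if (k == 1L) return(out)     # degenerate Dirichlet: always 1
  hi <- v >= (k - 1)
  if (any(hi)) {
    warning(sum(hi), " variance value(s) at or above k - 1 clamped to ",
            "(k - 1) * 0.999")
    v[hi] <- (k - 1) * 0.999
  }
  live <- v > 1e-8
  if (any(live)) {
    alpha <- (k - v[live] - 1) / (k * v[live])
    g <- matrix(stats::rgamma(sum(live) * k, shape = alpha), ncol = k)
    tot <- rowSums(g)
    # alpha -> 0 limit: all draws underflow; the Dirichlet degenerates
    # to a uniformly random vertex (one factor k, the rest 0)
    dead <- tot == 0
    if (any(dead)) {
      g[dead, ] <- 0
      g[cbind(which(dead), sample.int(k, sum(dead), replace = TRUE))] <- 1
      tot[dead] <- 1
    }
    out[live, ] <- k * g / tot
  }
  out
}

#' Draw gene-by-sample mean expression under the nested hierarchy
#'
#' For every gene, a subject- and a sample-level factor variance is
#' drawn log-normal; mean-one multiplicative factors with those
#' variances are drawn from scaled symmetric Dirichlets (dimension =
#' number of subjects, resp. timepoints per subject); and the sample
#' mean is the product `mu_g * a_gi * b_gij`.
#'
#' @param params A [sim_params()] object.
#' @return List: `mu` (genes x samples, columns subject-major),
#'   `a` (genes x subjects), `b` (genes x samples), `v_a`, `v_b`
#'   (the gene-wise drawn variances), `samples` (sample annotation
#'   data.frame with `sample_id`, `subject_id`, `timepoint`).
#' @export
simulate_sample_means <- function(params) {
  validate_params(params)
  G <- params$n_genes; m <- params$n_subjects; n <- params$n_timepoints
  v_a <- stats::rlnorm(G, params$subj_var_logmean, params$subj_var_logsd)
  v_b <- stats::rlnorm(G, params$samp_var_logmean, params$samp_var_logsd)
  a <- dirichlet_factor_matrix(m, v_a)
  b <- matrix(NA_real_, G, m * n)
  for (i in seq_len(m))
    b[, (i - 1L) * n + seq_len(n)] <- dirichlet_factor_matrix(n, v_b)
  subj <- rep(paste0("subj", seq_len(m)), each = n)
  tp <- rep(params$timepoint_labels, m)
  samples <- data.frame(sample_id = paste0(subj, "_", tp),
                        subject_id = subj, timepoint = tp)
  mu <- params$gene_means * a[, rep(seq_len(m), each = n), drop = FALSE] * b
  colnames(mu) <- samples$sample_id
  list(mu = mu, a = a, b = b, v_a = v_a, v_b = v_b, samples = samples)
}

#' Draw per-cell true expression from the gamma layer
#'
#' Every cell's latent expression is gamma with `shape = 1 / phi_g`
#' and `scale = phi_g * mu_gij * z_g(t)`, where `z_g(t) = 2^log2fc` is
#' the fold change of the cell's timepoint relative to baseline
#' (mean `mu * z`, variance `phi * (mu * z)^2`).  Dispersions below
#' `1e-8` degenerate to the deterministic mean.
#'
#' @param mu Genes x samples matrix of sample means.
#' @param dispersions Per-gene `phi_g` (>= 0).
#' @param log2fc Genes x timepoints log2FC matrix (zeros for no DE).
#' @param cell_sample Integer index of each cell's sample (column of
#'   `mu`).
#' @param cell_timepoint Integer index of each cell's timepoint
#'   (column of `log2fc`).
#' @return Genes x cells matrix of non-negative latent expression.
#' @export
simulate_true_expression <- function(mu, dispersions, log2fc,
                                     cell_sample, cell_timepoint) {
  if (any(mu < 0) || any(dispersions < 0))
    stop("means and dispersions must be non-negative")
  G <- nrow(mu)
  n_cells <- length(cell_sample)
  z <- 2^log2fc
  mean_mat <- mu[, cell_sample, drop = FALSE] *
    z[, cell_timepoint, drop = FALSE]
  det <- dispersions < 1e-8
  x <- matrix(0, G, n_cells)
  if (any(!det)) {
    phi <- dispersions[!det]
    x[!det, ] <- matrix(
      stats::rgamma(sum(!det) * n_cells, shape = 1 / phi,
                    scale = phi * mean_mat[!det, , drop = FALSE]),
      ncol = n_cells)
  }
  if (any(det)) x[det, ] <- mean_mat[det, , drop = FALSE]
  x
}

#' Draw expected per-cell library sizes
#'
#' Samples get mean-one multiplicative shifts `d_ij` from a scaled
#' symmetric Dirichlet whose variance is implied by the concentration
#' parameter (`v = (k - 1) / (k * alpha + 1)`, `k` = number of
#' samples).  In parametric mode the log library size of each cell is
#' normal with location `d_ij * lib_logmean` and scale `lib_logsd`.
#' With a custom library-size pool, sizes are resampled with
#' replacement and shifted on the log scale by
#' `(d_ij - 1) * mean(log(pool))`, reproducing the parametric
#' location effect around the pool's own location.
#'
#' @param params A [sim_params()] object.
#' @param cell_sample Integer sample index per cell (subject-major,
#'   `1..m*n`).
#' @return List: `L` (expected library size per cell), `d` (per-sample
#'   shift factors, sums to `m*n`).
#' @export
draw_library_sizes <- function(params, cell_sample) {
  k <- params$n_subjects * params$n_timepoints
  alpha <- params$lib_concentration
  v_d <- (k - 1) / (k * alpha + 1)
  d <- scaled_dirichlet_factors(k, v_d)
  n_cells <- length(cell_sample)
  if (is.null(params$custom_lib_sizes)) {
    if (params$lib_logmean <= 0 && v_d > 1e-8)
      warning("lib_logmean <= 0: multiplicative sample shifts invert ",
              "their direction")
    L <- stats::rlnorm(n_cells, meanlog = d[cell_sample] * params$lib_logmean,
                       sdlog = params$lib_logsd)
  } else {
    pool <- params$custom_lib_sizes
    loc <- mean(log(pool))
    L <- exp(log(sample(pool, n_cells, replace = TRUE)) +
               (d[cell_sample] - 1) * loc)
  }
  list(L = L, d = d)
}

#' Poisson observation layer
#'
#' Rescales each cell's latent expression to its expected library size
#' (`x* = L * x / sum_g(x)`, so the per-cell latent total is exactly
#' `L`) and draws observed counts `y ~ Poisson(x*)`.
#'
#' @param x Genes x cells latent expression.
#' @param L Expected library size per cell.
#' @param return_expected Return the library-adjusted expectation `x*`
#'   itself instead of Poisson draws (no RNG touched).
#' @return Genes x cells integer count matrix (or the `x*` matrix).
#' @export
poisson_observe <- function(x, L, return_expected = FALSE) {
  tot <- colSums(x)
  zero <- tot <= 0 | L <= 0
  if (any(tot <= 0))
    warning(sum(tot <= 0), " all-zero latent cell(s): observed counts ",
            "set to zero")
  scale <- ifelse(zero, 0, L / tot)
  xstar <- sweep(x, 2L, scale, "*")
  if (return_expected) return(xstar)
  matrix(stats::rpois(length(xstar), xstar), nrow = nrow(x))
}

#' Simulate a paired/longitudinal single-cell dataset
#'
#' Runs the full generative hierarchy for the given parameters:
#' cells-per-sample resolution, DE assignment, gene-wise factor
#' variances and nested Dirichlet factors, library shifts and per-cell
#' expected library sizes, gamma latent expression (with fold changes
#' applied to the gamma scale), and the Poisson observation layer.
#' The draw order is fixed and documented, so a given seed yields
#' bit-identical output across runs.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (mandatory: no silent nondeterminism).
#' @param keep_intermediates Store sample means, factors, shifts and
#'   expected library sizes in `metadata()`?
#' @return A `SingleCellExperiment` with assay `counts`, colData
#'   `cell_id` / `subject_id` / `sample_id` / `timepoint`, rowData
#'   `de_flag`, and `metadata()` entries `truth_log2fc` (genes x
#'   timepoints), `params`, `seed`, and optionally `intermediates`.
#' @examples
#' p <- sim_params(n_genes = 50, n_subjects = 2, n_timepoints = 2,
#'                 cells_per_sample = 20)
#' sim <- simulate_dataset(p, seed = 1)
#' dim(sim)
#' @export
simulate_dataset <- function(params, seed, keep_intermediates = FALSE) {
  validate_params(params)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  G <- params$n_genes
  gene_ids <- names(params$gene_means)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(G))

  # draw order: (1) cells per sample, (2) DE assignment, (3) factor
  # variances + factors, (4) library shifts + sizes, (5) gamma, (6) Poisson
  cps <- resolve_cells_per_sample(params)
  de <- resolve_de_spec(params$de_spec, gene_ids, params$n_timepoints)
  sm <- simulate_sample_means(params)
  n_samp <- nrow(sm$samples)
  cell_sample <- rep(seq_len(n_samp), times = cps)
  tp_index <- match(sm$samples$timepoint, params$timepoint_labels)
  libs <- draw_library_sizes(params, cell_sample)
  x <- simulate_true_expression(sm$mu, params$dispersions, de$log2fc,
                                cell_sample, tp_index[cell_sample])
  y <- poisson_observe(x, libs$L)
  rownames(y) <- gene_ids

  cells <- data.frame(
    cell_id = paste0("cell", seq_len(sum(cps))),
    subject_id = sm$samples$subject_id[cell_sample],
    sample_id = sm$samples$sample_id[cell_sample],
    timepoint = sm$samples$timepoint[cell_sample])
  sce <- sc_dataset(y, cells, timepoint_levels = params$timepoint_labels)
  SummarizedExperiment::rowData(sce)$de_flag <- de$de_flag
  colnames(de$log2fc) <- params$timepoint_labels
  S4Vectors::metadata(sce)$truth_log2fc <- de$log2fc
  S4Vectors::metadata(sce)$params <- params
  S4Vectors::metadata(sce)$seed <- as.integer(seed)
  if (keep_intermediates)
    S4Vectors::metadata(sce)$intermediates <-
      list(sample_means = sm$mu, a = sm$a, b = sm$b,
           v_a = sm$v_a, v_b = sm$v_b,
           lib_shifts = libs$d, expected_lib = libs$L)
  sce
}

#' Down-sample subjects, timepoints or cells
#'
#' Reduces a simulated (or empirical) dataset to a target design:
#' subjects are a uniform random subset; timepoints keep the first and
#' last plus evenly spaced interior ones, preserving the full
#' first-to-last fold change; cells are a uniform random subset per
#' sample.  Truth annotation is re-sliced consistently.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param n_subjects,n_timepoints,cells_per_sample Targets; `NULL`
#'   leaves that axis untouched.  `cells_per_sample` may be a single
#'   count or one count per remaining sample (subject-major order).
#' @return The down-sampled `SingleCellExperiment`.
#' @export
downsample_dataset <- function(dataset, n_subjects = NULL,
                               n_timepoints = NULL,
                               cells_per_sample = NULL) {
  cd <- dataset_cells(dataset)
  md <- S4Vectors::metadata(dataset)
  if (!is.null(n_subjects)) {
    subj <- unique(cd$subject_id)
    if (n_subjects > length(subj))
      stop("requested ", n_subjects, " subjects but only ",
           length(subj), " available")
    keep <- sample(subj, n_subjects)
    dataset <- dataset[, cd$subject_id %in% keep]
    cd <- dataset_cells(dataset)
  }
  if (!is.null(n_timepoints)) {
    lev <- levels(cd$timepoint)
    if (n_timepoints > length(lev))
      stop("requested ", n_timepoints, " timepoints but only ",
           length(lev), " available")
    idx <- unique(round(seq(1L, length(lev), length.out = n_timepoints)))
    keep_tp <- lev[idx]
    dataset <- dataset[, cd$timepoint %in% keep_tp]
    SummarizedExperiment::colData(dataset)$timepoint <-
      factor(dataset_cells(dataset)$timepoint, levels = keep_tp)
    if (!is.null(md$truth_log2fc))
      S4Vectors::metadata(dataset)$truth_log2fc <-
        md$truth_log2fc[, idx, drop = FALSE]
    cd <- dataset_cells(dataset)
  }
  if (!is.null(cells_per_sample)) {
    st <- sample_table(dataset)
    tgt <- if (length(cells_per_sample) == 1L)
      rep(as.integer(cells_per_sample), nrow(st))
    else as.integer(cells_per_sample)
    if (length(tgt) != nrow(st))
      stop("cells_per_sample must be one count or one per sample")
    if (any(tgt > st$n_cells))
      stop("cell target exceeds available cells in sample(s): ",
           paste(st$sample_id[tgt > st$n_cells], collapse = ", "))
    keep <- unlist(lapply(seq_len(nrow(st)), function(s) {
      in_s <- which(cd$sample_id == st$sample_id[s])
      sample(in_s, tgt[s])
    }))
    dataset <- dataset[, sort(keep)]
  }
  dataset
}
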