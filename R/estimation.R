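#' Pooled-deconvolution size factors
#'
#' Per-cell scale factors for normalization, computed by summing cells
#' into overlapping ring pools, comparing each pooled profile to the
#' average pseudo-cell (median ratio across genes), and solving the
#' resulting linear system for the per-cell factors by least squares.
#' Pooling stabilises the median ratio in sparse data, the principle
#' behind deconvolution normalization.  With fewer than `min_cells`
#' cells the routine falls back to simple library-size factors.
#' Factors are rescaled to mean 1, so normalized expression is
#' `count / factor` on the scale of an average cell.
#'
#' @param counts Genes x cells count matrix.
#' @param min_cells Below this many cells use library-size factors
#'   (default 100).
#' @param pool_sizes Integer pool sizes (default `seq(21, 101, 20)`,
#'   capped at the cell count).
#' @return Positive numeric vector, one factor per cell, mean 1.
#' @examples
#' m <- matrix(rpois(200, 5), 10, 20)
#' f <- pooled_size_factors(m)
#' mean(f)
#' @export
pooled_size_factors <- function(counts, min_cells = 100L,
                                pool_sizes = seq(21L, 101L, by = 20L)) {
  n <- ncol(counts)
  if (n <= 1L) return(rep(1, max(n, 1L)))
  lib <- Matrix::colSums(counts)
  lib_fac <- lib / mean(lib)
  fix_degenerate <- function(f) {
    bad <- !is.finite(f) | f <= 0
    if (any(bad)) {
      warning(sum(bad), " cell(s) with degenerate factors; ",
              "replaced by the smallest positive factor")
      repl <- if (all(bad)) 1 else min(f[!bad])
      f[bad] <- repl
    }
    f / mean(f)
  }
  if (n < min_cells) return(fix_degenerate(lib_fac))

  keep <- Matrix::rowSums(counts) > 0
  m <- as.matrix(counts[keep, , drop = FALSE])
  # work on library-size-scaled profiles: the pooled median ratio then
  # estimates the (near-constant) residual factor sum, which is far less
  # noisy than raw-count ratios; library size is multiplied back below
  m <- sweep(m, 2L, lib / mean(lib), "/")
  u <- rowMeans(m)                       # reference pseudo-cell
  ring <- order(lib)                     # ring ordered by library size
  m <- m[, ring, drop = FALSE]
  sizes <- unique(pmin(pool_sizes, n))
  # sliding-window pooled sums via cumulative sums over the doubled ring
  cs <- cbind(0, matrixStats::rowCumsums(
    cbind(m, m[, seq_len(max(sizes) - 1L), drop = FALSE])))
  rows <- integer(0); cols <- integer(0); b <- numeric(0)
  eq <- 0L
  for (s in sizes) {
    pooled <- cs[, (1L + s):(n + s), drop = FALSE] -
      cs[, 1L:n, drop = FALSE]           # genes x n window sums
    ratio <- matrixStats::colMedians(pooled / u)
    idx <- outer(seq_len(s) - 1L, seq_len(n), "+") %% n + 1L  # s x n
    rows <- c(rows, rep(eq + seq_len(n), each = s))
    cols <- c(cols, as.integer(idx))
    b <- c(b, ratio)
    eq <- eq + n
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(eq, n))
  # low-weight anchor rows keep the system full rank without biasing
  w <- sqrt(1e-3)
  A2 <- rbind(A, w * Matrix::Diagonal(n))
  b2 <- c(b, w * rep(1, n))
  phi <- as.numeric(Matrix::solve(Matrix::crossprod(A2),
                                  Matrix::crossprod(A2, b2)))
  f <- numeric(n)
  f[ring] <- phi
  fix_degenerate(f * lib_fac)
}

#' Decompose sample means into nested multiplicative factors
#'
#' Computes, for each gene, normalized per-sample means, per-subject
#' means and the global mean (average over all samples), then the
#' subject factors `a_gi = subject mean / global mean` and sample
#' factors `b_gij = sample mean / subject mean`, together with the
#' within-sample variance of normalized expression needed for the
#' sampling-error correction.  The reconstruction
#' `global * a * b = sample mean` holds exactly for every retained
#' gene.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param size_factors Optional per-cell factors; computed with
#'   [pooled_size_factors()] when missing.
#' @return List of class `estimation_intermediates`: `sample_means`
#'   (G x N), `subject_means` (G x m), `global_means` (G),
#'   `a` (G x m), `b` (G x N), `s2_within` (G x N), `zero_frac` (G),
#'   `samples` (sample table), `size_factors`.
#' @export
estimate_mean_hierarchy <- function(dataset, size_factors = NULL) {
  counts <- dataset_counts(dataset)
  if (is.null(size_factors))
    size_factors <- pooled_size_factors(counts)
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per cell")
  st <- sample_table(dataset)
  if (any(st$n_cells == 0L)) stop("sample with zero cells")
  cd <- dataset_cells(dataset)
  x <- counts %*% Matrix::Diagonal(x = 1 / size_factors)  # normalized
  samp <- factor(cd$sample_id, levels = st$sample_id)
  Msum <- Matrix::sparseMatrix(i = seq_along(samp), j = as.integer(samp),
                               x = 1, dims = c(ncol(counts), nrow(st)))
  c_ij <- st$n_cells
  mu_gij <- as.matrix(x %*% Msum) %*% diag(1 / c_ij, nrow(st))
  colnames(mu_gij) <- st$sample_id
  ex2 <- as.matrix((x * x) %*% Msum) %*% diag(1 / c_ij, nrow(st))
  s2 <- sweep(pmax(ex2 - mu_gij^2, 0), 2L,
              ifelse(c_ij > 1L, c_ij / (c_ij - 1L), NA_real_), "*")
  subjects <- unique(st$subject_id)
  subj_of <- factor(st$subject_id, levels = subjects)
  Ssum <- matrix(0, nrow(st), length(subjects))
  Ssum[cbind(seq_len(nrow(st)), as.integer(subj_of))] <- 1
  mu_gi <- mu_gij %*% Ssum %*% diag(1 / colSums(Ssum), length(subjects))
  colnames(mu_gi) <- subjects
  mu_g <- rowMeans(mu_gij)
  a <- mu_gi / ifelse(mu_g > 0, mu_g, NA_real_)
  b <- mu_gij / ifelse(mu_gi[, as.integer(subj_of), drop = FALSE] > 0,
                       mu_gi[, as.integer(subj_of), drop = FALSE], NA_real_)
  structure(list(
    sample_means = mu_gij,
    subject_means = mu_gi,
    global_means = mu_g,
    a = a, b = b,
    s2_within = s2,
    cells_per_sample = c_ij,
    zero_frac = 1 - Matrix::rowSums(counts > 0) / ncol(counts),
    samples = st,
    size_factors = size_factors,
    gene_ids = rownames(counts)
  ), class = "estimation_intermediates")
}

#' Error-corrected variance of the nested factors
#'
#' Takes the raw across-subject variance of the subject factors and the
#' pooled across-sample variance of the sample factors, estimates the
#' contribution of finite-cell sampling error by the delta method
#' (`Var(sample mean) ~ s2_within / c`, propagated to the factor scale),
#' subtracts it, and floors at zero.  Genes whose zero-count fraction
#' is at or above `zero_frac_cutoff` are excluded as unstable.
#'
#' @param interm Output of [estimate_mean_hierarchy()].
#' @param zero_frac_cutoff Retain genes with zero fraction strictly
#'   below this value (default 0.60).
#' @return `data.frame` with `gene_id`, raw `v_a`, `v_b`, corrected
#'   `v_a_star`, `v_b_star` for retained genes; attribute
#'   `subject_level_ok` is `FALSE` when fewer than 2 subjects (or no
#'   subject with 2+ samples) make the subject level inestimable.
#' @export
variance_decomposition <- function(interm, zero_frac_cutoff = 0.60) {
  stopifnot(inherits(interm, "estimation_intermediates"))
  st <- interm$samples
  n_subj <- ncol(interm$a)
  samples_per_subject <- table(st$subject_id)
  paired <- sum(samples_per_subject >= 2L) >= 2L
  subject_ok <- n_subj >= 2L
  keep <- interm$zero_frac < zero_frac_cutoff & interm$global_means > 0
  a <- interm$a[keep, , drop = FALSE]
  mu_g <- interm$global_means[keep]
  mu_gi <- interm$subject_means[keep, , drop = FALSE]
  var_mu <- sweep(interm$s2_within[keep, , drop = FALSE], 2L,
                  interm$cells_per_sample, "/")
  var_mu[is.na(var_mu)] <- 0   # single-cell samples: no correction info
  subj_of <- factor(st$subject_id, levels = colnames(interm$a))
  if (paired) {
    b <- interm$b[keep, , drop = FALSE]
    # delta method: Var(b_gij) ~ Var(mu_hat_gij) / mu_gi^2
    err_b <- var_mu /
      pmax(mu_gi[, as.integer(subj_of), drop = FALSE], 1e-300)^2
  } else {
    # without repeated samples per subject the sample factors are taken
    # against the global mean (subject and sample levels are confounded)
    b <- interm$sample_means[keep, , drop = FALSE] / pmax(mu_g, 1e-300)
    err_b <- var_mu / pmax(mu_g, 1e-300)^2
  }
  v_b <- matrixStats::rowVars(b, na.rm = TRUE)
  v_b_star <- pmax(v_b - rowMeans(err_b, na.rm = TRUE), 0)
  subject_ok <- subject_ok && paired
  if (subject_ok) {
    v_a <- matrixStats::rowVars(a, na.rm = TRUE)
    # Var(a_gi) ~ (1/n_i^2) sum_j Var(mu_hat_gij) / mu_g^2
    n_i <- as.integer(samples_per_subject[colnames(interm$a)])
    Ssum <- matrix(0, nrow(st), n_subj)
    Ssum[cbind(seq_len(nrow(st)), as.integer(subj_of))] <- 1
    err_a_per_subj <- (var_mu %*% Ssum) %*% diag(1 / n_i^2, n_subj)
    err_a <- rowMeans(err_a_per_subj / pmax(mu_g, 1e-300)^2)
    v_a_star <- pmax(v_a - err_a, 0)
  } else {
    v_a <- v_a_star <- rep(NA_real_, sum(keep))
  }
  out <- data.frame(gene_id = interm$gene_ids[keep],
                    v_a = v_a, v_b = v_b,
                    v_a_star = v_a_star, v_b_star = v_b_star)
  attr(out, "subject_level_ok") <- subject_ok
  attr(out, "paired") <- paired
  out
}

#' Moment-match a log-normal to per-gene variances
#'
#' Given the across-gene mean `M` and variance `V` of positive
#' variances, returns the log-normal parameters with those moments:
#' `sigma^2 = log(1 + V / M^2)`, `mu = log(M) - sigma^2 / 2`.
#' Non-positive entries are dropped (their count reported via a
#' message) since the log-normal has positive support.
#'
#' @param v_star Numeric vector of per-gene (corrected) variances.
#' @return Named vector `c(logmean, logsd)`.
#' @examples
#' fit_lognormal_hyperparams(c(2, 2, 2))  # c(log(2), 0)
#' @export
fit_lognormal_hyperparams <- function(v_star) {
  v <- v_star[is.finite(v_star)]
  n_zero <- sum(v <= 0)
  v <- v[v > 0]
  if (length(v) < 2L)
    stop("no between-level variability detected; supply defaults")
  if (n_zero > 0)
    message(n_zero, " gene(s) with non-positive variance dropped ",
            "from the log-normal fit")
  M <- mean(v); V <- stats::var(v)
  sigma2 <- log(1 + V / M^2)
  c(logmean = log(M) - sigma2 / 2, logsd = sqrt(sigma2))
}

#' Gene-wise negative-binomial dispersions
#'
#' Estimates the NB dispersion of every gene on the single sample with
#' the most cells (ties broken by sample id order), treating cells as
#' libraries: Cox-Reid adjusted-profile-likelihood tagwise estimates
#' squeezed toward a fitted mean-dispersion trend by empirical Bayes,
#' as provided by `edgeR::estimateDisp`.  Genes detected in fewer than
#' `detect_frac` of the sample's cells carry too little information
#' for a tagwise estimate (and drag the fitted trend down); they are
#' excluded from the fit and assigned the common dispersion of the
#' detected genes instead.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param detect_frac Minimum fraction of cells with a nonzero count
#'   for a gene to enter the tagwise fit (default 0.05).
#' @return Non-negative numeric vector, one dispersion per gene.
#' @export
estimate_dispersions <- function(dataset, detect_frac = 0.05) {
  st <- sample_table(dataset)
  st <- st[order(-st$n_cells, st$sample_id), , drop = FALSE]
  chosen <- st$sample_id[1L]
  if (st$n_cells[1L] < 2L) stop("largest sample has fewer than 2 cells")
  sel <- dataset_cells(dataset)$sample_id == chosen
  m <- as.matrix(dataset_counts(dataset)[, sel, drop = FALSE])
  if (all(Matrix::rowSums(m) == 0))
    stop("all genes are zero in the chosen sample (", chosen, ")")
  detected <- rowMeans(m > 0) >= detect_frac
  if (sum(detected) < 2L) detected <- Matrix::rowSums(m) > 0
  y <- edgeR::DGEList(counts = m[detected, , drop = FALSE])
  y <- edgeR::estimateDisp(y)
  phi <- rep(max(y$common.dispersion, 0), nrow(m))
  phi[detected] <- pmax(y$tagwise.dispersion, 0)
  names(phi) <- rownames(m)
  phi
}

#' Library-size hyper-parameters
#'
#' Computes the per-sample mean and standard deviation of per-cell log
#' library sizes and averages each across samples, giving the location
#' `lib_logmean` and scale `lib_logsd` of the log-normal library model.
#' Sample-specific shifts are summarised by the ratios of per-sample
#' mean log library to the grand mean; their variance is converted to a
#' symmetric Dirichlet concentration via
#' `alpha = (N - v - 1) / (N * v)` with `N` the number of samples.
#'
#' @param dataset A `SingleCellExperiment`.
#' @return Named list `lib_logmean`, `lib_logsd`, `lib_concentration`,
#'   plus the per-sample `shift_ratios`.
#' @export
estimate_library_params <- function(dataset) {
  cd <- dataset_cells(dataset)
  lib <- Matrix::colSums(dataset_counts(dataset))
  ok <- lib > 0
  if (!all(ok)) {
    warning(sum(!ok), " zero-library cell(s) excluded from library ",
            "size estimation")
    cd <- cd[ok, , drop = FALSE]; lib <- lib[ok]
  }
  loglib <- log(lib)
  mu_s <- tapply(loglib, cd$sample_id, mean)
  sd_s <- tapply(loglib, cd$sample_id, stats::sd)
  sd_s[is.na(sd_s)] <- 0          # single-cell samples carry no spread
  lib_logmean <- mean(mu_s)
  lib_logsd <- mean(sd_s)
  N <- length(mu_s)
  if (N == 1L) {
    warning("single sample: library shift concentration set to 1e6 ",
            "(shifts ~ 1)")
    alpha <- 1e6
    r <- stats::setNames(1, names(mu_s))
  } else {
    r <- mu_s / lib_logmean
    v <- stats::var(as.numeric(r))
    alpha <- if (v < 1e-12) 1e6 else max((N - v - 1) / (N * v), 1e-8)
  }
  list(lib_logmean = unname(lib_logmean), lib_logsd = unname(lib_logsd),
       lib_concentration = unname(alpha), shift_ratios = r)
}

#' Estimate the full parameter set from empirical data
#'
#' Orchestrates size-factor normalization, mean-hierarchy
#' decomposition, error-corrected variance estimation with the
#' log-normal moment fit, trended NB dispersion estimation on the
#' largest sample, and library-size estimation.  When the data carry no
#' paired structure (no two subjects with two or more samples), the
#' subject-level hyper-parameters fall back to packaged defaults; with
#' a single sample the sample-level ones do too.  Provenance of every
#' block is recorded in the returned object.
#'
#' Design sizes default to the empirical ones: as many subjects and
#' timepoints as observed, and cells per sample drawn uniformly between
#' the 10th and 90th percentile of the empirical cells-per-sample
#' distribution.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param n_subjects,n_timepoints,cells_per_sample Optional design
#'   overrides.
#' @param zero_frac_cutoff Gene zero-fraction cutoff for the hierarchy
#'   fit (default 0.60).
#' @param size_factors Optional precomputed per-cell factors.
#' @return A validated [sim_params()] object.
#' @examples
#' \dontrun{p <- estimate_params(ds)}
#' @export
estimate_params <- function(dataset, n_subjects = NULL, n_timepoints = NULL,
                            cells_per_sample = NULL,
                            zero_frac_cutoff = 0.60, size_factors = NULL) {
  interm <- estimate_mean_hierarchy(dataset, size_factors)
  st <- interm$samples
  prov <- c(gene_means = "estimated", dispersions = "estimated",
            hierarchy = "estimated", library = "estimated")

  hier <- list(subj_var_logmean = unname(default_hierarchy_params["subj_var_logmean"]),
               subj_var_logsd = unname(default_hierarchy_params["subj_var_logsd"]),
               samp_var_logmean = unname(default_hierarchy_params["samp_var_logmean"]),
               samp_var_logsd = unname(default_hierarchy_params["samp_var_logsd"]))
  if (nrow(st) == 1L) {
    warning("single-sample data: subject- and sample-level variance ",
            "hyper-parameters set to packaged defaults")
    prov["hierarchy"] <- "default"
  } else {
    vd <- variance_decomposition(interm, zero_frac_cutoff)
    fit_b <- fit_lognormal_hyperparams(vd$v_b_star)
    hier$samp_var_logmean <- unname(fit_b["logmean"])
    hier$samp_var_logsd <- unname(fit_b["logsd"])
    if (isTRUE(attr(vd, "paired")) && isTRUE(attr(vd, "subject_level_ok"))) {
      fit_a <- fit_lognormal_hyperparams(vd$v_a_star)
      hier$subj_var_logmean <- unname(fit_a["logmean"])
      hier$subj_var_logsd <- unname(fit_a["logsd"])
    } else {
      warning("no paired/longitudinal structure: subject-level variance ",
              "hyper-parameters set to packaged defaults")
      prov["hierarchy"] <- "sample=estimated,subject=default"
    }
  }

  phi <- estimate_dispersions(dataset)
  libp <- estimate_library_params(dataset)

  mu_g <- interm$global_means
  mu_g[mu_g <= 0] <- 1e-8   # keep 1:1 gene alignment with the input

  if (is.null(n_subjects)) n_subjects <- ncol(interm$a)
  if (is.null(n_timepoints))
    n_timepoints <- length(levels(dataset_cells(dataset)$timepoint))
  if (is.null(cells_per_sample)) {
    q <- stats::quantile(st$n_cells, c(0.1, 0.9), type = 1L)
    cells_per_sample <- if (q[1L] == q[2L]) as.integer(q[1L]) else
      cells_uniform(q[1L], q[2L])
  }
  tp_labels <- levels(dataset_cells(dataset)$timepoint)
  if (length(tp_labels) != n_timepoints)
    tp_labels <- paste0("t", seq_len(n_timepoints))

  sim_params(
    n_genes = length(mu_g),
    n_subjects = n_subjects,
    n_timepoints = n_timepoints,
    cells_per_sample = cells_per_sample,
    gene_means = unname(mu_g),
    dispersions = unname(phi),
    subj_var_logmean = hier$subj_var_logmean,
    subj_var_logsd = hier$subj_var_logsd,
    samp_var_logmean = hier$samp_var_logmean,
    samp_var_logsd = hier$samp_var_logsd,
    lib_logmean = libp$lib_logmean,
    lib_logsd = libp$lib_logsd,
    lib_concentration = libp$lib_concentration,
    timepoint_labels = tp_labels,
    provenance = prov
  )
}
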