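# Fixture builders.  These deliberately avoid the package's own simulator
# where they serve as independent oracles (plain rnbinom/rpois draws).

make_cells_meta <- function(m, n, cells_per_sample) {
  subj <- rep(paste0("s", seq_len(m)), each = n)
  tp <- rep(paste0("t", seq_len(n)), m)
  samp <- paste0(subj, "_", tp)
  idx <- rep(seq_len(m * n), times = cells_per_sample)
  data.frame(cell_id = paste0("c", seq_along(idx)),
             subject_id = subj[idx],
             sample_id = samp[idx],
             timepoint = tp[idx])
}

# tiny deterministic dataset: 3 genes x 4 cells, 2 subjects x 2 timepoints
make_toy_dataset <- function() {
  counts <- matrix(c(1, 0, 2,
                     3, 1, 0,
                     0, 2, 4,
                     5, 0, 1), nrow = 3)
  rownames(counts) <- paste0("g", 1:3)
  cells <- make_cells_meta(2, 2, rep(1L, 4))
  suppressWarnings(sc_dataset(counts, cells,
                              timepoint_levels = c("t1", "t2")))
}

# independent NB generator (no Dirichlet machinery): per-cell library
# multiplier times gene mean, NB dispersion phi
make_nb_dataset <- function(n_genes = 200, m = 2, n = 2,
                            cells_per_sample = 50, mu = NULL, phi = 0.5,
                            lib_mult = NULL, seed = 42) {
  set.seed(seed)
  cells <- make_cells_meta(m, n, rep(cells_per_sample, m * n))
  n_cells <- nrow(cells)
  if (is.null(mu)) mu <- exp(rnorm(n_genes, 0, 1))
  if (is.null(lib_mult)) lib_mult <- runif(n_cells, 1, 4)
  lam <- outer(mu, lib_mult)
  counts <- if (phi > 0) {
    matrix(rnbinom(n_genes * n_cells, size = 1 / phi, mu = lam),
           n_genes, n_cells)
  } else {
    matrix(rpois(n_genes * n_cells, lam), n_genes, n_cells)
  }
  rownames(counts) <- paste0("g", seq_len(n_genes))
  ds <- suppressWarnings(sc_dataset(counts, cells,
                                    timepoint_levels = paste0("t", seq_len(n))))
  attr(ds, "true_lib_mult") <- lib_mult
  ds
}

# dataset with exact per-sample normalized means (constant within sample),
# for hand-checkable hierarchy arithmetic; one gene per row of `means`
make_mean_dataset <- function(means, cells_per_sample = 3L) {
  m <- nrow(means)   # genes
  n_samp <- ncol(means)
  stopifnot(n_samp %% 2 == 0)
  cells <- make_cells_meta(n_samp / 2, 2, rep(cells_per_sample, n_samp))
  counts <- means[, rep(seq_len(n_samp), each = cells_per_sample),
                  drop = FALSE]
  rownames(counts) <- paste0("g", seq_len(m))
  suppressWarnings(sc_dataset(counts, cells,
                              timepoint_levels = c("t1", "t2")))
}

quick_params <- function(n_genes = 60, m = 3, n = 2, c = 30,
                         lib_logmean = log(2000), lib_logsd = 0.2, ...) {
  set.seed(99)
  sim_params(n_genes = n_genes, n_subjects = m, n_timepoints = n,
             cells_per_sample = c,
             gene_means = exp(rnorm(n_genes, -1, 1)),
             dispersions = rep(0.4, n_genes),
             lib_logmean = lib_logmean, lib_logsd = lib_logsd, ...)
}
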