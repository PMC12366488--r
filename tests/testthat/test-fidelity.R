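# brute-force quadrant oracle for the bivariate KS statistic
ks2d_oracle <- function(a, b) {
  pts <- rbind(a, b)
  d <- 0
  for (p in seq_len(nrow(pts))) {
    for (sx in c(TRUE, FALSE)) for (sy in c(TRUE, FALSE)) {
      inq <- function(m) {
        qx <- if (sx) m[, 1] > pts[p, 1] else m[, 1] <= pts[p, 1]
        qy <- if (sy) m[, 2] > pts[p, 2] else m[, 2] <= pts[p, 2]
        mean(qx & qy)
      }
      d <- max(d, abs(inq(a) - inq(b)))
    }
  }
  d
}

test_that("gene-level metrics: hand arithmetic and invariances", {
  counts <- rbind(g1 = c(1, 0, 3, 0),
                  g2 = c(0, 2, 0, 4),
                  g3 = c(0, 0, 0, 0))
  cells <- make_cells_meta(1, 2, c(2L, 2L))
  ds <- sc_dataset(counts, cells, timepoint_levels = c("t1", "t2"))
  gm <- gene_level_metrics(ds)
  expect_equal(gm$frac_zero, c(0.5, 0.5, 1))
  expect_equal(gm$mean_logcpm[3], 0)   # all-zero gene -> (0, 0, 1)
  expect_equal(gm$var_logcpm[3], 0)
  # 1 gene, 2 cells, counts (1,3), libs (100,300): both logCPM equal
  counts2 <- rbind(a = c(1, 3), b = c(99, 297))
  cells2 <- make_cells_meta(1, 2, c(1L, 1L))
  ds2 <- sc_dataset(counts2, cells2, timepoint_levels = c("t1", "t2"))
  gm2 <- gene_level_metrics(ds2)
  expect_equal(gm2$var_logcpm[1], 0, tolerance = 1e-12)
  expect_equal(gm2$mean_logcpm[1], log2(1e6 / 100 + 1))
  # permutation invariance
  p <- quick_params(n_genes = 40, m = 2, n = 2, c = 15)
  sim <- simulate_dataset(p, seed = 21)
  perm <- sample(ncol(sim))
  expect_equal(gene_level_metrics(sim), gene_level_metrics(sim[, perm]))
})

test_that("cell-level metrics: arithmetic and the all-zero-gene effect", {
  counts <- matrix(c(0, 0, 5), 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  cells <- data.frame(cell_id = "c1", subject_id = "s1", sample_id = "s1_t1",
                      timepoint = "t1")
  ds <- sc_dataset(counts, cells, timepoint_levels = "t1")
  cm <- cell_level_metrics(ds)
  expect_equal(cm$frac_zero, 2 / 3)
  expect_equal(cm$log_lib, log(5))
  ds2 <- sc_dataset(rbind(counts, g4 = 0), cells, timepoint_levels = "t1")
  expect_equal(cell_level_metrics(ds2)$frac_zero, 3 / 4)
})

test_that("univariate KS: exact toy values and agreement with stats::ks.test", {
  expect_equal(ks_statistic_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic_1d(1:3, 10:12), 1)
  expect_equal(ks_statistic_1d(c(1, 2, 3), c(1.5, 2.5, 3.5)), 1 / 3)
  set.seed(22)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(25, mean = runif(1, -1, 1))
    expect_equal(ks_statistic_1d(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  }
  expect_error(ks_statistic_1d(numeric(0), 1), "empty")
})

test_that("bivariate KS equals the brute-force quadrant oracle", {
  a0 <- cbind(c(0, 1), c(0, 1))
  expect_equal(ks_statistic_2d(a0, a0), 0)
  far <- cbind(c(10, 11), c(10, 11))
  expect_equal(ks_statistic_2d(a0, far), 1)
  set.seed(23)
  for (i in 1:100) {
    a <- matrix(rnorm(20), 10, 2)
    b <- matrix(rnorm(20, sd = runif(1, 0.5, 2)), 10, 2)
    expect_equal(ks_statistic_2d(a, b), ks2d_oracle(a, b))
  }
})

test_that("silhouette widths separate clusters and vanish under random labels", {
  set.seed(24)
  # two far-separated blobs expressing disjoint gene sets
  G <- 30
  c1 <- rbind(matrix(rpois(15 * 40, 50), 15, 40),
              matrix(0L, 15, 40))
  c2 <- rbind(matrix(0L, 15, 40),
              matrix(rpois(15 * 40, 50), 15, 40))
  counts <- cbind(c1, c2)
  rownames(counts) <- paste0("g", 1:G)
  cells <- make_cells_meta(2, 1, c(40L, 40L))
  ds <- sc_dataset(counts, cells, timepoint_levels = "t1")
  sil <- silhouette_by_label(ds, "subject")
  expect_gt(sil$mean, 0.9)
  expect_true(all(sil$widths >= -1 & sil$widths <= 1))
  # random labels ~ zero mean width
  p <- quick_params(n_genes = 100, m = 2, n = 1, c = 500)
  sim <- simulate_dataset(update_params(p,
      subj_var_logmean = log(1e-12), samp_var_logmean = log(1e-12)),
    seed = 25)
  sil0 <- silhouette_by_label(sim, "subject")
  expect_lt(abs(sil0$mean), 0.05)
  one <- sc_dataset(counts[, 1:40],
                    make_cells_meta(1, 1, 40L), timepoint_levels = "t1")
  expect_error(silhouette_by_label(one, "subject"), "undefined")
})

test_that("ICC: null, recovery against truth, and nesting inequality", {
  # null: no subject/sample structure
  p0 <- update_params(quick_params(n_genes = 40, m = 4, n = 2, c = 25),
                      subj_var_logmean = log(1e-12), subj_var_logsd = 0,
                      samp_var_logmean = log(1e-12), samp_var_logsd = 0)
  sim0 <- simulate_dataset(p0, seed = 26)
  icc0 <- variance_components_icc(sim0)
  expect_lt(median(icc0$icc_subject), 0.02)
  expect_true(all(icc0$icc_sample >= icc0$icc_subject - 1e-12))
  # gaussian recovery oracle: u = 1, v = 0.5, e = 1 ->
  # ICC_subject = 0.4, ICC_sample = 0.6
  set.seed(27)
  m <- 10; n <- 2; c_ <- 50
  n_genes <- 120
  cells <- make_cells_meta(m, n, rep(c_, m * n))
  subj_idx <- as.integer(factor(cells$subject_id,
                                levels = unique(cells$subject_id)))
  samp_idx <- as.integer(factor(cells$sample_id,
                                levels = unique(cells$sample_id)))
  y <- t(vapply(seq_len(n_genes), function(g) {
    u <- rnorm(m, sd = 1)
    v <- rnorm(m * n, sd = sqrt(0.5))
    8 + u[subj_idx] + v[samp_idx] + rnorm(length(subj_idx), sd = 1)
  }, numeric(nrow(cells))))
  rownames(y) <- paste0("g", seq_len(n_genes))
  counts <- matrix(1L, n_genes, nrow(cells),
                   dimnames = list(rownames(y), cells$cell_id))
  ds <- sc_dataset(counts, cells, timepoint_levels = c("t1", "t2"))
  icc <- variance_components_icc(ds, values = y)
  expect_lt(abs(median(icc$icc_subject) - 0.4), 0.05)
  expect_lt(abs(median(icc$icc_sample) - 0.6), 0.05)
})

test_that("ICC rises with the injected hierarchy variance", {
  set.seed(1000)
  G <- 100
  base <- sim_params(n_genes = G, n_subjects = 8, n_timepoints = 2,
                     cells_per_sample = 60,
                     gene_means = exp(rnorm(G, 0, 1)),
                     dispersions = rep(0.3, G),
                     subj_var_logmean = log(0.02), subj_var_logsd = 0.3,
                     samp_var_logmean = log(0.02), samp_var_logsd = 0.3,
                     lib_logmean = log(4000), lib_logsd = 0.2,
                     lib_concentration = 1e6)
  hi_a <- update_params(base, subj_var_logmean = log(0.3))
  hi_b <- update_params(base, samp_var_logmean = log(0.3))
  icc_lo <- variance_components_icc(simulate_dataset(base, seed = 28))
  icc_a <- variance_components_icc(simulate_dataset(hi_a, seed = 28))
  icc_b <- variance_components_icc(simulate_dataset(hi_b, seed = 28))
  expect_gt(median(icc_b$icc_sample), median(icc_lo$icc_sample))
  expect_gt(median(icc_a$icc_subject), median(icc_lo$icc_subject))
})

test_that("compare_datasets: self-comparison is the zero report", {
  p <- quick_params(n_genes = 80, m = 3, n = 2, c = 30)
  sim <- simulate_dataset(p, seed = 29)
  set.seed(30)
  rep_ <- compare_datasets(sim, sim, config = list(icc_max_genes = 20L))
  expect_s3_class(rep_, "fidelity_report")
  expect_true(all(rep_$ks$statistic == 0))
  expect_equal(nrow(rep_$ks[rep_$ks$type == "univariate" &
                            rep_$ks$level %in% c("gene", "cell"), ]), 5L)
  expect_equal(nrow(rep_$ks[rep_$ks$type == "bivariate", ]), 4L)
  out <- withr::local_tempdir()
  files <- write_fidelity_report(rep_, out)
  expect_true(all(file.exists(files)))
  tab <- read.delim(files[["report"]])
  expect_named(tab, c("level", "metric", "type", "statistic"))
})

test_that("simulated-vs-estimated fidelity on the self-hosted fixture", {
  set.seed(31)
  G <- 600
  ref_p <- sim_params(n_genes = G, n_subjects = 5, n_timepoints = 2,
                      cells_per_sample = 120,
                      gene_means = exp(rnorm(G, -2, 1.5)),
                      dispersions = rexp(G, 2),
                      lib_logmean = log(4000), lib_logsd = 0.3)
  empirical <- simulate_dataset(ref_p, seed = 32)
  est <- estimate_params(empirical)
  sim <- simulate_dataset(est, seed = 33)
  set.seed(34)
  rep_ <- compare_datasets(empirical, sim,
                           config = list(do_icc = FALSE,
                                         do_silhouette = FALSE))
  gene_ks <- rep_$ks$statistic[rep_$ks$level == "gene" &
                               rep_$ks$type == "univariate"]
  expect_true(all(gene_ks < 0.15))
})
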