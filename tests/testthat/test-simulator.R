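test_that("scaled Dirichlet factors: degenerate cases and exact sums", {
  expect_equal(scaled_dirichlet_factors(1, 0.7), 1)
  expect_equal(scaled_dirichlet_factors(5, 0), rep(1, 5))
  set.seed(1)
  for (k in c(2, 5, 12)) {
    f <- scaled_dirichlet_factors(k, 0.3)
    expect_equal(sum(f), k, tolerance = 1e-12)
    expect_true(all(f > 0))
  }
  expect_warning(scaled_dirichlet_factors(3, 5), "clamped")
  expect_error(scaled_dirichlet_factors(0, 0.5), "positive integer")
  expect_error(scaled_dirichlet_factors(5, -1), "non-negative")
})

test_that("Dirichlet calibration: component variance matches the target", {
  set.seed(2)
  draws <- asNamespace("scNestSim")$dirichlet_factor_matrix(5, rep(0.5, 2e4))
  # population-style component variance (mean over draws x components)
  v_hat <- mean((draws - 1)^2)
  expect_equal(v_hat, 0.5, tolerance = 0.03)
})

test_that("sample means obey conservation and the no-hierarchy limit", {
  p <- quick_params(n_genes = 200, m = 4, n = 3, c = 10)
  set.seed(3)
  sm <- simulate_sample_means(p)
  expect_equal(rowSums(sm$a), rep(4, 200), tolerance = 1e-12)
  for (i in 1:4)
    expect_equal(rowSums(sm$b[, (i - 1) * 3 + 1:3]), rep(3, 200),
                 tolerance = 1e-12)
  # variance floor: all factors exactly 1, means collapse to mu_g
  p0 <- update_params(p, subj_var_logmean = log(1e-12), subj_var_logsd = 0,
                      samp_var_logmean = log(1e-12), samp_var_logsd = 0)
  sm0 <- simulate_sample_means(p0)
  expect_equal(sm0$mu, matrix(p$gene_means, 200, 12,
                              dimnames = dimnames(sm0$mu)))
  # mean drawn variance matches the log-normal mean
  set.seed(4)
  p1 <- update_params(quick_params(n_genes = 5000, m = 6, n = 2, c = 5),
                      subj_var_logmean = log(0.3), subj_var_logsd = 0.4)
  sm1 <- simulate_sample_means(p1)
  v_pop <- rowMeans((sm1$a - 1)^2)
  expect_equal(mean(v_pop), exp(log(0.3) + 0.4^2 / 2), tolerance = 0.05)
})

test_that("DE resolution: proportion, interpolation, pool, matrix, null", {
  set.seed(5)
  r <- resolve_de_spec(de_spec_proportion(0.2, 0.35), paste0("g", 1:10), 2)
  expect_equal(sum(r$de_flag), 2L)
  expect_setequal(r$log2fc[r$de_flag, 2], c(0.35, -0.35))
  expect_true(all(r$log2fc[, 1] == 0))
  expect_true(all(r$log2fc[!r$de_flag, ] == 0))
  # linear interpolation over 4 timepoints
  r4 <- resolve_de_spec(de_spec_proportion(0.5, 0.35), paste0("g", 1:4), 4)
  up <- which(r4$log2fc[, 4] > 0)[1]
  expect_equal(unname(r4$log2fc[up, ]), 0.35 * c(0, 1 / 3, 2 / 3, 1))
  # odd DE count: extra gene goes up
  r5 <- resolve_de_spec(de_spec_proportion(0.3, 1), paste0("g", 1:10), 2)
  expect_equal(sum(r5$log2fc[, 2] > 0), 2L)
  expect_equal(sum(r5$log2fc[, 2] < 0), 1L)
  # pool form samples only pool values
  rp <- resolve_de_spec(de_spec_pool(c(-1, 2), 0.5), paste0("g", 1:20), 2)
  expect_true(all(rp$log2fc[rp$de_flag, 2] %in% c(-1, 2)))
  # matrix form: pass-through and validation
  mat <- matrix(c(0, 1.5), 1, 2, dimnames = list("g3", NULL))
  rm_ <- resolve_de_spec(de_spec_matrix(mat), paste0("g", 1:5), 2)
  expect_equal(unname(rm_$log2fc["g3", 2]), 1.5)
  expect_equal(sum(rm_$de_flag), 1L)
  expect_error(resolve_de_spec(de_spec_matrix(
    matrix(c(0, 1), 1, 2, dimnames = list("nope", NULL))),
    paste0("g", 1:5), 2), "absent")
  # null spec
  r0 <- resolve_de_spec(NULL, paste0("g", 1:5), 3)
  expect_true(all(r0$log2fc == 0) && !any(r0$de_flag))
})

test_that("gamma layer has the right moments and degenerate limit", {
  set.seed(6)
  mu <- matrix(10, 1, 1)
  lfc <- matrix(0, 1, 1)
  x <- simulate_true_expression(mu, 0.4, lfc, rep(1L, 1e5), rep(1L, 1e5))
  expect_equal(mean(x), 10, tolerance = 0.01)
  expect_equal(var(as.numeric(x)), 0.4 * 100, tolerance = 0.05)
  # fold change scales the mean
  xz <- simulate_true_expression(mu, 0.4, matrix(1, 1, 1),
                                 rep(1L, 2e4), rep(1L, 2e4))
  expect_equal(mean(xz), 20, tolerance = 0.05)
  # phi -> 0 gives the deterministic mean
  x0 <- simulate_true_expression(mu, 0, lfc, rep(1L, 5), rep(1L, 5))
  expect_equal(as.numeric(x0), rep(10, 5))
  expect_error(simulate_true_expression(mu, -0.1, lfc, 1L, 1L),
               "non-negative")
})

test_that("library sizes: shifts sum exactly, log-normal moments recover", {
  p <- quick_params(n_genes = 10, m = 3, n = 2, c = 5,
                    lib_logmean = 9, lib_logsd = 0.3)
  set.seed(7)
  dl <- draw_library_sizes(p, rep(1:6, each = 5))
  expect_equal(sum(dl$d), 6, tolerance = 1e-12)
  # sigma_L = 0, huge concentration -> all L = exp(mu_L)
  p0 <- update_params(p, lib_logsd = 0, lib_concentration = 1e12)
  dl0 <- draw_library_sizes(p0, rep(1:6, each = 2))
  expect_equal(dl0$L, rep(exp(9), 12))
  # Monte-Carlo recovery of (9, 0.3)
  p1 <- update_params(quick_params(n_genes = 2, m = 1, n = 1, c = 5),
                      lib_logmean = 9, lib_logsd = 0.3,
                      lib_concentration = 1e12)
  set.seed(8)
  dl1 <- draw_library_sizes(p1, rep(1L, 1e5))
  expect_equal(mean(log(dl1$L)), 9, tolerance = 0.005 * 9)
  expect_equal(sd(log(dl1$L)), 0.3, tolerance = 0.03 * 0.3)
  # custom pool: values resampled from the pool, location shift applied
  pool <- c(1000, 2000, 4000)
  p2 <- update_params(p, custom_lib_sizes = pool, lib_concentration = 1e12)
  set.seed(9)
  dl2 <- draw_library_sizes(p2, rep(1:6, each = 10))
  expect_true(all(round(dl2$L) %in% pool))
})

test_that("Poisson observation conserves the library in expectation", {
  set.seed(10)
  x <- matrix(rgamma(50 * 1e4, 2, 1), 50)
  L <- rep(5000, 1e4)
  y <- poisson_observe(x, L)
  expect_equal(mean(colSums(y)), 5000, tolerance = 0.01)
  # single nonzero gene takes the whole library
  x1 <- matrix(c(0, 0, 3), 3, 1)
  y1 <- poisson_observe(x1, 100)
  expect_equal(y1[1:2, 1], c(0, 0))
  expect_gt(y1[3, 1], 0)
  # L = 0 -> all-zero cell
  expect_equal(as.numeric(poisson_observe(x1, 0)), c(0, 0, 0))
  expect_warning(poisson_observe(matrix(0, 2, 1), 10), "all-zero")
})

test_that("simulate_dataset is deterministic and has the declared shape", {
  p <- quick_params(n_genes = 100, m = 5, n = 2, c = 200)
  s1 <- simulate_dataset(p, seed = 11)
  s2 <- simulate_dataset(p, seed = 11)
  expect_identical(as.matrix(SummarizedExperiment::assay(s1)),
                   as.matrix(SummarizedExperiment::assay(s2)))
  cd <- as.data.frame(SummarizedExperiment::colData(s1))
  expect_equal(length(unique(cd$sample_id)), 10L)
  expect_equal(ncol(s1), 2000L)
  expect_equal(nrow(s1), 100L)
  s3 <- simulate_dataset(p, seed = 12)
  expect_false(identical(as.matrix(SummarizedExperiment::assay(s1)),
                         as.matrix(SummarizedExperiment::assay(s3))))
  expect_error(simulate_dataset(p), "seed")
})

test_that("null simulation shows no systematic timepoint shift", {
  # library shifts are held off (huge concentration): a single draw of
  # 12 sample shifts would otherwise dominate the Monte-Carlo error
  p <- quick_params(n_genes = 2000, m = 6, n = 2, c = 150,
                    lib_concentration = 1e9)
  sim <- simulate_dataset(p, seed = 13)
  counts <- as.matrix(SummarizedExperiment::assay(sim))
  cd <- as.data.frame(SummarizedExperiment::colData(sim))
  lc <- log2(sweep(counts, 2, colSums(counts) / 1e6, "/") + 1)
  d <- rowMeans(lc[, cd$timepoint == "t2"]) -
    rowMeans(lc[, cd$timepoint == "t1"])
  expect_lt(abs(mean(d)), 0.05)
})

test_that("fold-change injection is recovered at pseudobulk level", {
  set.seed(14)
  G <- 500
  p <- sim_params(n_genes = G, n_subjects = 6, n_timepoints = 2,
                  cells_per_sample = 300,
                  gene_means = exp(rnorm(G, 0, 1)),
                  dispersions = rep(0.3, G),
                  lib_logmean = log(5000), lib_logsd = 0.2,
                  de_spec = de_spec_proportion(0.1, 1.0))
  sim <- simulate_dataset(p, seed = 15)
  counts <- as.matrix(SummarizedExperiment::assay(sim))
  cd <- as.data.frame(SummarizedExperiment::colData(sim))
  truth <- S4Vectors::metadata(sim)$truth_log2fc
  cpm <- sweep(counts, 2, colSums(counts) / 1e6, "/")
  m1 <- rowMeans(cpm[, cd$timepoint == "t1"])
  m2 <- rowMeans(cpm[, cd$timepoint == "t2"])
  up <- truth[, 2] > 0
  down <- truth[, 2] < 0
  expect_equal(median(m2[up] / m1[up]), 2, tolerance = 0.1)
  expect_equal(median(m2[down] / m1[down]), 0.5, tolerance = 0.1)
})

test_that("down-sampling subjects, timepoints and cells", {
  p <- quick_params(n_genes = 50, m = 10, n = 4, c = 30)
  p <- update_params(p, timepoint_labels = paste0("t", 1:4),
                     de_spec = de_spec_proportion(0.2, 0.5))
  sim <- simulate_dataset(p, seed = 16)
  set.seed(17)
  d1 <- downsample_dataset(sim, n_subjects = 5)
  cd1 <- as.data.frame(SummarizedExperiment::colData(d1))
  expect_equal(length(unique(cd1$subject_id)), 5L)
  expect_equal(length(unique(cd1$sample_id)), 20L)  # samples intact
  # 4 -> 2 timepoints keeps the endpoints, truth re-sliced
  d2 <- downsample_dataset(sim, n_timepoints = 2)
  cd2 <- as.data.frame(SummarizedExperiment::colData(d2))
  expect_equal(levels(cd2$timepoint), c("t1", "t4"))
  tr2 <- S4Vectors::metadata(d2)$truth_log2fc
  tr <- S4Vectors::metadata(sim)$truth_log2fc
  expect_equal(tr2, tr[, c(1, 4)])
  # exact per-sample cell counts
  d3 <- downsample_dataset(sim, cells_per_sample = 20)
  cd3 <- as.data.frame(SummarizedExperiment::colData(d3))
  expect_true(all(table(cd3$sample_id) == 20))
  expect_error(downsample_dataset(sim, n_subjects = 99), "available")
  expect_error(downsample_dataset(sim, cells_per_sample = 1e5), "exceeds")
})
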