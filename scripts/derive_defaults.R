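#!/usr/bin/env Rscript
# Derives the packaged fallback hierarchy hyper-parameters
# (default_hierarchy_params in R/params.R) by simulating a synthetic
# reference dataset with moderate nested variability and re-estimating
# the hierarchy from it.  The reference world: 2000 genes with
# log-normal means, NB dispersion 0.4, 10 subjects x 2 timepoints x
# 200 cells, subject-level factor variance ~ LNorm(log 0.05, 0.8^2),
# sample-level ~ LNorm(log 0.02, 0.6^2) — i.e. subject effects a bit
# stronger than sample effects, both small relative to biological
# gene-level spread, as typically seen in sorted cell types.
# Run from the repo root:  Rscript scripts/derive_defaults.R

library(scNestSim)

set.seed(20260909)
G <- 2000
p <- sim_params(
  n_genes = G, n_subjects = 10, n_timepoints = 2, cells_per_sample = 200,
  gene_means = exp(rnorm(G, -3, 1.8)),
  dispersions = rep(0.4, G),
  subj_var_logmean = log(0.05), subj_var_logsd = 0.8,
  samp_var_logmean = log(0.02), samp_var_logsd = 0.6,
  lib_logmean = log(6000), lib_logsd = 0.4, lib_concentration = 300)

# note: the simulation seed must differ from the seed used to draw the
# gene means above, otherwise the simulator's per-gene variance draws
# reuse the same normal stream and correlate with the means
ref <- simulate_dataset(p, seed = 4711)
est <- estimate_params(ref)

cat(sprintf(paste0(
  "default_hierarchy_params <- c(\n",
  "  subj_var_logmean = %.2f,\n  subj_var_logsd   = %.2f,\n",
  "  samp_var_logmean = %.2f,\n  samp_var_logsd   = %.2f\n)\n"),
  est$subj_var_logmean, est$subj_var_logsd,
  est$samp_var_logmean, est$samp_var_logsd))
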