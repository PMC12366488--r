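# scNestSim

Simulation of **paired and longitudinal single-cell RNA-seq data** with
nested subject → sample → cell variability, parameter estimation from
empirical count matrices, a simulation-fidelity battery, and a
power / FDR / type-I-error engine for study design.

## Who this is for

Paired and longitudinal scRNA-seq designs — the same subjects sequenced
at several timepoints — induce a correlation hierarchy that single-sample
simulators ignore: cells from one sample resemble each other (shared
dissociation, batch, sequencing run), and samples from one subject
resemble each other across timepoints (shared biology). Anyone planning
such a study (how many subjects? timepoints? cells per sample?) or
benchmarking longitudinal differential-expression methods needs
synthetic data that reproduces both levels of that hierarchy with known
ground truth. That is what this package generates.

## The model

For gene *g*, subject *i*, sample (timepoint) *j*, cell *k*:

```
mu_gij   = mu_g * a_gi * b_gij                    sample-specific mean
a_g      = m * Dir(alpha_ag),  b_gi = n * Dir(alpha_bg)   mean-one factors
v_ag     ~ LogNormal(mu_a, sigma_a^2)             gene-wise factor variances
v_bg     ~ LogNormal(mu_b, sigma_b^2)
alpha    = (k - v - 1) / (k v)                    variance -> concentration
x_gijk   ~ Gamma(shape = 1/phi_g, scale = phi_g * mu_gij * z_g(t))
L_ijk    ~ LogNormal(d_ij * mu_L, sigma_L),  d = (m n) * Dir(alpha_d)
x*_gijk  = L_ijk * x_gijk / sum_g x_gijk          library adjustment
y_gijk   ~ Poisson(x*_gijk)                       observed count
```

Scaled symmetric Dirichlet draws give multiplicative factors with mean
exactly 1 and a controlled variance, so subject and sample effects
perturb — but never systematically shift — gene means. Differential
expression enters as fold changes `z_g(t) = 2^log2FC` on the gamma
scale, linearly interpolated across timepoints. Every hyper-parameter
(`mu_g`, `phi_g`, `mu_a`, `sigma_a`, `mu_b`, `sigma_b`, `mu_L`,
`sigma_L`, `alpha_d`) is estimable from a single empirical count matrix
via `estimate_params()`.

## Worked example

```r
library(scNestSim)
set.seed(42)
G <- 500
p <- sim_params(n_genes = G, n_subjects = 5, n_timepoints = 2,
                cells_per_sample = cells_uniform(150, 250),
                gene_means = exp(rnorm(G, -2, 1.5)),
                dispersions = rexp(G, 2),
                lib_logmean = log(4000), lib_logsd = 0.3,
                de_spec = de_spec_proportion(0.2, 0.35))
sim <- simulate_dataset(p, seed = 42)
sim
#> class: SingleCellExperiment
#> dim: 500 2042
#> metadata(3): truth_log2fc params seed
#> assays(1): counts
#> colData names(4): cell_id subject_id sample_id timepoint
```

2042 cells across 10 samples (5 subjects × 2 timepoints, 150–250 cells
each); `metadata(sim)$truth_log2fc` holds the injected per-gene log2
fold-change trajectories (20% of genes at ±0.35), `rowData(sim)$de_flag`
the DE ground truth.

Estimation closes the loop — re-estimating parameters from the
simulation and simulating again yields a dataset whose gene- and
cell-level distributions match the original (two-sample KS statistics,
univariate and bivariate):

```r
est <- estimate_params(sim)
rep <- compare_datasets(sim, simulate_dataset(est, seed = 43),
                        config = list(do_icc = FALSE, do_silhouette = FALSE))
rep
#>  level                 metric       type  statistic
#>   gene            mean_logcpm univariate 0.01800000
#>   gene             var_logcpm univariate 0.03800000
#>   gene              frac_zero univariate 0.02000000
#>   cell              frac_zero univariate 0.02594813
#>   cell                log_lib univariate 0.02192696
#>   gene  frac_zero~mean_logcpm  bivariate 0.02400000
#>   ...
```

Power analysis with the simulate-then-down-sample design (one master
simulation per replicate, carved into each scenario so truth labels are
shared):

```r
grid <- list(scenario("baseline",    5, 2, 150, cells_jitter = 50),
             scenario("2x_subjects", 10, 2, 150, cells_jitter = 50))
res <- run_power_grid(update_params(p, n_subjects = 10), grid,
                      seed = 1, replicates = 3)
res
#>     scenario replicates mean_power   sd_power   mean_fdr   mean_t1e
#>  2x_subjects          3  0.1578114 0.03870893 0.04166667 0.05573047
#>     baseline          3  0.0000000 0.00000000 0.33333333 0.04641796
```

Doubling subjects raises the power of the built-in paired pseudobulk
moderated-t backend from ~0 to ~0.16 at this small effect size; type-I
error stays near the nominal 0.05. (The FDR estimate at zero/near-zero
rejections is dominated by single false positives.) A cell-level
mixed-model backend can be plugged in through the external adapter
contract (see `?run_power_grid`).

## Command line

```sh
Rscript -e 'quit(status = scNestSim::run_cli())' estimate \
    --matrix matrix.mtx --genes genes.tsv --metadata meta.tsv --out params_dir/
Rscript -e 'quit(status = scNestSim::run_cli())' simulate \
    --params params_dir/params.json --seed 7 --out sim_dir/
Rscript -e 'quit(status = scNestSim::run_cli())' assess \
    --a empirical_dir/ --b sim_dir/ --out report_dir/
Rscript -e 'quit(status = scNestSim::run_cli())' power \
    --params params_dir/params.json --grid grid.json --seed 1 --out pow_dir/
```

Every output directory receives a `provenance.json` sufficient to re-run
the command bit-identically.

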