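---
title: "scNestSim: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scNestSim: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scNestSim)
```

# The generative model

scNestSim simulates a genes × cells count matrix for a design with `m`
subjects, `n` samples (timepoints) per subject and on average `c` cells
per sample, for a single cell type. The hierarchy has three layers.

**Sample means.** Every gene has a global mean `mu_g`. The mean in
subject `i`, sample `j` is `mu_gij = mu_g * a_gi * b_gij`, where the
subject factors `a_g = (a_g1, ..., a_gm)` and per-subject sample factors
`b_gi = (b_gi1, ..., b_gin)` are symmetric Dirichlet draws scaled by
their dimension. Scaling forces `sum_i a_gi = m` and `sum_j b_gij = n`
exactly, so the factors have mean one and perturb rather than shift the
gene's expression; the concentration `alpha = (k - v - 1) / (k v)` is
the unique value for which the dimension-scaled component variance
equals a target `v` (valid for `0 < v < k - 1`). The targets `v_ag`,
`v_bg` are themselves drawn per gene from log-normals with
hyper-parameters `(mu_a, sigma_a)` and `(mu_b, sigma_b)` — these four
numbers control how strongly cells cluster by subject and by sample.

**True expression.** Each cell's latent expression is
`x ~ Gamma(shape = 1/phi_g, scale = phi_g * mu_gij * z_g(t))`, i.e.
mean `mu * z` and variance `phi * (mu z)^2`. `z_g(t) = 2^log2FC` injects
differential expression on the gamma scale; `phi_g = 0` degenerates to
the deterministic mean.

**Observation.** Expected library sizes are
`L ~ LogNormal(d_ij * mu_L, sigma_L)` with per-sample mean-one shifts
`d` from a scaled symmetric Dirichlet of dimension `m*n` (concentration
`alpha_d`; large values switch shifts off). Latent expression is
rescaled so each cell's latent total is exactly `L`
(`x* = L x / sum_g x`), and observed counts are `y ~ Poisson(x*)`.
Marginally within a sample this yields gamma-Poisson (negative-binomial
like) counts with overdispersion `phi_g`.

**Assumptions worth knowing.** Genes are conditionally independent
(factors and gamma draws are independent across genes); there is one
sample per subject per timepoint; fold changes act multiplicatively and
interpolate linearly over timepoints; library sizes are log-normal
unless an empirical pool is supplied.

# Key parameters

| parameter | meaning | unit/scale | default | why |
|---|---|---|---|---|
| `mu_a`, `sigma_a` | log-mean/sd of subject-factor variance `v_ag` | natural log of a variance | −3.04 / 0.95 | package-derived, see below |
| `mu_b`, `sigma_b` | same, sample level | natural log | −4.06 / 0.76 | package-derived |
| `mu_L`, `sigma_L` | mean/sd of per-cell log library size | natural log counts | log(5000) / 0.35 | typical 10x library |
| `alpha_d` | library-shift concentration | unitless, >0 | 500 | mild sample shifts (shift variance `(k−1)/(k·alpha+1)`) |
| `phi_g` | gene dispersion | unitless | 0.4 | mid-range UMI overdispersion |
| `cells_per_sample` | fixed, uniform range, or explicit | cells | 100 | desk-scale default |

The shipped hierarchy defaults are **not** estimated from any published
dataset: `scripts/derive_defaults.R` simulates a synthetic reference
(2000 genes, 10 subjects × 2 timepoints × 200 cells, subject-factor
variance ~ LNorm(log 0.05, 0.8²), sample level LNorm(log 0.02, 0.6²) —
subject effects somewhat stronger than sample effects, both small
against gene-level spread, as is typical for a sorted cell type) and
re-estimates the hierarchy from it. They are used only when the input
data cannot support estimation (no paired structure / single sample)
and are always flagged in the returned provenance.

# Estimation

`estimate_params()` runs four estimators against a validated dataset.

**Size factors.** A pooled-deconvolution scheme implemented in-package:
cells are ordered on a ring by library size; overlapping pools of sizes
21–101 are summed; each pooled profile is compared to the average
pseudo-cell by a median ratio across genes; and the per-cell factors are
recovered by sparse least squares with low-weight anchor rows. Pools are
built from library-size-scaled profiles (the pooled ratio then estimates
a near-constant residual factor, which is much less noisy than raw-count
ratios) and the library size is multiplied back. Below 100 cells the
routine falls back to plain library-size factors. On negative-binomial
data with 1×–4× library variation the factors track the true scale with
Spearman correlation above 0.95 (tested), and agree with the reference
deconvolution implementation where available.

**Mean hierarchy.** Normalized expression is averaged per sample
(`mu_hat_gij`), per subject, and over all `N` samples (`mu_hat_g`);
factors are the ratios `a_gi = mu_hat_gi / mu_hat_g`,
`b_gij = mu_hat_gij / mu_hat_gi`. The product reconstruction
`mu_hat_g * a * b = mu_hat_gij` is exact by construction and verified to
1e-10 in the tests.

**Variance decomposition with error correction.** The raw across-subject
variance of `a_gi` and pooled across-sample variance of `b_gij` both
contain finite-cell sampling noise even without true subject/sample
effects. The exact reference procedure for this correction was not
available to us, so the package uses a first-order delta-method
stand-in, documented as such: `Var(mu_hat_gij) ≈ s²_gij / c_ij` (within-
sample variance over cells divided by cell count), propagated to factor
scale as `Var(b) ≈ Var(mu_hat_gij)/mu_hat_gi²` and
`Var(a) ≈ (1/n²) Σ_j Var(mu_hat_gij)/mu_hat_g²`, averaged per gene,
subtracted, and floored at zero. Genes with ≥ 60% zero counts are
excluded as unstable. Only genes with data at both levels enter; when
the data carry no paired structure (fewer than two subjects with two or
more samples), sample factors are taken against the global mean instead
(`b' = mu_hat_gij / mu_hat_g`) and the subject level falls back to the
packaged defaults — the two levels are confounded in such data and we
refuse to guess.

**Log-normal moment fit.** With `M` and `V` the across-gene mean and
variance of the corrected variances, `sigma² = log(1 + V/M²)`,
`mu = log M − sigma²/2`. Non-positive entries are dropped (log-normal
support); all-zero input is an error, not a silent default.

**Dispersions.** Estimated on the single sample with the most cells
(ties broken by sample id) with `edgeR::estimateDisp` — Cox–Reid
adjusted-profile-likelihood tagwise estimates squeezed toward a fitted
mean–dispersion trend. Genes detected in fewer than 5% of that sample's
cells are excluded from the fit and assigned the common dispersion of
the detected genes: tagwise estimates are unidentifiable there, and
letting those genes into the fit drags the trend (and hence the
squeezed estimates) downward by tens of percent on our fixtures.
Filtering weakly detected genes before `estimateDisp` is standard
practice; the cutoff is exposed as `detect_frac`.

**Library sizes.** `mu_L` and `sigma_L` are the across-sample averages
of the per-sample mean and sd of log library size. Shift ratios
`r_ij = (per-sample mean log lib)/mu_L` have variance `v`; the
concentration is recovered by the same identity used in simulation,
`alpha_d = (N − v − 1)/(N v)`. A single sample yields `alpha_d = 1e6`
(shifts ≈ 1) with a warning.

# Differential expression specification

Three forms, all resolving to a genes × timepoints log2FC matrix whose
first column is zero: a proportion plus a single magnitude (random gene
subset, even up/down split with the odd gene up, linear interpolation
between first and last timepoint); a pool of log2FC values sampled per
DE gene; or an explicit per-gene trajectory matrix for arbitrary
non-linear patterns. Ground truth (matrix + per-gene flag) is stored in
the simulated object and written alongside the counts.

# Fidelity battery

`compare_datasets()` quantifies how close two datasets are:

* univariate two-sample KS statistics for per-gene mean/variance of
  log2 CPM and zero fraction, and per-cell zero fraction and log
  library size;
* bivariate KS for the three gene-metric pairs and the cell-metric
  pair. The two-sample bivariate statistic is the quadrant construction:
  at every observed point of either sample and all four quadrant
  orientations, the absolute difference in quadrant fractions, maximised
  over everything. Published two-sample variants differ in whether the
  two per-sample maxima are averaged or maximised; we maximise (the
  conservative choice) and pin the definition with a brute-force oracle
  test. Inputs beyond 2000 points per sample are subsampled for the
  quadratic scan.
* silhouette widths per cell at the sample and subject level, on the
  top 10 principal components of log2 CPM;
* per-gene intraclass correlations from nested random-intercept mixed
  models (REML via lme4) on log2 CPM, with a method-of-moments fallback
  on non-convergence (flagged per gene). We define `ICC_subject` as the
  correlation of two cells from the same subject in different samples,
  `sigma²_u / (sigma²_u + sigma²_v + sigma²_e)`, and `ICC_sample` as the
  correlation of two cells from the same sample,
  `(sigma²_u + sigma²_v) / (total)` — the sample ICC therefore includes
  the subject component and can never be smaller. log2(CPM+1) is used
  as the variance-stabilizing transform throughout, matching the rest
  of the battery. ICC defaults to a 100-gene subsample for speed
  (configurable; DE genes are excluded when truth is present).

# Power engine

`run_power_grid()` reproduces the simulate-then-down-sample design: per
replicate one master dataset at the grid envelope (max subjects,
timepoints, cells), carved into each scenario by down-sampling so all
scenarios share the master's truth labels. Down-sampling keeps the
first and last timepoint (plus evenly spaced interior ones) so the
full first-to-last effect size is preserved; subjects and cells are
uniform random subsets. Per scenario the engine filters genes with
> 90% zeros (strict inequality), tests, adjusts by Benjamini–Hochberg,
and scores: power over truth-DE genes surviving the filter at adjusted
p < 0.05, FDR over rejections, type-I error over truth-null genes at
unadjusted p < 0.05. Truth-DE genes removed by the filter are excluded
from the power denominator (the alternative — counting them as misses —
would conflate detectability with expression level; the filtered count
is reported so either convention can be recomputed).

The built-in DE backend is a paired pseudobulk moderated t-test:
per-sample count sums, log2 CPM, within-subject first-vs-last
differences, empirical-Bayes variance moderation. It is deliberately
**not** a cell-level hurdle model with random effects — that class of
model is reachable through the adapter contract (a command receiving
counts directory, metadata, contrast file and output path, returning a
`gene_id`/`p_value` TSV, or an R function). The builtin backend is
well calibrated at desk scale (null type-I error within (0.03, 0.07) in
the acceptance suite) but conservative for small per-cell effects, so
absolute power values are not comparable to cell-level methods; the
engine's purpose at desk scale is the *ordering* of design scenarios,
which the acceptance suite checks directionally.

# Numerical choices

* Variance targets below 1e-8 yield exact ones (no RNG); targets at or
  above `k − 1` are clamped to `0.999 (k − 1)` with a warning (the
  concentration would otherwise be non-positive).
* When the clamped concentration is so small that all gamma draws
  underflow to zero, the draw degenerates — correctly, this is the
  Dirichlet's `alpha -> 0` limit — to a uniformly random one-hot vertex.
* Draw order in `simulate_dataset()` is fixed and documented: cells per
  sample, DE assignment, factor variances and factors (gene-major,
  subjects before samples), library shifts and sizes, gamma layer,
  Poisson layer. Identical seeds give bit-identical counts.
* `d_ij` multiplies `mu_L` (location product); a warning is issued if
  `mu_L <= 0`, where multiplicative shifts would invert direction.
* With a custom library-size pool, sizes are resampled with replacement
  and shifted on the log scale by `(d_ij − 1) * mean(log(pool))`,
  matching the parametric mode's location effect around the pool's own
  location.
* Degenerate size factors (non-finite or non-positive) are replaced by
  the smallest positive factor with a warning; factors always rescale
  to mean one.
* Zero-library cells are excluded from metric computations with a
  warning; all-zero latent cells produce all-zero observed cells.

# What the synthetic fixtures do and do not establish

The test fixtures emulate gene-wise means with log-normal spread, NB
overdispersion, log-normal library sizes with sample shifts, and the
nested factor hierarchy — i.e. exactly the model the estimators assume.
Green recovery tests therefore establish internal consistency
(estimators invert the generator at stated tolerances), not fidelity to
any particular tissue: real data depart from the model through
gene–gene correlation, zero inflation beyond gamma-Poisson, discrete
subpopulation structure within a "cell type", and non-log-normal
library tails (the custom library pool exists for the latter). The
published headline fidelity and power results for this class of method
depend on restricted empirical datasets and an external hurdle-model
backend; they are intentionally not reproduced here, and the acceptance
report carries no stand-in values for them.

# Known limitations

* One sample per subject per timepoint; two-group cross-sectional
  designs are expressed as two "timepoints".
* No gene–gene correlation, doublets, ambient RNA or UMI saturation.
* Multiple cell types require repeated runs; cross-cell-type
  correlation within subjects is not modelled.
* The delta-method error-variance correction is first-order; for genes
  with extreme sampling noise relative to their mean it can
  over-subtract (floored at zero) or under-subtract.
* The adapter contract runs one process per dataset; per-replicate
  model fitting cost is the caller's responsibility.
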