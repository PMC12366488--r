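#' Default hierarchy hyper-parameters
#'
#' Log-scale mean/sd of the gene-wise subject- and sample-level factor
#' variances, used when the input data carry no multi-sample or paired
#' structure to estimate them from.  The values were derived by running
#' `scripts/derive_defaults.R` (in the package source repository), which
#' simulates a synthetic reference dataset with moderate nested
#' variability and re-estimates the hierarchy from it; they are
#' package-derived, not taken from any published table.
#'
#' @format Named numeric vector with elements `subj_var_logmean`,
#'   `subj_var_logsd`, `samp_var_logmean`, `samp_var_logsd`.
#' @export
default_hierarchy_params <- c(
  subj_var_logmean = -3.04,
  subj_var_logsd   = 0.95,
  samp_var_logmean = -4.06,
  samp_var_logsd   = 0.76
)

#' Uniform cells-per-sample specification
#'
#' Marks a length-2 range so that the simulator draws the number of cells
#' for every sample independently from a discrete uniform distribution.
#'
#' @param lo,hi Integer bounds (inclusive), `1 <= lo <= hi`.
#' @return Object of class `cells_uniform`.
#' @examples
#' p <- sim_params(n_genes = 50, cells_per_sample = cells_uniform(80, 120))
#' @export
cells_uniform <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi))
    stop("'lo' and 'hi' must be single integers")
  if (lo < 1L || hi < lo)
    stop("need 1 <= lo <= hi for a cells-per-sample range")
  structure(c(lo = lo, hi = hi), class = "cells_uniform")
}

#' Simulation parameter set
#'
#' Bundles every hyper-parameter of the nested gamma-Poisson model:
#' design sizes (genes G, subjects m, timepoints n, cells per sample c),
#' gene-wise global means and dispersions, log-normal hyper-parameters of
#' the subject- and sample-level factor variances, library-size
#' log-normal location/scale and the Dirichlet concentration controlling
#' sample-specific library shifts, an optional empirical library-size
#' pool, and an optional differential-expression specification.
#'
#' Gene means default to draws from a log-normal chosen to mimic a
#' typical UMI cell type (most genes lowly expressed, a long right tail)
#' and dispersions to a constant 0.4; both are normally replaced by
#' [estimate_params()] output.
#'
#' @param n_genes Number of genes G (>= 1).
#' @param n_subjects Number of subjects m (>= 1).
#' @param n_timepoints Samples (timepoints) per subject n (>= 1).
#' @param cells_per_sample Single number (same cell count for every
#'   sample), a [cells_uniform()] range, or an explicit vector of
#'   `n_subjects * n_timepoints` counts ordered subject-major.
#' @param gene_means Positive length-G vector of global means `mu_g`.
#' @param dispersions Non-negative length-G vector `phi_g`.
#' @param subj_var_logmean,subj_var_logsd Log-scale mean / sd of the
#'   gene-wise subject-factor variance (drawn log-normal per gene).
#' @param samp_var_logmean,samp_var_logsd Same for the sample level.
#' @param lib_logmean,lib_logsd Mean / sd of per-cell log library size.
#' @param lib_concentration Symmetric Dirichlet concentration for
#'   sample-specific library-size shifts; large values mean no shift.
#' @param custom_lib_sizes Optional positive vector of empirical library
#'   sizes to resample instead of the log-normal draw.
#' @param de_spec Optional DE specification, see [de_spec_proportion()].
#' @param timepoint_labels Optional character labels, length
#'   `n_timepoints`, first label = baseline.
#' @param provenance Named character vector tagging fields as
#'   "estimated", "default" or "user"; filled automatically.
#' @return Object of class `sim_params` (validated list).
#' @seealso [estimate_params()], [simulate_dataset()], [read_params()]
#' @examples
#' p <- sim_params(n_genes = 100, n_subjects = 4, n_timepoints = 2,
#'                 cells_per_sample = 50)
#' p
#' @export
sim_params <- function(n_genes,
                       n_subjects = 5L,
                       n_timepoints = 2L,
                       cells_per_sample = 100L,
                       gene_means = NULL,
                       dispersions = NULL,
                       subj_var_logmean = unname(default_hierarchy_params["subj_var_logmean"]),
                       subj_var_logsd   = unname(default_hierarchy_params["subj_var_logsd"]),
                       samp_var_logmean = unname(default_hierarchy_params["samp_var_logmean"]),
                       samp_var_logsd   = unname(default_hierarchy_params["samp_var_logsd"]),
                       lib_logmean = log(5000),
                       lib_logsd = 0.35,
                       lib_concentration = 500,
                       custom_lib_sizes = NULL,
                       de_spec = NULL,
                       timepoint_labels = NULL,
                       provenance = NULL) {
  n_genes <- as.integer(n_genes)
  n_subjects <- as.integer(n_subjects)
  n_timepoints <- as.integer(n_timepoints)
  if (is.null(gene_means)) {
    # log-normal spread typical of a filtered UMI cell type: median ~0.05,
    # heavy right tail so top genes dominate the library
    gene_means <- exp(stats::rnorm(n_genes, mean = -3, sd = 1.8))
  }
  if (is.null(dispersions)) dispersions <- rep(0.4, n_genes)
  if (is.null(timepoint_labels))
    timepoint_labels <- paste0("t", seq_len(n_timepoints))
  if (is.null(provenance))
    provenance <- c(gene_means = "user", dispersions = "user",
                    hierarchy = "user", library = "user")
  p <- structure(list(
    n_genes = n_genes,
    n_subjects = n_subjects,
    n_timepoints = n_timepoints,
    cells_per_sample = cells_per_sample,
    gene_means = gene_means,
    dispersions = dispersions,
    subj_var_logmean = subj_var_logmean,
    subj_var_logsd = subj_var_logsd,
    samp_var_logmean = samp_var_logmean,
    samp_var_logsd = samp_var_logsd,
    lib_logmean = lib_logmean,
    lib_logsd = lib_logsd,
    lib_concentration = lib_concentration,
    custom_lib_sizes = custom_lib_sizes,
    de_spec = de_spec,
    timepoint_labels = timepoint_labels,
    provenance = provenance
  ), class = "sim_params")
  validate_params(p)
  p
}

#' Validate a `sim_params` object
#'
#' Checks every invariant of the parameter set and stops with an
#' informative message on the first violation.
#'
#' @param p A `sim_params` object.
#' @return `p`, invisibly.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  with(p, {
    if (n_genes < 1L) stop("n_genes must be >= 1")
    if (n_subjects < 1L) stop("n_subjects must be >= 1")
    if (n_timepoints < 1L) stop("n_timepoints must be >= 1")
    if (length(gene_means) != n_genes || any(!is.finite(gene_means)) ||
        any(gene_means <= 0))
      stop("gene_means must be length n_genes and strictly positive")
    if (length(dispersions) != n_genes || any(!is.finite(dispersions)) ||
        any(dispersions < 0))
      stop("dispersions must be length n_genes and non-negative")
    if (subj_var_logsd < 0 || samp_var_logsd < 0 || lib_logsd < 0)
      stop("log-sd hyper-parameters must be non-negative")
    if (!is.finite(lib_concentration) || lib_concentration <= 0)
      stop("lib_concentration must be positive")
    if (!is.null(custom_lib_sizes)) {
      if (length(custom_lib_sizes) == 0L)
        stop("custom_lib_sizes is empty")
      if (any(!is.finite(custom_lib_sizes)) || any(custom_lib_sizes <= 0))
        stop("custom_lib_sizes must be positive")
    }
    if (length(timepoint_labels) != n_timepoints ||
        anyDuplicated(timepoint_labels))
      stop("timepoint_labels must be n_timepoints unique labels")
    cs <- resolve_cells_per_sample(p, check_only = TRUE)
    if (any(cs < 1L)) stop("cells per sample must be >= 1")
    invisible(NULL)
  })
  invisible(p)
}

# Resolve the cells-per-sample spec to a vector of length m*n (subject-major).
# With check_only the uniform range returns its bounds (no RNG touched).
resolve_cells_per_sample <- function(p, check_only = FALSE) {
  spec <- p$cells_per_sample
  n_samp <- p$n_subjects * p$n_timepoints
  if (inherits(spec, "cells_uniform")) {
    if (check_only) return(as.integer(spec))
    return(as.integer(sample(seq(spec[["lo"]], spec[["hi"]]), n_samp,
                             replace = TRUE)))
  }
  spec <- as.integer(spec)
  if (length(spec) == 1L) return(rep(spec, n_samp))
  if (length(spec) == n_samp) return(spec)
  stop("cells_per_sample must be a single count, a cells_uniform() range, ",
       "or an explicit vector of length n_subjects * n_timepoints")
}

#' Modify fields of a parameter set
#'
#' @param p A `sim_params` object.
#' @param ... Named fields to replace (same names as [sim_params()]).
#' @return The updated, re-validated `sim_params`.
#' @examples
#' p <- sim_params(n_genes = 20)
#' p2 <- update_params(p, subj_var_logmean = p$subj_var_logmean + log(1.5))
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "sim_params"))
  upd <- list(...)
  unknown <- setdiff(names(upd), names(p))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(upd)) p[[nm]] <- upd[[nm]]
  validate_params(p)
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Nested gamma-Poisson simulation parameters\n")
  cat(sprintf("  design: %d genes, %d subjects x %d timepoints\n",
              x$n_genes, x$n_subjects, x$n_timepoints))
  cs <- x$cells_per_sample
  if (inherits(cs, "cells_uniform")) {
    cat(sprintf("  cells/sample: uniform [%d, %d]\n", cs[["lo"]], cs[["hi"]]))
  } else if (length(cs) == 1L) {
    cat(sprintf("  cells/sample: %d (fixed)\n", as.integer(cs)))
  } else {
    cat(sprintf("  cells/sample: explicit (%d..%d)\n", min(cs), max(cs)))
  }
  cat(sprintf("  gene means: median %.4g  dispersions: median %.3g\n",
              stats::median(x$gene_means), stats::median(x$dispersions)))
  cat(sprintf("  subject factor variance ~ LNorm(%.3g, %.3g^2)\n",
              x$subj_var_logmean, x$subj_var_logsd))
  cat(sprintf("  sample factor variance  ~ LNorm(%.3g, %.3g^2)\n",
              x$samp_var_logmean, x$samp_var_logsd))
  cat(sprintf("  log library size ~ N(%.3g, %.3g^2), shift concentration %.4g%s\n",
              x$lib_logmean, x$lib_logsd, x$lib_concentration,
              if (!is.null(x$custom_lib_sizes)) " (custom pool)" else ""))
  if (!is.null(x$de_spec)) cat("  DE spec: ", format_de_spec(x$de_spec), "\n")
  if (!is.null(x$provenance))
    cat("  provenance:", paste(names(x$provenance), x$provenance,
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a parameter set to a structured text file
#'
#' Parameters are serialized as JSON with sections `design`, `gene`,
#' `hierarchy`, `library`, `de` and `provenance`.  Gene means and
#' dispersions go to a sidecar TSV next to the main file
#' (`<stem>_genes.tsv`, columns `gene_index`, `mean`, `dispersion`) so
#' the JSON stays readable.
#'
#' @param p A `sim_params` object.
#' @param path Output path for the JSON file.
#' @return Invisibly, paths written (json + sidecar).
#' @export
write_params <- function(p, path) {
  validate_params(p)
  sidecar <- paste0(sub("\\.json$", "", path), "_genes.tsv")
  utils::write.table(
    data.frame(gene_index = seq_len(p$n_genes),
               mean = p$gene_means, dispersion = p$dispersions),
    sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- p$cells_per_sample
  cells <- if (inherits(cs, "cells_uniform")) {
    list(type = "uniform", lo = unname(cs[["lo"]]), hi = unname(cs[["hi"]]))
  } else if (length(cs) == 1L) {
    list(type = "fixed", value = as.integer(cs))
  } else list(type = "explicit", values = as.integer(cs))
  obj <- list(
    design = list(n_genes = p$n_genes, n_subjects = p$n_subjects,
                  n_timepoints = p$n_timepoints, cells = cells,
                  timepoint_labels = p$timepoint_labels),
    gene = list(sidecar = basename(sidecar)),
    hierarchy = list(subj_var_logmean = p$subj_var_logmean,
                     subj_var_logsd = p$subj_var_logsd,
                     samp_var_logmean = p$samp_var_logmean,
                     samp_var_logsd = p$samp_var_logsd),
    library = list(lib_logmean = p$lib_logmean, lib_logsd = p$lib_logsd,
                   lib_concentration = p$lib_concentration,
                   custom_lib_sizes = p$custom_lib_sizes),
    de = serialize_de_spec(p$de_spec),
    provenance = as.list(p$provenance)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(json = path, sidecar = sidecar))
}

#' Read a parameter set written by [write_params()]
#'
#' @param path Path to the JSON parameter file; the `<stem>_genes.tsv`
#'   sidecar must sit next to it.
#' @return A validated `sim_params` object.
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sidecar <- file.path(dirname(path), obj$gene$sidecar)
  if (!file.exists(sidecar))
    stop("gene sidecar file not found: ", sidecar)
  genes <- utils::read.delim(sidecar)
  cells <- obj$design$cells
  cs <- switch(cells$type,
               fixed = as.integer(cells$value),
               uniform = cells_uniform(cells$lo, cells$hi),
               explicit = as.integer(cells$values),
               stop("unknown cells spec type: ", cells$type))
  prov <- unlist(obj$provenance)
  sim_params(
    n_genes = obj$design$n_genes,
    n_subjects = obj$design$n_subjects,
    n_timepoints = obj$design$n_timepoints,
    cells_per_sample = cs,
    gene_means = genes$mean,
    dispersions = genes$dispersion,
    subj_var_logmean = obj$hierarchy$subj_var_logmean,
    subj_var_logsd = obj$hierarchy$subj_var_logsd,
    samp_var_logmean = obj$hierarchy$samp_var_logmean,
    samp_var_logsd = obj$hierarchy$samp_var_logsd,
    lib_logmean = obj$library$lib_logmean,
    lib_logsd = obj$library$lib_logsd,
    lib_concentration = obj$library$lib_concentration,
    custom_lib_sizes = obj$library$custom_lib_sizes,
    de_spec = deserialize_de_spec(obj$de),
    timepoint_labels = obj$design$timepoint_labels,
    provenance = if (length(prov)) prov else NULL
  )
}
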