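#' Differential-expression specifications
#'
#' Three ways to declare which genes change over time and by how much.
#' All forms resolve (via [resolve_de_spec()]) to a genes x timepoints
#' matrix of log2 fold changes relative to the first timepoint, whose
#' first column is all zeros.
#'
#' * `de_spec_proportion(prop, lfc)`: a random `ceiling(prop * G)` genes
#'   become DE, half up- and half down-regulated by `lfc` log2 units
#'   between the first and last timepoint, with linear interpolation at
#'   intermediate timepoints.  An odd DE count puts the extra gene in
#'   the up-regulated half.
#' * `de_spec_pool(pool, prop)`: like the proportion form, but each DE
#'   gene's first-to-last log2FC is sampled with replacement from
#'   `pool` (signs as given in the pool).
#' * `de_spec_matrix(log2fc)`: explicit genes x timepoints matrix (or a
#'   named list of per-gene trajectories) passed through after
#'   validation; rownames identify genes.
#'
#' @param prop Proportion of genes DE, in \[0, 1\].
#' @param lfc Magnitude of the first-to-last log2 fold change (> 0).
#' @param pool Numeric vector of candidate log2FC values (non-zero).
#' @param log2fc Matrix genes x timepoints of log2FC, first column zero,
#'   or a named list of length-`n_timepoints` numeric trajectories.
#' @return An object of class `de_spec`.
#' @examples
#' de_spec_proportion(0.2, 0.35)
#' @export
de_spec_proportion <- function(prop, lfc) {
  if (prop < 0 || prop > 1) stop("prop must be in [0, 1]")
  if (lfc <= 0) stop("lfc must be positive; direction is split evenly")
  structure(list(form = "proportion", prop = prop, lfc = lfc),
            class = "de_spec")
}

#' @rdname de_spec_proportion
#' @export
de_spec_pool <- function(pool, prop) {
  if (length(pool) == 0L || any(!is.finite(pool)))
    stop("pool must be a non-empty finite numeric vector")
  if (any(pool == 0)) stop("pool log2FC values must be non-zero")
  if (prop < 0 || prop > 1) stop("prop must be in [0, 1]")
  structure(list(form = "pool", pool = as.numeric(pool), prop = prop),
            class = "de_spec")
}

#' @rdname de_spec_proportion
#' @export
de_spec_matrix <- function(log2fc) {
  if (is.list(log2fc) && !is.null(names(log2fc)))
    log2fc <- do.call(rbind, log2fc)
  if (!is.matrix(log2fc)) stop("log2fc must be a matrix or named list")
  if (is.null(rownames(log2fc)))
    stop("log2fc matrix needs rownames identifying genes")
  structure(list(form = "matrix", log2fc = log2fc), class = "de_spec")
}

format_de_spec <- function(spec) {
  if (is.null(spec)) return("none")
  switch(spec$form,
         proportion = sprintf("%.3g of genes at +/-%.3g log2FC",
                              spec$prop, spec$lfc),
         pool = sprintf("%.3g of genes, log2FC pool of %d values",
                        spec$prop, length(spec$pool)),
         matrix = sprintf("explicit matrix for %d genes",
                          nrow(spec$log2fc)))
}

serialize_de_spec <- function(spec) {
  if (is.null(spec)) return(NULL)
  if (spec$form == "matrix") {
    list(form = "matrix",
         genes = rownames(spec$log2fc),
         log2fc = apply(spec$log2fc, 1L, as.numeric, simplify = FALSE))
  } else unclass(spec)
}

deserialize_de_spec <- function(obj) {
  if (is.null(obj) || length(obj) == 0L) return(NULL)
  switch(obj$form,
         proportion = de_spec_proportion(obj$prop, obj$lfc),
         pool = de_spec_pool(unlist(obj$pool), obj$prop),
         matrix = {
           m <- do.call(rbind, lapply(obj$log2fc, unlist))
           rownames(m) <- unlist(obj$genes)
           de_spec_matrix(m)
         },
         stop("unknown de_spec form: ", obj$form))
}

#' Resolve a DE specification to a log2 fold-change matrix
#'
#' Expands any [de_spec_proportion()] / [de_spec_pool()] /
#' [de_spec_matrix()] object into the full genes x timepoints log2FC
#' matrix used by the simulator, plus a per-gene DE flag.  The first
#' column (baseline) is always zero; the proportion and pool forms
#' interpolate linearly between baseline and the final timepoint.  A
#' `NULL` spec yields the all-zero matrix.
#'
#' @param spec A `de_spec` or `NULL`.
#' @param gene_ids Character vector of gene identifiers (length G).
#' @param n_timepoints Number of timepoints T (>= 2 if `spec` non-null).
#' @return List with `log2fc` (G x T matrix, dimnames gene x timepoint
#'   index) and `de_flag` (logical length G).
#' @examples
#' r <- resolve_de_spec(de_spec_proportion(0.2, 0.35), paste0("g", 1:10), 2)
#' table(r$de_flag)
#' @export
resolve_de_spec <- function(spec, gene_ids, n_timepoints) {
  G <- length(gene_ids)
  lfc_mat <- matrix(0, G, n_timepoints,
                    dimnames = list(gene_ids, NULL))
  de_flag <- rep(FALSE, G)
  if (is.null(spec))
    return(list(log2fc = lfc_mat, de_flag = de_flag))
  if (n_timepoints < 2L)
    stop("differential expression needs at least 2 timepoints")
  ramp <- seq(0, 1, length.out = n_timepoints)
  if (spec$form %in% c("proportion", "pool")) {
    n_de <- ceiling(spec$prop * G)
    if (spec$prop > 0 && n_de < 1L) {
      warning("prop * n_genes < 1: no DE genes assigned")
      n_de <- 0L
    }
    if (n_de > 0L) {
      idx <- sample.int(G, n_de)
      de_flag[idx] <- TRUE
      if (spec$form == "proportion") {
        n_up <- ceiling(n_de / 2)  # odd count: extra gene goes up
        final <- c(rep(spec$lfc, n_up), rep(-spec$lfc, n_de - n_up))
      } else {
        final <- sample(spec$pool, n_de, replace = TRUE)
      }
      lfc_mat[idx, ] <- outer(final, ramp)
    }
  } else if (spec$form == "matrix") {
    m <- spec$log2fc
    if (ncol(m) != n_timepoints)
      stop("log2fc matrix has ", ncol(m), " columns but the design has ",
           n_timepoints, " timepoints")
    missing <- setdiff(rownames(m), gene_ids)
    if (length(missing))
      stop("log2fc matrix names genes absent from the dataset: ",
           paste(utils::head(missing, 5), collapse = ", "))
    if (any(m[, 1L] != 0))
      stop("log2fc at the first (baseline) timepoint must be zero")
    lfc_mat[rownames(m), ] <- m
    de_flag <- rowSums(lfc_mat != 0) > 0
  } else stop("unknown de_spec form: ", spec$form)
  list(log2fc = lfc_mat, de_flag = de_flag)
}
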