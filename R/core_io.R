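#' Construct a validated nested single-cell dataset
#'
#' The package's dataset container is a
#' [SingleCellExperiment::SingleCellExperiment] whose `counts` assay
#' holds non-negative integers (genes x cells, sparse) and whose
#' `colData` carries `cell_id`, `subject_id`, `sample_id` and
#' `timepoint` (a factor; its level order defines the first and last
#' timepoint).  Validation enforces the nesting: every cell belongs to
#' one sample, every sample to one subject and one timepoint, and no
#' subject has two samples at the same timepoint.
#'
#' @param counts Genes x cells matrix (base or `Matrix` sparse) of
#'   non-negative integers, rownames = gene ids.
#' @param cells `data.frame` with columns `cell_id`, `subject_id`,
#'   `sample_id`, `timepoint`, one row per column of `counts` (same
#'   order).
#' @param timepoint_levels Optional character vector giving timepoint
#'   order; defaults to lexicographic sorting with a warning when there
#'   is more than one timepoint.
#' @return A `SingleCellExperiment`.
#' @export
sc_dataset <- function(counts, cells, timepoint_levels = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  check_count_matrix(counts)
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  req <- c("cell_id", "subject_id", "sample_id", "timepoint")
  if (!all(req %in% names(cells)))
    stop("cell metadata must have columns: ", paste(req, collapse = ", "))
  if (nrow(cells) != ncol(counts))
    stop("metadata has ", nrow(cells), " rows but matrix has ",
         ncol(counts), " cells")
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell ids in metadata")
  cells$subject_id <- as.character(cells$subject_id)
  cells$sample_id <- as.character(cells$sample_id)
  tp <- as.character(cells$timepoint)
  if (is.null(timepoint_levels)) {
    timepoint_levels <- sort(unique(tp))
    if (length(timepoint_levels) > 1L)
      warning("no timepoint order declared; using lexicographic order: ",
              paste(timepoint_levels, collapse = " < "))
  }
  if (!all(tp %in% timepoint_levels))
    stop("timepoint value(s) not in declared levels: ",
         paste(setdiff(unique(tp), timepoint_levels), collapse = ", "))
  cells$timepoint <- factor(tp, levels = timepoint_levels)
  # nesting: sample -> unique (subject, timepoint)
  smap <- unique(cells[, c("sample_id", "subject_id", "timepoint")])
  if (anyDuplicated(smap$sample_id)) {
    bad <- smap$sample_id[duplicated(smap$sample_id)]
    stop("sample(s) mapped to several subjects/timepoints: ",
         paste(unique(bad), collapse = ", "))
  }
  st <- paste(smap$subject_id, smap$timepoint, sep = "\r")
  if (anyDuplicated(st))
    stop("subject has duplicate samples at one timepoint: ",
         paste(smap$subject_id[duplicated(st)], collapse = ", "))
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  colnames(counts) <- cells$cell_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id))
}

check_count_matrix <- function(counts) {
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else counts
  if (any(!is.finite(vals))) stop("counts contain non-finite values")
  if (any(vals < 0)) stop("negative count in matrix")
  if (any(vals != round(vals))) stop("non-integer count in matrix")
  invisible(TRUE)
}

# internal shorthand accessors
dataset_counts <- function(x) SummarizedExperiment::assay(x, "counts")
dataset_cells <- function(x) as.data.frame(SummarizedExperiment::colData(x))

# cells-per-sample table and total sample count
sample_table <- function(x) {
  cd <- dataset_cells(x)
  st <- unique(cd[, c("sample_id", "subject_id", "timepoint")])
  st$n_cells <- as.integer(table(cd$sample_id)[st$sample_id])
  st[order(st$subject_id, st$timepoint), , drop = FALSE]
}

#' Read a count matrix plus cell metadata
#'
#' Reads a MatrixMarket coordinate file (or a dense delimited matrix)
#' together with gene ids and a delimited per-cell metadata table, and
#' assembles a validated dataset.  Matrix and metadata are aligned by
#' `cell_id` against the barcodes file when one is given (`align =
#' "id"`), otherwise positionally with a warning.
#'
#' @param matrix_path Path to `matrix.mtx` or a dense TSV/CSV (genes x
#'   cells, first column gene ids when `genes_path` is `NULL`).
#' @param genes_path Path to a 1- or 2-column gene id file (10x
#'   `genes.tsv`/`features.tsv`); first column used.
#' @param metadata_path Delimited file with a header.
#' @param column_map Named list mapping metadata columns:
#'   `cell`, `subject`, `sample`, `timepoint`, and optionally
#'   `align` ("id" or "order").
#' @param barcodes_path Optional path to per-column cell barcodes (one
#'   per line); required for `align = "id"` with MTX input.
#' @param timepoint_levels Optional declared timepoint order.
#' @return A `SingleCellExperiment` (see [sc_dataset()]).
#' @examples
#' \dontrun{
#' ds <- read_counts_with_metadata("matrix.mtx", "genes.tsv", "meta.tsv",
#'   column_map = list(cell = "cell_id", subject = "subject",
#'                     sample = "sample", timepoint = "time"))
#' }
#' @export
read_counts_with_metadata <- function(matrix_path, genes_path = NULL,
                                      metadata_path,
                                      column_map = list(),
                                      barcodes_path = NULL,
                                      timepoint_levels = NULL) {
  cm <- utils::modifyList(
    list(cell = "cell_id", subject = "subject_id", sample = "sample_id",
         timepoint = "timepoint", align = "id"), column_map)
  is_mtx <- grepl("\\.mtx$", matrix_path)
  if (is_mtx) {
    counts <- as.matrix(Matrix::readMM(matrix_path))
    if (is.null(genes_path))
      stop("genes_path is required for MatrixMarket input")
    genes <- utils::read.delim(genes_path, header = FALSE)
    if (nrow(genes) != nrow(counts))
      stop("gene file has ", nrow(genes), " rows but matrix has ",
           nrow(counts), " genes")
    rownames(counts) <- as.character(genes[[1L]])
    if (!is.null(barcodes_path)) {
      bc <- readLines(barcodes_path)
      if (length(bc) != ncol(counts))
        stop("barcodes file has ", length(bc), " entries but matrix has ",
             ncol(counts), " cells")
      colnames(counts) <- bc
    }
  } else {
    tab <- utils::read.delim(matrix_path, check.names = FALSE,
                             sep = delim_guess(matrix_path))
    if (is.null(genes_path)) {
      rn <- as.character(tab[[1L]])
      counts <- as.matrix(tab[, -1L, drop = FALSE])
      rownames(counts) <- rn
    } else {
      counts <- as.matrix(tab)
      genes <- utils::read.delim(genes_path, header = FALSE)
      rownames(counts) <- as.character(genes[[1L]])
    }
  }
  meta <- utils::read.delim(metadata_path, sep = delim_guess(metadata_path))
  need <- unlist(cm[c("cell", "subject", "sample", "timepoint")])
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  cells <- data.frame(cell_id = as.character(meta[[cm$cell]]),
                      subject_id = meta[[cm$subject]],
                      sample_id = meta[[cm$sample]],
                      timepoint = meta[[cm$timepoint]])
  if (identical(cm$align, "id") && !is.null(colnames(counts))) {
    missing_cells <- setdiff(cells$cell_id, colnames(counts))
    if (length(missing_cells))
      stop("metadata cell(s) absent from the matrix: ",
           paste(utils::head(missing_cells, 5), collapse = ", "))
    counts <- counts[, cells$cell_id, drop = FALSE]
  } else {
    if (identical(cm$align, "id"))
      warning("no cell ids on the matrix; falling back to positional ",
              "alignment of metadata rows to matrix columns")
    if (nrow(cells) != ncol(counts))
      stop("metadata has ", nrow(cells), " rows but matrix has ",
           ncol(counts), " cells")
  }
  sc_dataset(counts, cells, timepoint_levels = timepoint_levels)
}

delim_guess <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

# MatrixMarket writer with the integer header (Matrix::writeMM always
# declares "real"); 1-based coordinates per the standard.
write_mtx_integer <- function(counts, path) {
  m <- methods::as(counts, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x))
    writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  invisible(path)
}

#' Write a simulated (or empirical) dataset to disk
#'
#' Writes counts, cell metadata, ground-truth DE annotation and, when
#' available, the generating parameters, so the directory round-trips
#' through [read_counts_with_metadata()].
#'
#' @param dataset A `SingleCellExperiment` from [simulate_dataset()] or
#'   [sc_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param format `"mtx_dir"` (matrix.mtx + genes.tsv + barcodes.tsv) or
#'   `"dense_tsv"`.
#' @return Named character vector of files written (the manifest).
#' @export
write_simulated <- function(dataset, out_dir, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  counts <- dataset_counts(dataset)
  cells <- dataset_cells(dataset)
  manifest <- c()
  if (format == "mtx_dir") {
    write_mtx_integer(counts, file.path(out_dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(out_dir, "genes.tsv"))
    writeLines(colnames(counts), file.path(out_dir, "barcodes.tsv"))
    manifest <- c(matrix = file.path(out_dir, "matrix.mtx"),
                  genes = file.path(out_dir, "genes.tsv"),
                  barcodes = file.path(out_dir, "barcodes.tsv"))
  } else {
    dense <- data.frame(gene_id = rownames(counts),
                        as.matrix(counts), check.names = FALSE)
    f <- file.path(out_dir, "counts.tsv")
    utils::write.table(dense, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(counts = f)
  }
  meta_f <- file.path(out_dir, "cell_metadata.tsv")
  utils::write.table(cells[, c("cell_id", "subject_id", "sample_id",
                               "timepoint")],
                     meta_f, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, metadata = meta_f)

  truth <- dataset_truth(dataset)
  if (!is.null(truth)) {
    tt <- data.frame(gene_id = rownames(truth$log2fc),
                     de_flag = truth$de_flag)
    lfc <- truth$log2fc
    colnames(lfc) <- paste0("log2fc_", seq_len(ncol(lfc)))
    tt <- cbind(tt, as.data.frame(lfc, row.names = NULL))
    truth_f <- file.path(out_dir, "truth.tsv")
    utils::write.table(tt, truth_f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, truth = truth_f)
  }
  prm <- S4Vectors::metadata(dataset)$params
  if (!is.null(prm)) {
    pf <- file.path(out_dir, "params.json")
    write_params(prm, pf)
    manifest <- c(manifest, params = pf)
  }
  manifest
}

# truth annotation stored by the simulator (NULL for empirical data)
dataset_truth <- function(dataset) {
  md <- S4Vectors::metadata(dataset)
  if (is.null(md$truth_log2fc)) return(NULL)
  list(log2fc = md$truth_log2fc,
       de_flag = SummarizedExperiment::rowData(dataset)$de_flag)
}

#' Drop subjects with under-sized samples
#'
#' Retains a subject only when every one of its samples has at least
#' `min_cells` cells, then removes genes left with zero total count.
#' The standard quality threshold for paired designs is 25 cells per
#' sample.
#'
#' @param dataset A `SingleCellExperiment`.
#' @param min_cells Non-negative integer.
#' @return The filtered `SingleCellExperiment`.
#' @examples
#' \dontrun{filter_subjects_min_cells(ds, 25)}
#' @export
filter_subjects_min_cells <- function(dataset, min_cells = 25L) {
  if (min_cells < 0) stop("min_cells must be >= 0")
  st <- sample_table(dataset)
  bad_subj <- unique(st$subject_id[st$n_cells < min_cells])
  keep_cells <- !(dataset_cells(dataset)$subject_id %in% bad_subj)
  if (!any(keep_cells))
    stop("all subjects removed at min_cells = ", min_cells)
  out <- dataset[, keep_cells]
  keep_genes <- Matrix::rowSums(dataset_counts(out)) > 0
  out <- out[keep_genes, ]
  md <- S4Vectors::metadata(out)
  if (!is.null(md$truth_log2fc)) {
    S4Vectors::metadata(out)$truth_log2fc <-
      md$truth_log2fc[keep_genes, , drop = FALSE]
  }
  out
}
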