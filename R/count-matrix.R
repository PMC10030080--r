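#' Gene-by-cell count matrix with cell metadata
#'
#' The universal input container of the package: a nonnegative integer
#' gene x cell matrix together with per-cell batch and group labels and
#' library sizes (column sums over the retained genes).
#'
#' @param counts Nonnegative integer matrix or `Matrix::dgCMatrix`,
#'   genes in rows, cells in columns.
#' @param batch Per-cell batch labels (coerced to factor).
#' @param group Per-cell group labels with values `"case"` / `"control"`.
#' @param gene_ids Unique gene identifiers; default taken from rownames.
#' @param cell_ids Unique cell identifiers; default taken from colnames.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (dgCMatrix), `gene_ids`, `cell_ids`, `batch`, `group`,
#'   `lib_size`.
#' @export
count_matrix <- function(counts, batch, group,
                         gene_ids = rownames(counts),
                         cell_ids = colnames(counts)) {
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%06d", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- sprintf("C%06d", seq_len(ncol(counts)))
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length mismatch")
  if (length(cell_ids) != ncol(counts)) stop("cell_ids length mismatch")
  if (length(batch) != ncol(counts)) stop("batch length mismatch")
  if (length(group) != ncol(counts)) stop("group length mismatch")
  x <- counts@x
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be nonnegative integers")
  }
  group <- as.character(group)
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  obj <- list(
    counts = counts,
    gene_ids = as.character(gene_ids),
    cell_ids = as.character(cell_ids),
    batch = factor(as.character(batch)),
    group = factor(group, levels = c("control", "case")),
    lib_size = Matrix::colSums(counts)
  )
  class(obj) <- "count_matrix"
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d cells; %d batch(es); %d case / %d control; zero rate %.3f\n",
    nrow(x$counts), ncol(x$counts), nlevels(x$batch),
    sum(x$group == "case"), sum(x$group == "control"),
    1 - Matrix::nnzero(x$counts) / prod(dim(x$counts))
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or cells
#'
#' Library sizes are recomputed on the retained genes.
#'
#' @param cm A `count_matrix`.
#' @param genes Gene index / logical / id vector (default: all).
#' @param cells Cell index / logical / id vector (default: all).
#' @export
subset_counts <- function(cm, genes = NULL, cells = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(genes)) genes <- seq_len(nrow(cm$counts))
  if (is.null(cells)) cells <- seq_len(ncol(cm$counts))
  sub <- cm$counts[genes, cells, drop = FALSE]
  count_matrix(sub,
    batch = cm$batch[cells][drop = TRUE], group = cm$group[cells],
    gene_ids = rownames(sub), cell_ids = colnames(sub)
  )
}

#' Per-gene differential-expression ground truth
#'
#' @param gene_id Gene identifiers.
#' @param status Per-gene label in `up`, `down`, `null` (direction in the
#'   case group relative to control).
#' @param effect Per-gene generative effect: the multiplicative case-group
#'   factor for the model-based simulator (exactly 1 for null genes) or the
#'   binomial success probability for the downsampling simulator.
#' @param provenance Which simulator produced the truth.
#' @return A data frame of class `sim_truth`.
#' @export
sim_truth <- function(gene_id, status, effect, provenance = "unknown") {
  status <- as.character(status)
  stopifnot(
    all(status %in% c("up", "down", "null")),
    length(gene_id) == length(status), length(status) == length(effect),
    all(effect > 0)
  )
  out <- data.frame(
    gene_id = as.character(gene_id), status = status,
    effect = as.numeric(effect), stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("sim_truth", "data.frame")
  out
}

# ---- file formats ------------------------------------------------------

#' Write a count matrix as Matrix Market plus TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, integer), `genes.tsv` (gene_id) and
#' `cells.tsv` (cell_id, batch, group) into `dir`.
#'
#' @param cm A `count_matrix`.
#' @param dir Output directory (created if missing).
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene_id = cm$gene_ids),
    file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(
      cell_id = cm$cell_ids, batch = as.character(cm$batch),
      group = as.character(cm$group)
    ),
    file.path(dir, "cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a count matrix written by [write_counts()]
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A `count_matrix`.
#' @export
read_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  count_matrix(m,
    batch = cells$batch, group = cells$group,
    gene_ids = genes$gene_id, cell_ids = cells$cell_id
  )
}

#' Write simulation truth as TSV
#' @param truth A `sim_truth`.
#' @param path Output file (`gene_id`, `status`, `effect`).
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth)[c("gene_id", "status", "effect")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read simulation truth written by [write_sim_truth()]
#' @param path TSV file with columns gene_id, status, effect.
#' @export
read_sim_truth <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  sim_truth(d$gene_id, d$status, d$effect, provenance = "file")
}

#' Read a weighted gene set
#'
#' A two-column TSV (`gene_id`, `weight`) of standard-positive genes with
#' nonnegative weights, e.g. gene-disease association scores.
#'
#' @param path TSV file.
#' @return Named numeric vector of weights.
#' @export
read_gene_set <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "weight") %in% names(d))) {
    stop("gene set file needs columns gene_id, weight")
  }
  if (anyDuplicated(d$gene_id)) stop("duplicate gene ids in gene set")
  w <- as.numeric(d$weight)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  if (!any(w > 0)) stop("gene set needs at least one positive weight")
  stats::setNames(w, d$gene_id)
}
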