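#' Filter sparsely expressed genes
#'
#' Retains genes whose zero fraction across all cells is at most
#' `max_zero_rate` (the conventional cut: genes expressed in fewer than 5%
#' of cells are removed). Library sizes are recomputed on the retained
#' genes; gene order is preserved. The operation is idempotent.
#'
#' @param cm A [count_matrix()].
#' @param max_zero_rate Maximum tolerated per-gene zero fraction, in (0,1).
#' @return The filtered [count_matrix()].
#' @export
filter_genes <- function(cm, max_zero_rate = 0.95) {
  stopifnot(inherits(cm, "count_matrix"))
  if (max_zero_rate <= 0 || max_zero_rate >= 1) {
    stop("max_zero_rate must lie in (0, 1)")
  }
  n_cells <- ncol(cm$counts)
  zero_frac <- 1 - tabulate(cm$counts@i + 1L, nbins = nrow(cm$counts)) / n_cells
  keep <- zero_frac <= max_zero_rate
  if (!any(keep)) stop("gene filter removed every gene")
  subset_counts(cm, genes = keep)
}

#' Log-normalize counts
#'
#' Computes `log(c / L * scale + 1)` entrywise in the requested base,
#' where `L` is the cell library size. A zero count maps to exactly 0.
#'
#' @param cm A [count_matrix()] with positive library sizes.
#' @param scale Scale constant (default `1e4`).
#' @param base Logarithm base, 2 (default) or `exp(1)`.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (dense genes x cells matrix), cell metadata carried over from `cm`,
#'   `scale_factor`, `log_base` and `provenance` (`"raw"`).
#' @export
log_normalize <- function(cm, scale = 1e4, base = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$lib_size <= 0)) stop("every cell needs a positive library size")
  v <- as.matrix(cm$counts)
  v <- log1p(sweep(v, 2, cm$lib_size, "/") * scale) / log(base)
  obj <- list(
    values = v, gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
    batch = cm$batch, group = cm$group, lib_size = cm$lib_size,
    scale_factor = scale, log_base = base, provenance = "raw"
  )
  class(obj) <- "normalized_matrix"
  obj
}

#' Wrap an already-normalized (e.g. batch-corrected) matrix
#'
#' @param values Real genes x cells matrix on the log scale.
#' @param batch,group Per-cell labels.
#' @param scale_factor,log_base Normalization constants used upstream.
#' @return A `normalized_matrix` with `provenance = "corrected"`.
#' @export
normalized_matrix <- function(values, batch, group, scale_factor = 1e4,
                              log_base = 2) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("G%06d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("C%06d", seq_len(ncol(values)))
  obj <- list(
    values = values, gene_ids = rownames(values), cell_ids = colnames(values),
    batch = factor(as.character(batch)),
    group = factor(as.character(group), levels = c("control", "case")),
    lib_size = NULL, scale_factor = scale_factor, log_base = log_base,
    provenance = "corrected"
  )
  class(obj) <- "normalized_matrix"
  obj
}

#' Invert log-normalization
#'
#' Recovers integer counts from a `normalized_matrix` with
#' `provenance = "raw"`; exact round trip with [log_normalize()].
#'
#' @param norm A raw-provenance `normalized_matrix`.
#' @return Integer genes x cells matrix.
#' @export
invert_log_normalize <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!identical(norm$provenance, "raw")) {
    stop("round trip is only defined for raw-provenance matrices")
  }
  cnt <- (norm$log_base^norm$values - 1) / norm$scale_factor
  round(sweep(cnt, 2, norm$lib_size, "*"))
}

#' Estimate per-gene log fold change over nonzero cells
#'
#' For each gene, the mean of the log-normalized values over cells with a
#' nonzero value is computed separately in case and control cells, and
#' the difference (case minus control) is returned. Genes with no nonzero
#' cell in one group are flagged and carry a non-finite logFC.
#'
#' @param norm A `normalized_matrix`.
#' @param groups Factor of `"case"`/`"control"` labels (default: labels
#'   stored in `norm`).
#' @return Data frame of class `logfc_table` with columns `gene_id`,
#'   `logfc`, `n_nonzero_case`, `n_nonzero_control`, `flag` (one of `ok`,
#'   `case_all_zero`, `control_all_zero`, `both_zero`).
#' @export
estimate_logfc <- function(norm, groups = norm$group) {
  stopifnot(inherits(norm, "normalized_matrix"))
  groups <- factor(as.character(groups), levels = c("control", "case"))
  if (!any(groups == "case") || !any(groups == "control")) {
    stop("both groups must be nonempty")
  }
  v <- norm$values
  case <- groups == "case"
  nz <- v != 0
  n1 <- rowSums(nz[, case, drop = FALSE])
  n2 <- rowSums(nz[, !case, drop = FALSE])
  # zero entries contribute nothing to the sums, so plain row sums suffice
  s1 <- rowSums(v[, case, drop = FALSE])
  s2 <- rowSums(v[, !case, drop = FALSE])
  logfc <- s1 / n1 - s2 / n2
  flag <- rep("ok", nrow(v))
  flag[n1 == 0 & n2 > 0] <- "case_all_zero"
  flag[n2 == 0 & n1 > 0] <- "control_all_zero"
  flag[n1 == 0 & n2 == 0] <- "both_zero"
  out <- data.frame(
    gene_id = norm$gene_ids, logfc = logfc,
    n_nonzero_case = n1, n_nonzero_control = n2, flag = flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("logfc_table", "data.frame")
  out
}

#' Write a logFC table as TSV
#' @param tab A `logfc_table`.
#' @param path Output path.
#' @export
write_logfc <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
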