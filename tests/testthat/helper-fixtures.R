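# Small programmatic fixtures shared across test files.

# Dense-ish Poisson toy matrix with block batches and within-batch
# case/control labels.
toy_counts <- function(n_genes = 20, n_cells = 30, n_batches = 1,
                       ratio = 0.5, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda), n_genes)
  })
  sizes <- rep(n_cells %/% n_batches, n_batches)
  sizes[n_batches] <- n_cells - sum(sizes[-n_batches])
  batch <- rep(sprintf("b%d", seq_len(n_batches)), sizes)
  group <- unlist(lapply(sizes, function(nb) {
    k <- round(ratio * nb)
    c(rep("case", k), rep("control", nb - k))
  }))
  count_matrix(m, batch = batch, group = group)
}

# A de_result with prescribed p-values / signs, default unit logFC.
toy_result <- function(p, sign = rep(1L, length(p)), logfc = NULL,
                       gene_id = sprintf("G%06d", seq_along(p)),
                       method = "toy") {
  if (is.null(logfc)) logfc <- sign * 1
  de_result(gene_id, pvalue = p, logfc = logfc, sign = sign, method = method)
}

# Truth table over the same default gene ids.
toy_truth <- function(status, effect = NULL,
                      gene_id = sprintf("G%06d", seq_along(status))) {
  if (is.null(effect)) effect <- ifelse(status == "null", 1, 2)
  sim_truth(gene_id, status, effect, provenance = "toy")
}

# Brute-force BH step-up, the independent oracle for bh_adjust().
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q[o] <- pmin(adj, 1)
  q
}

# Direct weighted one-sided KS D+ on a ranked weight vector (no bridge).
weighted_ks_direct <- function(w) {
  Fx <- cumsum(w) / sum(w)
  Fy <- seq_along(w) / length(w)
  max(0, Fx - Fy)
}
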