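#' Parameters of the model-free (downsampling) DE simulator
#'
#' DE genes are spiked into a real or simulated count matrix by binomial
#' downsampling of positive counts in one group, with a per-gene success
#' probability drawn from a Beta distribution. With the default
#' `Beta(2, 2)` the median success probability is 1/2, i.e. a median fold
#' change of two.
#'
#' @param de_fraction Fraction of genes made differentially expressed
#'   (half downsampled in case = "down", half in control = "up"; an odd
#'   count gives the extra gene to "up").
#' @param beta_alpha,beta_beta Positive Beta shape parameters of the
#'   per-gene binomial success probability.
#' @param group_ratio Per-batch case fraction in (0,1); the standard
#'   benchmark presets are 0.2, 0.3, 0.4, 0.5.
#' @param seed Master integer seed.
#' @export
downsample_params <- function(de_fraction = 0.2, beta_alpha = 2,
                              beta_beta = 2, group_ratio = 0.5, seed = 1) {
  p <- list(
    de_fraction = de_fraction, beta_alpha = beta_alpha,
    beta_beta = beta_beta, group_ratio = group_ratio, seed = as.integer(seed)
  )
  if (p$de_fraction < 0 || p$de_fraction > 1) stop("de_fraction must lie in [0, 1]")
  if (p$beta_alpha <= 0 || p$beta_beta <= 0) stop("beta parameters must be positive")
  if (p$group_ratio <= 0 || p$group_ratio >= 1) stop("group_ratio must lie in (0, 1)")
  class(p) <- "downsample_params"
  p
}

#' Randomly split cells into case and control within each batch
#'
#' Within every batch, `round(ratio * n_cells_in_batch)` cells are drawn
#' (without replacement) as cases and the rest labelled controls.
#'
#' @param cm A [count_matrix()] (existing group labels are ignored).
#' @param ratio Case fraction in (0,1).
#' @param seed Integer seed; each batch uses an independent substream.
#' @return Factor of `"case"` / `"control"` labels along the cells.
#' @export
split_case_control <- function(cm, ratio, seed = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  labels <- rep("control", ncol(cm$counts))
  for (b in seq_along(levels(cm$batch))) {
    idx <- which(cm$batch == levels(cm$batch)[b])
    if (length(idx) < 2) {
      stop("batch '", levels(cm$batch)[b], "' has fewer than 2 cells")
    }
    n_case <- round(ratio * length(idx))
    pick <- with_substream(seed, "split", b,
      expr = sample(idx, n_case)
    )
    labels[pick] <- "case"
  }
  factor(labels, levels = c("control", "case"))
}

#' Select DE genes and draw their downsampling probabilities
#'
#' Two disjoint random gene sets are chosen, each holding half of
#' `round(de_fraction * n_genes)` genes (ties: extra gene to "up"). Genes
#' marked "down" are later downsampled in the case group, genes marked
#' "up" in the control group; every DE gene gets one Beta-distributed
#' success probability.
#'
#' @param gene_ids Character vector of (post-filter) gene ids.
#' @param params A [downsample_params()] object.
#' @return A [sim_truth()]; `effect` holds the success probability
#'   (1 for null genes).
#' @export
select_de_genes <- function(gene_ids, params) {
  stopifnot(inherits(params, "downsample_params"))
  n <- length(gene_ids)
  status <- rep("null", n)
  effect <- rep(1, n)
  n_de <- round(params$de_fraction * n)
  if (params$de_fraction > 0) {
    if (n_de < 2) stop("de_fraction x n_genes < 2: cannot form up and down sets")
    n_down <- floor(n_de / 2)
    n_up <- n_de - n_down
    idx <- with_substream(params$seed, "de_select",
      expr = sample.int(n, n_de)
    )
    p <- with_substream(params$seed, "de_factors",
      expr = stats::rbeta(n_de, params$beta_alpha, params$beta_beta)
    )
    status[idx[seq_len(n_up)]] <- "up"
    status[idx[n_up + seq_len(n_down)]] <- "down"
    effect[idx] <- p
  }
  sim_truth(gene_ids, status, effect, provenance = "downsample")
}

#' Downsample counts of DE genes by a binomial thinning
#'
#' For each DE gene with success probability `p`, every count `c` of that
#' gene in the targeted group ("down" genes: case cells; "up" genes:
#' control cells) is replaced by a `Binomial(c, p)` draw. All other
#' entries are returned unchanged; zeros stay zero.
#'
#' @param cm A [count_matrix()].
#' @param truth A [sim_truth()] whose genes are a subset of `cm`'s.
#' @param groups Factor of `"case"`/`"control"` labels along cells
#'   (default: the labels stored in `cm`).
#' @param seed Integer seed.
#' @return A new [count_matrix()] with recomputed library sizes and the
#'   given group labels attached.
#' @export
downsample_counts <- function(cm, truth, groups = cm$group, seed = 1) {
  stopifnot(inherits(cm, "count_matrix"), inherits(truth, "sim_truth"))
  if (!all(truth$gene_id %in% cm$gene_ids)) {
    stop("truth contains genes absent from the count matrix")
  }
  de <- truth[truth$status != "null", , drop = FALSE]
  if (any(de$effect <= 0 | de$effect > 1)) {
    stop("downsampling probabilities must lie in (0, 1]")
  }
  groups <- factor(as.character(groups), levels = c("control", "case"))
  counts <- as.matrix(cm$counts)
  case_cols <- which(groups == "case")
  ctrl_cols <- which(groups == "control")
  withr::with_seed(substream_seed(seed, "downsample"), {
    for (k in seq_len(nrow(de))) {
      g <- match(de$gene_id[k], cm$gene_ids)
      cols <- if (de$status[k] == "down") case_cols else ctrl_cols
      x <- counts[g, cols]
      pos <- x > 0
      if (any(pos)) {
        counts[g, cols[pos]] <- stats::rbinom(sum(pos), size = x[pos], prob = de$effect[k])
      }
    }
  })
  count_matrix(counts,
    batch = cm$batch, group = groups,
    gene_ids = cm$gene_ids, cell_ids = cm$cell_ids
  )
}

#' Run the full model-free simulation
#'
#' Filters sparsely expressed genes (zero rate > 0.95), splits each batch
#' into case and control at `params$group_ratio`, selects DE genes and
#' downsamples them.
#'
#' @param cm Source [count_matrix()] (real data or another simulation).
#' @param params A [downsample_params()] object.
#' @param max_zero_rate Gene filter threshold applied before DE selection.
#' @return A list with `counts` (downsampled [count_matrix()]) and
#'   `truth` (a [sim_truth()]).
#' @export
simulate_downsample <- function(cm, params, max_zero_rate = 0.95) {
  stopifnot(inherits(cm, "count_matrix"), inherits(params, "downsample_params"))
  cm <- filter_genes(cm, max_zero_rate)
  groups <- split_case_control(cm, params$group_ratio, seed = params$seed)
  truth <- select_de_genes(cm$gene_ids, params)
  out <- downsample_counts(cm, truth, groups, seed = params$seed)
  list(counts = out, truth = truth)
}
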