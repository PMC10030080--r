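#' Parameters of the model-based count simulator
#'
#' A splat-style generative model: baseline gene means are Gamma
#' distributed, library sizes and multiplicative batch / DE factors are
#' log-normal, counts are negative binomial with a common dispersion, and
#' technical zeros are injected by a mean-dependent logistic dropout.
#'
#' @param n_genes Number of simulated genes.
#' @param batch_sizes Integer vector of cells per batch.
#' @param group_ratios Per-batch case fraction in (0,1); recycled to the
#'   number of batches.
#' @param mean_shape,mean_rate Gamma shape / rate of baseline gene means.
#' @param libsize_loc,libsize_scale Log-normal meanlog / sdlog of cell
#'   library sizes.
#' @param batch_facLoc,batch_facScale Log-normal meanlog / sdlog of the
#'   per-(gene, batch) batch factors (both 0 disables batch effects).
#' @param de_prob Fraction of genes that are differentially expressed.
#' @param de_downProb Fraction of DE genes downregulated in the case group.
#' @param de_facLoc,de_facScale Log-normal meanlog / sdlog of DE factors.
#' @param dropout_mid,dropout_shape Midpoint (on the natural-log mean
#'   scale) and slope of the logistic dropout; `dropout_mid = -Inf` with
#'   negative shape disables dropout.
#' @param dispersion Common negative-binomial dispersion (`size` =
#'   1/dispersion).
#' @param seed Master integer seed; every stage and batch draws from an
#'   independent substream derived from it.
#' @return An object of class `splat_params`.
#' @seealso [splat_preset()] for calibrated sparsity/depth regimes.
#' @export
splat_params <- function(n_genes = 2000, batch_sizes = c(300, 750),
                         group_ratios = 0.5,
                         mean_shape = 0.6, mean_rate = 0.3,
                         libsize_loc = 11, libsize_scale = 0.2,
                         batch_facLoc = 0.4, batch_facScale = 0.4,
                         de_prob = 0.2, de_downProb = 0.5,
                         de_facLoc = 0.2, de_facScale = 0.2,
                         dropout_mid = 3.7, dropout_shape = -1,
                         dispersion = 0.1, seed = 1) {
  p <- list(
    n_genes = as.integer(n_genes), batch_sizes = as.integer(batch_sizes),
    group_ratios = rep_len(group_ratios, length(batch_sizes)),
    mean_shape = mean_shape, mean_rate = mean_rate,
    libsize_loc = libsize_loc, libsize_scale = libsize_scale,
    batch_facLoc = batch_facLoc, batch_facScale = batch_facScale,
    de_prob = de_prob, de_downProb = de_downProb,
    de_facLoc = de_facLoc, de_facScale = de_facScale,
    dropout_mid = dropout_mid, dropout_shape = dropout_shape,
    dispersion = dispersion, seed = as.integer(seed)
  )
  if (p$n_genes < 1) stop("n_genes must be positive")
  if (any(p$batch_sizes <= 0)) stop("batch sizes must be positive")
  if (any(p$group_ratios <= 0 | p$group_ratios >= 1)) {
    stop("group_ratios must lie in (0, 1)")
  }
  for (nm in c("mean_shape", "mean_rate", "dispersion")) {
    if (p[[nm]] <= 0) stop(nm, " must be strictly positive")
  }
  for (nm in c("libsize_scale", "batch_facScale", "de_facScale")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  for (nm in c("de_prob", "de_downProb")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  class(p) <- "splat_params"
  p
}

# Calibrated (libsize_loc, dispersion) pairs per preset at 1000 genes.
# Depth-77/10/4 target the average nonzero count after gene filtering;
# sparse80/sparse40 target overall zero rates above 80% / near 40%.
.splat_presets <- list(
  "sparse80-depth77" = list(dropout_mid = 3.7, libsize_loc = 9.9, dispersion = 8),
  "sparse80-depth10" = list(dropout_mid = 3.7, libsize_loc = 8.0, dispersion = 0.1),
  "sparse80-depth4"  = list(dropout_mid = 3.7, libsize_loc = 6.8, dispersion = 0.1),
  "sparse40-depth77" = list(dropout_mid = 0.05, libsize_loc = 10.7, dispersion = 4),
  "sparse40-depth4"  = list(dropout_mid = 0.05, libsize_loc = 7.8, dispersion = 0.1)
)

#' Calibrated simulation presets
#'
#' Returns [splat_params()] tuned so that, after the standard gene filter
#' (zero rate > 0.95), the overall zero rate and the mean nonzero count
#' match the named sparsity/depth regime. The calibrated library-size
#' location is shifted by `log(n_genes / 1000)` so the per-entry depth is
#' independent of the simulated gene count.
#'
#' @param name One of `"sparse80-depth77"`, `"sparse80-depth10"`,
#'   `"sparse80-depth4"`, `"sparse40-depth77"`, `"sparse40-depth4"`.
#' @param n_genes,batch_sizes,group_ratios,seed Passed to [splat_params()].
#' @param ... Further overrides passed to [splat_params()].
#' @export
splat_preset <- function(name, n_genes = 1000, batch_sizes = c(300, 750),
                         group_ratios = 0.5, seed = 1, ...) {
  name <- match.arg(name, names(.splat_presets))
  pre <- .splat_presets[[name]]
  splat_params(
    n_genes = n_genes, batch_sizes = batch_sizes,
    group_ratios = group_ratios, seed = seed,
    dropout_mid = pre$dropout_mid,
    libsize_loc = pre$libsize_loc + log(n_genes / 1000),
    dispersion = pre$dispersion, ...
  )
}

#' Draw multiplicative log-normal factors
#'
#' @param loc Meanlog of the factor distribution.
#' @param scale Sdlog, `>= 0`; a zero scale gives the degenerate value
#'   `exp(loc)` for every factor.
#' @param n Number of factors.
#' @return `n` strictly positive factors.
#' @export
draw_lognormal_factors <- function(loc, scale, n) {
  if (n <= 0) stop("n must be positive")
  if (scale < 0) stop("scale must be >= 0")
  if (scale == 0) rep(exp(loc), n) else stats::rlnorm(n, loc, scale)
}

#' Logistic dropout mask
#'
#' Each entry of a positive mean matrix is dropped independently with
#' probability `plogis(shape * (log(mu) - mid))`, i.e. the logistic
#' function of the natural-log mean. With the conventional negative
#' shape, larger midpoints drop more entries and `mid = -Inf` drops none.
#'
#' @param means Matrix of strictly positive expected counts.
#' @param mid Dropout midpoint on the log-mean scale.
#' @param shape Logistic slope (negative for mean-decreasing dropout).
#' @return Logical matrix; `TRUE` marks entries to zero out.
#' @export
logistic_dropout <- function(means, mid, shape = -1) {
  if (any(means <= 0)) stop("means must be strictly positive")
  prob <- stats::plogis(shape * (log(means) - mid))
  mask <- matrix(stats::runif(length(means)) < prob, nrow = nrow(means))
  dimnames(mask) <- dimnames(means)
  mask
}

#' Simulate multi-batch scRNA-seq counts with known DE truth
#'
#' Generates counts for `sum(batch_sizes)` cells. Baseline gene means are
#' Gamma draws; a per-(gene, batch) log-normal batch factor and, for case
#' cells of DE genes, a log-normal DE factor multiply the baseline; each
#' cell's means are rescaled to its log-normal library size; counts are
#' negative binomial with the configured dispersion and then zeroed by the
#' logistic dropout mask. DE factors are folded above 1 so that the truth
#' label always states the true direction: "up" genes are multiplied by
#' `f > 1` in case cells, "down" genes by `1/f`.
#'
#' Cells are ordered batch-major with case cells before control cells
#' within each batch; ids are `G%06d` / `C%06d`.
#'
#' @param params A [splat_params()] object.
#' @param keep_means Keep the expected-count matrix (before NB sampling
#'   and dropout) in the result, for diagnostics.
#' @return A list with elements `counts` (a [count_matrix()]), `truth`
#'   (a [sim_truth()]) and, if requested, `means`.
#' @export
simulate_counts <- function(params, keep_means = FALSE) {
  stopifnot(inherits(params, "splat_params"))
  p <- params
  n_batches <- length(p$batch_sizes)
  n_cells <- sum(p$batch_sizes)

  gene_means <- with_substream(
    p$seed, "means",
    expr = stats::rgamma(p$n_genes, shape = p$mean_shape, rate = p$mean_rate)
  )

  # DE gene selection and factors
  n_de <- round(p$de_prob * p$n_genes)
  if (p$de_prob > 0 && n_de == 0) {
    warning("de_prob > 0 but rounds to zero DE genes")
  }
  status <- rep("null", p$n_genes)
  effect <- rep(1, p$n_genes)
  if (n_de > 0) {
    n_down <- floor(n_de * p$de_downProb)
    n_up <- n_de - n_down
    de_idx <- with_substream(p$seed, "de_select",
      expr = sample.int(p$n_genes, n_de)
    )
    up_idx <- de_idx[seq_len(n_up)]
    down_idx <- de_idx[setdiff(seq_len(n_de), seq_len(n_up))]
    f <- with_substream(p$seed, "de_factors",
      expr = draw_lognormal_factors(p$de_facLoc, p$de_facScale, n_de)
    )
    f <- pmax(f, 1 / f) # fold below-1 draws so labels state true direction
    status[up_idx] <- "up"
    status[down_idx] <- "down"
    effect[up_idx] <- f[seq_len(n_up)]
    effect[down_idx] <- 1 / f[setdiff(seq_len(n_de), seq_len(n_up))]
  }

  counts <- matrix(0L, p$n_genes, n_cells)
  batch_lab <- character(n_cells)
  group_lab <- character(n_cells)
  mean_store <- if (keep_means) matrix(0, p$n_genes, n_cells) else NULL

  col_off <- 0L
  for (b in seq_len(n_batches)) {
    nb <- p$batch_sizes[b]
    cols <- col_off + seq_len(nb)
    n_case <- round(p$group_ratios[b] * nb)
    grp <- c(rep("case", n_case), rep("control", nb - n_case))

    bfac <- with_substream(p$seed, "batch_factors", b,
      expr = draw_lognormal_factors(p$batch_facLoc, p$batch_facScale, p$n_genes)
    )
    lib <- with_substream(p$seed, "libsize", b,
      expr = stats::rlnorm(nb, p$libsize_loc, p$libsize_scale)
    )

    base <- gene_means * bfac
    mean_case <- base * effect
    # per-cell means scaled so expected totals match the library size
    mu <- matrix(0, p$n_genes, nb)
    case_cols <- grp == "case"
    if (any(case_cols)) {
      mu[, case_cols] <- outer(mean_case / sum(mean_case), lib[case_cols])
    }
    if (any(!case_cols)) {
      mu[, !case_cols] <- outer(base / sum(base), lib[!case_cols])
    }

    cnt <- with_substream(p$seed, "counts", b, expr = {
      matrix(
        stats::rnbinom(length(mu), mu = mu, size = 1 / p$dispersion),
        nrow = p$n_genes
      )
    })
    drop <- with_substream(p$seed, "dropout", b,
      expr = logistic_dropout(mu, p$dropout_mid, p$dropout_shape)
    )
    cnt[drop] <- 0L
    counts[, cols] <- cnt
    batch_lab[cols] <- sprintf("batch%d", b)
    group_lab[cols] <- grp
    if (keep_means) mean_store[, cols] <- mu
    col_off <- col_off + nb
  }

  gene_ids <- sprintf("G%06d", seq_len(p$n_genes))
  cell_ids <- sprintf("C%06d", seq_len(n_cells))
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  cm <- count_matrix(counts, batch = batch_lab, group = group_lab)
  truth <- sim_truth(gene_ids, status, effect, provenance = "splat")
  out <- list(counts = cm, truth = truth)
  if (keep_means) {
    dimnames(mean_store) <- dimnames(counts)
    out$means <- mean_store
  }
  out
}
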