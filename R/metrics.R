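#' Metric configuration
#'
#' @param f_beta Beta of the F-score (default 0.5: precision weighted
#'   twice as high as recall).
#' @param paupr_T Recall truncation of the partial AUPR, in (0,1\].
#' @param q_threshold q-value cutoff declaring a gene DE.
#' @param top_fraction Top rank fraction for the truncated KS test and
#'   the cumulative-score pAUC.
#' @param n_permutations Permutations of the truncated KS null.
#' @param logfc_threshold Optional additional `|logFC|` cutoff on
#'   detections (0 disables).
#' @export
metric_config <- function(f_beta = 0.5, paupr_T = 0.5, q_threshold = 0.05,
                          top_fraction = 0.2, n_permutations = 10000,
                          logfc_threshold = 0) {
  stopifnot(
    f_beta > 0, paupr_T > 0, paupr_T <= 1,
    q_threshold > 0, q_threshold < 1,
    top_fraction > 0, top_fraction <= 1,
    n_permutations >= 1, logfc_threshold >= 0
  )
  structure(
    list(
      f_beta = f_beta, paupr_T = paupr_T, q_threshold = q_threshold,
      top_fraction = top_fraction, n_permutations = n_permutations,
      logfc_threshold = logfc_threshold
    ),
    class = "metric_config"
  )
}

#' Precision/recall F-score
#'
#' `(1 + beta^2) P R / (beta^2 P + R)`, with value 0 when both precision
#' and recall are 0. `beta < 1` weighs precision higher.
#'
#' @param precision,recall Values in \[0, 1\] (vectorized).
#' @param beta Positive weight.
#' @export
f_beta <- function(precision, recall, beta = 0.5) {
  stopifnot(beta > 0, all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, num / den)
}

# Canonical ranking of a DE result: p ascending, ties broken by larger
# |signed score| then lexicographic gene id. Every rank-based metric in
# the package uses this order.
rank_de <- function(result) {
  ss <- signed_score(result)
  order(result$pvalue, -abs(ss), result$gene_id)
}

#' Precision-recall curve for one DE direction
#'
#' Genes are ranked by p-value (ties: larger absolute signed score, then
#' gene id). Walking down the ranking, a gene counts as a true positive
#' only if it is a truth gene of the requested direction *and* its
#' declared sign matches that direction.
#'
#' @param result A `de_result`.
#' @param truth A [sim_truth()] with at least one gene of `direction`.
#' @param direction `"up"` or `"down"`.
#' @param q_threshold The curve's attribute `q_point` records the
#'   (recall, precision) pair at the last rank with `qvalue <
#'   q_threshold`.
#' @return Data frame (class `pr_curve`) with columns `rank`, `gene_id`,
#'   `recall`, `precision`, `qvalue`.
#' @export
pr_curve <- function(result, truth, direction = c("up", "down"),
                     q_threshold = 0.05) {
  stopifnot(inherits(result, "de_result"), inherits(truth, "sim_truth"))
  direction <- match.arg(direction)
  want_sign <- if (direction == "up") 1L else -1L
  pos <- truth$gene_id[truth$status == direction]
  if (!length(pos)) stop("truth holds no '", direction, "' gene")
  ord <- rank_de(result)
  r <- result[ord, ]
  tp <- cumsum(r$gene_id %in% pos & r$sign == want_sign)
  out <- data.frame(
    rank = seq_len(nrow(r)), gene_id = r$gene_id,
    recall = tp / length(pos), precision = tp / seq_len(nrow(r)),
    qvalue = r$qvalue, stringsAsFactors = FALSE
  )
  sig <- which(r$qvalue < q_threshold)
  attr(out, "q_point") <- if (length(sig)) {
    c(recall = out$recall[max(sig)], precision = out$precision[max(sig)])
  } else {
    c(recall = 0, precision = NA_real_)
  }
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Partial area under the precision-recall curve
#'
#' `(1/T) * integral_0^T precision d(recall)`, integrating precision as a
#' step function of recall: the segment of recall `(r_(k-1), r_k]`
#' carries the precision observed at the rank where the k-th true
#' positive is found.
#'
#' @param curve A [pr_curve()].
#' @param T Recall truncation in (0,1\].
#' @export
paupr <- function(curve, T = 0.5) {
  stopifnot(inherits(curve, "pr_curve"), T > 0, T <= 1)
  jump <- which(c(curve$recall[1] > 0, diff(curve$recall) > 0))
  r <- curve$recall[jump]
  p <- curve$precision[jump]
  r_prev <- c(0, r[-length(r)])
  seg <- pmin(r, T) - pmin(r_prev, T)
  sum(p * seg) / T
}

#' Sign error ratio of DE genes
#'
#' Percentage of truth DE genes whose declared sign contradicts the true
#' direction. `scope = "detected"` restricts to genes with `qvalue <
#' q_threshold`; genes with a non-finite logFC are excluded from both
#' numerator and denominator.
#'
#' @param result A `de_result`.
#' @param truth A [sim_truth()] with at least one DE gene.
#' @param scope `"all_de"` or `"detected"`.
#' @param q_threshold Detection cutoff.
#' @return Percentage in \[0, 100\], or `NA` when the scope is empty.
#' @export
error_ratio <- function(result, truth, scope = c("all_de", "detected"),
                        q_threshold = 0.05) {
  stopifnot(inherits(result, "de_result"), inherits(truth, "sim_truth"))
  scope <- match.arg(scope)
  de <- truth[truth$status != "null", , drop = FALSE]
  if (!nrow(de)) stop("truth holds no DE gene")
  m <- match(de$gene_id, result$gene_id)
  keep <- !is.na(m) & is.finite(result$logfc[m])
  de <- de[keep, , drop = FALSE]
  m <- m[keep]
  if (scope == "detected") {
    sel <- result$qvalue[m] < q_threshold
    de <- de[sel, , drop = FALSE]
    m <- m[sel]
  }
  if (!nrow(de)) return(NA_real_)
  true_sign <- ifelse(de$status == "up", 1L, -1L)
  100 * sum(result$sign[m] != true_sign) / nrow(de)
}

#' Angular logFC distortion
#'
#' Mean, over DE genes, of the cosine-angle distance between the point
#' `(logFC_raw, logFC_corrected)` and the identity line `y = x`:
#' `1 - sign(logFC_raw) * <(1,1), v> / (sqrt(2) * ||v||)`. Points with a
#' non-finite coordinate are dropped (and counted); exact-zero-norm
#' points are excluded and counted separately.
#'
#' @param logfc_raw,logfc_corrected `logfc_table`s (or data frames with
#'   `gene_id` and `logfc`) before and after correction.
#' @param de_genes Optional gene ids to restrict to (default: all genes
#'   shared by both tables).
#' @return Mean distortion in \[0, 2\], with attributes `n_used` and
#'   `n_dropped`.
#' @export
distortion <- function(logfc_raw, logfc_corrected, de_genes = NULL) {
  if (is.null(de_genes)) {
    de_genes <- intersect(logfc_raw$gene_id, logfc_corrected$gene_id)
  }
  x <- logfc_raw$logfc[match(de_genes, logfc_raw$gene_id)]
  y <- logfc_corrected$logfc[match(de_genes, logfc_corrected$gene_id)]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  nz <- !(x == 0 & y == 0)
  x <- x[nz]
  y <- y[nz]
  if (!length(x)) stop("no usable gene pair")
  d <- 1 - sign(x) * (x + y) / (sqrt(2) * sqrt(x^2 + y^2))
  out <- mean(d)
  attr(out, "n_used") <- length(x)
  attr(out, "n_dropped") <- length(de_genes) - length(x)
  out
}

#' Cumulative weighted score of standard positives along a DE ranking
#'
#' Genes are ranked by p-value; the curve value at rank `u` is the sum of
#' standard-positive weights among the top `u` genes, normalized by the
#' total weight.
#'
#' @param result A `de_result`.
#' @param positives Named weight vector (see [read_gene_set()]); genes
#'   absent from the ranking contribute no weight.
#' @return Data frame (class `cumscore_curve`) with `rank`, `gene_id`,
#'   `cum_score`; the aligned weights are kept as attribute `w`.
#' @export
cumulative_score_curve <- function(result, positives) {
  stopifnot(inherits(result, "de_result"))
  w_all <- stats::setNames(rep(0, nrow(result)), result$gene_id)
  hit <- intersect(names(positives), result$gene_id)
  if (!length(hit) || !any(positives[hit] > 0)) {
    stop("no positive-weight gene overlaps the ranking")
  }
  w_all[hit] <- positives[hit]
  ord <- rank_de(result)
  w <- unname(w_all[result$gene_id[ord]])
  out <- data.frame(
    rank = seq_along(w), gene_id = result$gene_id[ord],
    cum_score = cumsum(w) / sum(w), stringsAsFactors = FALSE
  )
  attr(out, "w") <- w
  class(out) <- c("cumscore_curve", "data.frame")
  out
}

#' Partial area under the cumulative score curve
#'
#' Area of the curve over ranks `1 .. floor(top_fraction * u_max)`,
#' normalized by the area of the ideal curve (all weight concentrated at
#' the top ranks in decreasing order) over the same span, so a maximal
#' ranking scores 1.
#'
#' @param curve A [cumulative_score_curve()].
#' @param top_fraction Rank fraction in (0,1\].
#' @export
pauc <- function(curve, top_fraction = 0.2) {
  stopifnot(inherits(curve, "cumscore_curve"))
  u_max <- nrow(curve)
  K <- max(1L, floor(top_fraction * u_max))
  w <- attr(curve, "w")
  ideal <- cumsum(sort(w, decreasing = TRUE)) / sum(w)
  sum(curve$cum_score[seq_len(K)]) / sum(ideal[seq_len(K)])
}

#' Truncated weighted Kolmogorov-Smirnov test
#'
#' One-sided weighted KS test of whether standard-positive genes sit at
#' high DE ranks, with the maximum discrepancy confined to the top
#' `top_fraction` of ranks: beyond rank `N = floor(top_fraction *
#' u_max)` the empirical cdf is replaced by the linear bridge from
#' `F_x(N)` to 1, so positives in the tail cannot contribute. The
#' statistic is `D+ = max_u(F~_x(u) - u/u_max)`; its right-tailed
#' p-value is computed by permuting which genes carry the weight
#' multiset, with add-one correction `(b + 1) / (m + 1)`.
#'
#' @param result A `de_result`.
#' @param positives Named nonnegative weight vector.
#' @param top_fraction Rank fraction in (0,1\]; 1 disables the bridge and
#'   recovers the classic weighted one-sided KS statistic.
#' @param n_permutations Number of permutations.
#' @param seed Optional seed for the permutation stream.
#' @return List of class `ks_result`: `statistic`, `p_value`, `F_x`
#'   (empirical cdf over ranks), `F_y` (null cdf), `N`, `u_max`,
#'   `n_permutations`.
#' @export
truncated_ks_test <- function(result, positives, top_fraction = 0.2,
                              n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(result, "de_result"), top_fraction > 0, top_fraction <= 1)
  w_all <- stats::setNames(rep(0, nrow(result)), result$gene_id)
  hit <- intersect(names(positives), result$gene_id)
  w_all[hit] <- positives[hit]
  if (!any(w_all > 0)) stop("all weights are zero on the ranking")
  ord <- rank_de(result)
  w <- unname(w_all[result$gene_id[ord]])
  u_max <- length(w)
  N <- floor(top_fraction * u_max)
  if (N < 1) stop("top_fraction leaves no rank (N < 1)")
  W <- sum(w)
  Fx <- cumsum(w) / W
  Fy <- seq_len(u_max) / u_max
  Fx_t <- Fx
  if (N < u_max) {
    u <- seq(N, u_max)
    Fx_t[u] <- Fx[N] + (u - N) / (u_max - N) * (1 - Fx[N])
  }
  D_obs <- max(0, Fx_t - Fy)

  # permutation null: weight multiset scattered over random ranks; the
  # statistic's maximum can only occur at a jump (rank of a positive)
  # strictly below N or at N itself, so only those points are evaluated.
  pos_idx <- which(w > 0)
  wpos <- w[pos_idx]
  k <- length(pos_idx)
  perm_stat <- function(pos, wp) {
    o <- order(pos)
    pos <- pos[o]
    cw <- cumsum(wp[o]) / W
    below <- pos < N
    FxN <- if (any(pos <= N)) max(cw[pos <= N]) else 0
    max(0, cw[below] - pos[below] / u_max, FxN - N / u_max)
  }
  run <- function() {
    d <- numeric(n_permutations)
    for (j in seq_len(n_permutations)) {
      d[j] <- perm_stat(sample.int(u_max, k), sample(wpos))
    }
    d
  }
  d_null <- if (is.null(seed)) run() else with_substream(seed, "permute", 0L, run())
  p <- (1 + sum(d_null >= D_obs)) / (n_permutations + 1)
  structure(
    list(
      statistic = D_obs, p_value = p, F_x = Fx_t, F_y = Fy,
      N = N, u_max = u_max, n_permutations = n_permutations
    ),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "truncated weighted KS: D+ = %.4f, p = %.4g (N = %d of %d ranks, %d permutations)\n",
    x$statistic, x$p_value, x$N, x$u_max, x$n_permutations
  ))
  invisible(x)
}

#' Count false positives and false discoveries on a null design
#'
#' For a result computed on data with no injected DE (random
#' within-sample splits), counts genes with `pvalue < 0.05` (false
#' positives) and `qvalue < 0.05` (false discoveries), plus the 5%-of-
#' genes reference value.
#'
#' @param result A `de_result`.
#' @param p_threshold,q_threshold Cutoffs (defaults 0.05).
#' @return Named vector `n_p`, `n_q`, `reference`.
#' @export
count_false_calls <- function(result, p_threshold = 0.05, q_threshold = 0.05) {
  stopifnot(inherits(result, "de_result"))
  c(
    n_p = sum(result$pvalue < p_threshold, na.rm = TRUE),
    n_q = sum(result$qvalue < q_threshold, na.rm = TRUE),
    reference = p_threshold * nrow(result)
  )
}

#' Spearman rank similarity of two workflows
#'
#' Spearman correlation of two per-gene signed-score vectors on their
#' common gene universe.
#'
#' @param scores_a,scores_b Named numeric vectors (see [signed_score()]).
#' @export
rank_similarity <- function(scores_a, scores_b) {
  common <- intersect(names(scores_a), names(scores_b))
  if (length(common) < 3) stop("need at least 3 common genes")
  stats::cor(scores_a[common], scores_b[common], method = "spearman")
}

#' Evaluate one workflow against truth and/or a weighted gene set
#'
#' Convenience wrapper assembling the package's metric report: F-beta
#' and pAUPR per direction and sign error ratios when simulation truth is
#' given; cumulative-score pAUC and truncated KS when a weighted gene set
#' is given; false-call counts when the design is declared null.
#'
#' @param result A `de_result`.
#' @param truth Optional [sim_truth()].
#' @param geneset Optional named weight vector.
#' @param config A [metric_config()].
#' @param null_design The result comes from a no-DE split.
#' @param seed Seed for the KS permutations.
#' @return One-row data frame of class `metric_report`.
#' @export
evaluate_workflow <- function(result, truth = NULL, geneset = NULL,
                              config = metric_config(), null_design = FALSE,
                              seed = NULL) {
  stopifnot(inherits(result, "de_result"))
  row <- data.frame(method = attr(result, "method") %||% "unknown")
  if (!is.null(truth)) {
    for (dir in c("up", "down")) {
      want <- if (dir == "up") 1L else -1L
      det <- result$qvalue < config$q_threshold & result$sign == want
      if (config$logfc_threshold > 0) {
        det <- det & abs(result$logfc) > config$logfc_threshold
      }
      det[is.na(det)] <- FALSE
      pos <- truth$gene_id[truth$status == dir]
      tp <- sum(result$gene_id[det] %in% pos)
      prec <- if (sum(det)) tp / sum(det) else 0
      rec <- if (length(pos)) tp / length(pos) else 0
      row[[paste0("f", sub("\\.", "", config$f_beta), "_", dir)]] <-
        f_beta(prec, rec, config$f_beta)
      row[[paste0("paupr_", dir)]] <-
        paupr(pr_curve(result, truth, dir, config$q_threshold), config$paupr_T)
    }
    row$error_ratio_all <- error_ratio(result, truth, "all_de", config$q_threshold)
    row$error_ratio_detected <-
      error_ratio(result, truth, "detected", config$q_threshold)
  }
  if (!is.null(geneset)) {
    cur <- cumulative_score_curve(result, geneset)
    row$pauc <- pauc(cur, config$top_fraction)
    ks <- truncated_ks_test(result, geneset,
      top_fraction = config$top_fraction,
      n_permutations = config$n_permutations, seed = seed
    )
    row$ks_statistic <- ks$statistic
    row$ks_p <- ks$p_value
  }
  if (null_design) {
    fc <- count_false_calls(result)
    row$false_positive_count <- fc[["n_p"]]
    row$false_discovery_count <- fc[["n_q"]]
  }
  class(row) <- c("metric_report", "data.frame")
  row
}

`%||%` <- function(a, b) if (is.null(a)) b else a
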