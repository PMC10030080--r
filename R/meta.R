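#' Configuration of per-batch meta-analysis combination
#'
#' @param combiner `"weighted_fisher"` (Lancaster-style combination of
#'   one-sided p-values with batch-size weights), `"fixed_effects"`
#'   (inverse-variance pooling of per-batch logFC) or `"random_effects"`
#'   (DerSimonian-Laird).
#' @param weights Optional positive per-batch weights; default: the batch
#'   cell counts recorded on each per-batch result, falling back to equal
#'   weights.
#' @export
meta_config <- function(combiner = c("weighted_fisher", "fixed_effects",
                                     "random_effects"),
                        weights = NULL) {
  combiner <- match.arg(combiner)
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be positive")
  structure(list(combiner = combiner, weights = weights),
    class = "meta_config"
  )
}

#' Run a DE engine independently within each batch
#'
#' Splits a count matrix by batch, re-applies the gene filter within each
#' batch and runs the requested engine, producing one `de_result` per
#' batch for [meta_combine()]. The `"lognorm_t"` engine (a per-gene Welch
#' t-test on log-normalized values, all cells) additionally reports the
#' effect standard error required by the effect-size combiners.
#'
#' @param cm A [count_matrix()].
#' @param engine `"wilcoxon"` (p-values and signs; pair with the
#'   weighted-Fisher combiner) or `"lognorm_t"`.
#' @param max_zero_rate Per-batch gene filter threshold.
#' @return Named list of `de_result`, one per batch, each carrying an
#'   `n_cells` attribute used as the default combination weight.
#' @export
per_batch_de <- function(cm, engine = c("wilcoxon", "lognorm_t"),
                         max_zero_rate = 0.95) {
  stopifnot(inherits(cm, "count_matrix"))
  engine <- match.arg(engine)
  out <- list()
  for (b in levels(cm$batch)) {
    sub <- subset_counts(cm, cells = cm$batch == b)
    sub <- filter_genes(sub, max_zero_rate)
    res <- switch(engine,
      wilcoxon = wilcoxon_de(log_normalize(sub)),
      lognorm_t = lognorm_t_de(log_normalize(sub))
    )
    attr(res, "n_cells") <- ncol(sub$counts)
    out[[b]] <- res
  }
  out
}

#' Per-gene two-sample t-test on log-normalized values
#'
#' Welch t-test per gene over all cells (zeros included), reporting the
#' mean difference as logFC together with its standard error; the
#' per-batch engine behind the fixed/random-effects combiners.
#'
#' @param norm A `normalized_matrix`.
#' @param groups Case/control factor.
#' @return A `de_result` with an `se` column (method `"lognorm_t"`).
#' @export
lognorm_t_de <- function(norm, groups = norm$group) {
  stopifnot(inherits(norm, "normalized_matrix"))
  groups <- factor(as.character(groups), levels = c("control", "case"))
  case <- groups == "case"
  n1 <- sum(case)
  n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 cells")
  v <- norm$values
  m1 <- rowMeans(v[, case, drop = FALSE])
  m2 <- rowMeans(v[, !case, drop = FALSE])
  s1 <- apply(v[, case, drop = FALSE], 1, stats::var) / n1
  s2 <- apply(v[, !case, drop = FALSE], 1, stats::var) / n2
  se <- sqrt(s1 + s2)
  t <- (m1 - m2) / se
  df <- (s1 + s2)^2 / (s1^2 / (n1 - 1) + s2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  de_result(norm$gene_ids,
    pvalue = p, logfc = m1 - m2, se = se,
    method = "lognorm_t"
  )
}

#' Combine per-batch DE results by meta-analysis
#'
#' The gene universe is the union of the per-batch gene sets; each gene
#' is combined over the batches where it was tested, with weights
#' renormalized over those batches.
#'
#' `weighted_fisher` combines one-sided p-values in both tail directions
#' with batch-size weights via the Lancaster gamma reparameterization
#' (weights scaled so the total degrees of freedom equal `2K` for `K`
#' contributing batches; equal weights reduce to Fisher's method), takes
#' the smaller of the two combined tails, doubles it (capped at 1) and
#' sets the sign to the direction of the smaller tail. `fixed_effects`
#' pools per-batch logFC by inverse variance; `random_effects` adds a
#' DerSimonian-Laird between-batch variance. Both report a Wald p-value
#' on the pooled effect. BH correction is applied to the combined
#' p-values.
#'
#' @param per_batch List of per-batch `de_result` tables (the effect-size
#'   combiners require an `se` column).
#' @param config A [meta_config()].
#' @return A `de_result` (method `"meta-wfisher"`, `"meta-fem"` or
#'   `"meta-rem"`).
#' @export
meta_combine <- function(per_batch, config = meta_config()) {
  stopifnot(inherits(config, "meta_config"), length(per_batch) >= 1)
  K_all <- length(per_batch)
  w_all <- config$weights
  if (is.null(w_all)) {
    w_all <- vapply(per_batch, function(r) {
      n <- attr(r, "n_cells")
      if (is.null(n)) 1 else as.numeric(n)
    }, numeric(1))
  }
  if (length(w_all) != K_all) stop("need one weight per batch")
  if (any(w_all <= 0)) stop("weights must be positive")
  genes <- sort(unique(unlist(lapply(per_batch, `[[`, "gene_id"))))
  n <- length(genes)
  idx <- lapply(per_batch, function(r) match(genes, r$gene_id))
  p_mat <- lfc_mat <- se_mat <- sgn_mat <- matrix(NA_real_, n, K_all)
  for (k in seq_len(K_all)) {
    r <- per_batch[[k]]
    p_mat[, k] <- r$pvalue[idx[[k]]]
    lfc_mat[, k] <- r$logfc[idx[[k]]]
    sgn_mat[, k] <- r$sign[idx[[k]]]
    if (!is.null(r$se)) se_mat[, k] <- r$se[idx[[k]]]
  }

  if (config$combiner == "weighted_fisher") {
    pv <- lfc <- numeric(n)
    sg <- integer(n)
    for (i in seq_len(n)) {
      ok <- which(!is.na(p_mat[i, ]))
      K <- length(ok)
      p <- pmin(pmax(p_mat[i, ok], 1e-300), 1)
      s <- sgn_mat[i, ok]
      p_right <- ifelse(s >= 0, p / 2, 1 - p / 2)
      p_left <- 1 - p_right
      w <- w_all[ok] / sum(w_all[ok]) * 2 * K # total df 2K
      Tr <- sum(stats::qgamma(pmin(pmax(p_right, 1e-300), 1 - 1e-16),
        shape = w / 2, scale = 2, lower.tail = FALSE
      ))
      Tl <- sum(stats::qgamma(pmin(pmax(p_left, 1e-300), 1 - 1e-16),
        shape = w / 2, scale = 2, lower.tail = FALSE
      ))
      pr <- stats::pchisq(Tr, df = 2 * K, lower.tail = FALSE)
      pl <- stats::pchisq(Tl, df = 2 * K, lower.tail = FALSE)
      pv[i] <- min(1, 2 * min(pr, pl))
      sg[i] <- if (pr < pl) 1L else if (pl < pr) -1L else 0L
      lfc[i] <- sum(w_all[ok] * lfc_mat[i, ok]) / sum(w_all[ok])
    }
    return(de_result(genes,
      pvalue = pv, logfc = lfc, sign = sg,
      method = "meta-wfisher"
    ))
  }

  if (all(is.na(se_mat))) {
    stop("effect-size combiners need per-batch standard errors (se column)")
  }
  est <- se_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok <- which(is.finite(se_mat[i, ]) & se_mat[i, ] > 0 &
                  is.finite(lfc_mat[i, ]))
    if (!length(ok)) next
    y <- lfc_mat[i, ok]
    vi <- se_mat[i, ok]^2
    wi <- 1 / vi
    mu_f <- sum(wi * y) / sum(wi)
    if (config$combiner == "random_effects" && length(ok) > 1) {
      Q <- sum(wi * (y - mu_f)^2)
      tau2 <- max(0, (Q - (length(ok) - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
      wi <- 1 / (vi + tau2)
    }
    est[i] <- sum(wi * y) / sum(wi)
    se_p[i] <- sqrt(1 / sum(wi))
  }
  pv <- 2 * stats::pnorm(-abs(est / se_p))
  pv[is.na(pv)] <- 1
  est[is.na(est)] <- 0
  method <- if (config$combiner == "fixed_effects") "meta-fem" else "meta-rem"
  de_result(genes, pvalue = pv, logfc = est, se = se_p, method = method)
}
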