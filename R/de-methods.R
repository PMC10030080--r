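#' Assemble a DE result table
#'
#' The common per-gene output schema of every native DE procedure and of
#' the external-result adapter: p-value, BH q-value, log2 fold change,
#' declared sign and (optionally) a standard error of the effect.
#'
#' @param gene_id Gene identifiers.
#' @param pvalue P-values in \[0, 1\].
#' @param logfc Log2 fold changes (case over control).
#' @param method Method label.
#' @param sign Declared direction; default `sign(logfc)`.
#' @param qvalue BH-adjusted p-values; recomputed when `NULL`.
#' @param se Optional standard errors of `logfc`.
#' @return Data frame of class `de_result` with attribute `method` and
#'   `n_genes_tested`.
#' @export
de_result <- function(gene_id, pvalue, logfc, method, sign = NULL,
                      qvalue = NULL, se = NULL) {
  if (any(pvalue < 0 | pvalue > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  if (is.null(sign)) sign <- sign(logfc)
  sign[!is.finite(sign)] <- 0
  if (is.null(qvalue)) qvalue <- bh_adjust(pvalue)
  out <- data.frame(
    gene_id = as.character(gene_id), logfc = logfc, pvalue = pvalue,
    qvalue = qvalue, sign = as.integer(sign),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(se)) out$se <- se
  attr(out, "method") <- method
  attr(out, "n_genes_tested") <- sum(!is.na(pvalue))
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with enforced monotonicity; `NA`/`NaN` p-values stay `NA`
#' and are excluded from the number of tests.
#'
#' @param p Vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Signed log p-value score
#'
#' `-log(p) * sign`, the ranking score used to compare workflows; p-values
#' of zero are clamped to `1e-300` before the log.
#'
#' @param result A `de_result`.
#' @param base Log base (default 10).
#' @return Named numeric vector of per-gene scores.
#' @export
signed_score <- function(result, base = 10) {
  stopifnot(inherits(result, "de_result"))
  p <- pmax(result$pvalue, 1e-300)
  stats::setNames(-log(p, base = base) * result$sign, result$gene_id)
}

#' Wilcoxon rank-sum DE test on log-normalized values
#'
#' Two-sided rank-sum test per gene using the tie-corrected normal
#' approximation (equivalent to `wilcox.test(exact = FALSE,
#' correct = FALSE)`), with the sign taken from the nonzero-mean log2
#' fold change. Genes that are constant across all cells get p = 1 and
#' sign 0.
#'
#' @param norm A `normalized_matrix`.
#' @param groups Case/control factor (default: labels in `norm`).
#' @return A `de_result` (method `"wilcoxon"`).
#' @export
wilcoxon_de <- function(norm, groups = norm$group) {
  stopifnot(inherits(norm, "normalized_matrix"))
  groups <- factor(as.character(groups), levels = c("control", "case"))
  case <- groups == "case"
  n1 <- sum(case)
  n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 cells")
  N <- n1 + n2
  v <- norm$values
  p <- apply(v, 1, function(x) {
    r <- rank(x)
    U <- sum(r[case]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(1) # constant gene
    2 * stats::pnorm(-abs((U - n1 * n2 / 2) / sqrt(sig2)))
  })
  fc <- estimate_logfc(norm, groups)
  s <- sign(fc$logfc)
  # flagged genes: fall back to the sign of the all-cell mean difference
  bad <- !is.finite(fc$logfc)
  if (any(bad)) {
    d <- rowMeans(v[bad, case, drop = FALSE]) - rowMeans(v[bad, !case, drop = FALSE])
    s[bad] <- sign(d)
  }
  s[p >= 1] <- 0
  de_result(norm$gene_ids, pvalue = pmin(p, 1), logfc = fc$logfc,
            sign = s, method = "wilcoxon")
}

#' Batch-covariate negative-binomial regression DE test
#'
#' Per gene, fits the log-linear count model
#' `log E(y) = a0 + a1 * log(L) + batch + group` by negative-binomial
#' regression (log link) and tests the case-vs-control coefficient
#' (Wald by default, likelihood-ratio optionally). `include_batch =
#' FALSE` drops the batch block (the pooled naive model). The library
#' size enters as a covariate with its own coefficient, or as a fixed
#' offset with `libsize = "offset"`.
#'
#' @param cm A [count_matrix()].
#' @param include_batch Include reference-coded batch coefficients. Every
#'   batch must then contain both groups; an unbalanced batch is a hard
#'   error naming the batch.
#' @param test `"wald"` (default) or `"lrt"`.
#' @param libsize `"covariate"` (coefficient on log L) or `"offset"`.
#' @return A list with `result` (a `de_result`, logFC reported in log2
#'   units) and `fit` (per-gene coefficient table: intercept, libsize
#'   coefficient, batch coefficients, group coefficient `gamma` on the
#'   natural-log scale, its SE, statistic and p-value, and a
#'   `flag` column marking genes where the fit failed).
#' @export
covariate_glm_de <- function(cm, include_batch = TRUE,
                             test = c("wald", "lrt"),
                             libsize = c("covariate", "offset")) {
  stopifnot(inherits(cm, "count_matrix"))
  test <- match.arg(test)
  libsize <- match.arg(libsize)
  groups <- cm$group
  batch <- droplevels(cm$batch)
  if (include_batch && nlevels(batch) > 1) {
    tab <- table(batch, groups)
    bad <- rownames(tab)[apply(tab == 0, 1, any)]
    if (length(bad)) {
      stop("batch '", bad[1], "' does not contain both groups; ",
           "cannot fit the batch-covariate model")
    }
  }
  logL <- log(cm$lib_size)
  use_batch <- include_batch && nlevels(batch) > 1
  dat <- data.frame(logL = logL, batch = batch, group = groups)
  form <- if (use_batch) {
    if (libsize == "covariate") y ~ logL + batch + group else y ~ batch + group + offset(logL)
  } else {
    if (libsize == "covariate") y ~ logL + group else y ~ group + offset(logL)
  }
  counts <- as.matrix(cm$counts)
  n_genes <- nrow(counts)
  gamma <- se <- stat <- pval <- rep(NA_real_, n_genes)
  flag <- rep("ok", n_genes)
  for (g in seq_len(n_genes)) {
    dat$y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(form, data = dat)),
      error = function(e) NULL
    )
    if (is.null(fit) || !("groupcase" %in% names(stats::coef(fit))) ||
        !is.finite(stats::coef(fit)[["groupcase"]])) {
      flag[g] <- "fit_failed"
      pval[g] <- 1
      gamma[g] <- 0
      next
    }
    cf <- suppressWarnings(summary(fit)$coefficients)
    gamma[g] <- cf["groupcase", "Estimate"]
    se[g] <- cf["groupcase", "Std. Error"]
    if (test == "wald") {
      stat[g] <- cf["groupcase", "z value"]
      pval[g] <- cf["groupcase", "Pr(>|z|)"]
    } else {
      fit0 <- tryCatch(
        suppressWarnings(MASS::glm.nb(stats::update(form, . ~ . - group), data = dat)),
        error = function(e) NULL
      )
      if (is.null(fit0)) {
        flag[g] <- "fit_failed"
        pval[g] <- 1
        next
      }
      stat[g] <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(fit0)))
      pval[g] <- stats::pchisq(max(stat[g], 0), df = 1, lower.tail = FALSE)
    }
    if (!is.finite(pval[g])) {
      flag[g] <- "fit_failed"
      pval[g] <- 1
    }
  }
  method <- if (use_batch) "glm-cov" else "glm"
  res <- de_result(cm$gene_ids,
    pvalue = pval, logfc = gamma / log(2),
    se = se / log(2), method = method
  )
  fittab <- data.frame(
    gene_id = cm$gene_ids, gamma = gamma, se = se,
    statistic = stat, pvalue = pval, flag = flag, stringsAsFactors = FALSE
  )
  list(result = res, fit = fittab)
}

#' Aggregate single-cell counts into pseudobulk units
#'
#' Sums counts over cells within each aggregation unit. Units must be
#' nested within batch x group so the output columns inherit unambiguous
#' labels; by default one unit per batch-group combination. A group
#' represented by a single unit (no replication) is a hard error.
#'
#' @param cm A [count_matrix()].
#' @param units Optional factor along cells defining aggregation units
#'   (e.g. patient of origin). Default `interaction(batch, group)`.
#' @return A [count_matrix()] whose columns are units.
#' @export
pseudobulk_aggregate <- function(cm, units = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(units)) {
    units <- interaction(cm$batch, cm$group, drop = TRUE, sep = ".")
  }
  units <- factor(units)
  if (length(units) != ncol(cm$counts)) stop("units must label every cell")
  ub <- tapply(as.character(cm$batch), units, function(x) unique(x))
  ug <- tapply(as.character(cm$group), units, function(x) unique(x))
  if (any(lengths(ub) > 1) || any(lengths(ug) > 1)) {
    stop("aggregation units must be nested within batch and group")
  }
  per_group <- table(unlist(ug))
  if (any(per_group < 2) || length(per_group) < 2) {
    stop("each group needs at least 2 aggregation units (replication)")
  }
  agg <- cm$counts %*% Matrix::t(Matrix::fac2sparse(units))
  count_matrix(agg,
    batch = unlist(ub)[colnames(agg)], group = unlist(ug)[colnames(agg)],
    gene_ids = cm$gene_ids, cell_ids = colnames(agg)
  )
}

#' DE test on pseudobulk units
#'
#' Per gene, a two-sided two-sample t-test (pooled variance) on the
#' log2-CPM of the aggregation units, case versus control; optionally a
#' paired-by-batch t-test when every batch holds exactly one case and one
#' control unit. Genes with identical values in both groups get p = 1.
#'
#' @param bulk A [count_matrix()] from [pseudobulk_aggregate()].
#' @param paired Pair units by batch.
#' @return A `de_result` (method `"pseudobulk"`).
#' @export
pseudobulk_de <- function(bulk, paired = FALSE) {
  stopifnot(inherits(bulk, "count_matrix"))
  case <- bulk$group == "case"
  n1 <- sum(case)
  n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop("need at least 2 units per group")
  v <- log1p(sweep(as.matrix(bulk$counts), 2, bulk$lib_size, "/") * 1e6) / log(2)
  if (paired) {
    bt <- as.character(bulk$batch)
    ok <- all(table(bt, case) == 1)
    if (!ok) stop("paired test needs one case and one control unit per batch")
    d <- v[, case, drop = FALSE][, order(bt[case]), drop = FALSE] -
      v[, !case, drop = FALSE][, order(bt[!case]), drop = FALSE]
    m <- rowMeans(d)
    sdd <- apply(d, 1, stats::sd)
    t <- m / (sdd / sqrt(ncol(d)))
    p <- 2 * stats::pt(-abs(t), df = ncol(d) - 1)
    p[sdd == 0 & m == 0] <- 1
    p[sdd == 0 & m != 0] <- 0
    lfc <- m
  } else {
    m1 <- rowMeans(v[, case, drop = FALSE])
    m2 <- rowMeans(v[, !case, drop = FALSE])
    v1 <- apply(v[, case, drop = FALSE], 1, stats::var)
    v2 <- apply(v[, !case, drop = FALSE], 1, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
    p[sp2 == 0 & m1 == m2] <- 1
    p[sp2 == 0 & m1 != m2] <- 0
    lfc <- m1 - m2
  }
  de_result(bulk$gene_ids, pvalue = p, logfc = lfc, method = "pseudobulk")
}

#' Read an externally computed DE result table
#'
#' Adapter for result files produced by external DE engines or
#' batch-effect-correction pipelines. The TSV must carry columns
#' `gene_id`, `logfc`, `pvalue`; `qvalue` and `sign` are optional (the
#' q-value is recomputed by [bh_adjust()] when absent, the sign defaults
#' to `sign(logfc)`).
#'
#' @param path TSV file.
#' @param method Method label; defaults to a `method` column if present,
#'   else the file name.
#' @return A validated `de_result`.
#' @export
read_external_result <- function(path, method = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "logfc", "pvalue")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$gene_id)) {
    stop("duplicate gene ids: ", d$gene_id[anyDuplicated(d$gene_id)][1])
  }
  bad <- which(!is.na(d$pvalue) & (d$pvalue < 0 | d$pvalue > 1))
  if (length(bad)) {
    stop("p-value outside [0, 1] in row ", bad[1], " (gene ", d$gene_id[bad[1]], ")")
  }
  if (is.null(method)) {
    method <- if ("method" %in% names(d)) d$method[1] else basename(path)
  }
  de_result(d$gene_id,
    pvalue = d$pvalue, logfc = d$logfc,
    sign = if ("sign" %in% names(d)) d$sign else NULL,
    qvalue = if ("qvalue" %in% names(d)) d$qvalue else NULL,
    method = method
  )
}

#' Write a DE result as TSV
#'
#' Fixed column order: gene_id, logfc, pvalue, qvalue, sign, method.
#'
#' @param result A `de_result`.
#' @param path Output path.
#' @export
write_de_result <- function(result, path) {
  stopifnot(inherits(result, "de_result"))
  out <- data.frame(
    gene_id = result$gene_id, logfc = result$logfc,
    pvalue = result$pvalue, qvalue = result$qvalue, sign = result$sign,
    method = attr(result, "method"), stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
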