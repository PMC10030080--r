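test_that("vectorized rank-sum test matches wilcox.test", {
  cm <- toy_counts(n_genes = 50, n_cells = 40, lambda = 3, seed = 41)
  nm <- log_normalize(cm)
  res <- wilcoxon_de(nm)
  case <- nm$group == "case"
  ref <- apply(nm$values, 1, function(x) {
    if (length(unique(x)) == 1) return(1)
    suppressWarnings(
      stats::wilcox.test(x[case], x[!case], exact = FALSE, correct = FALSE)$p.value
    )
  })
  expect_equal(res$pvalue, unname(ref), tolerance = 1e-10)
})

test_that("rank-sum degenerate cases: constant genes and identical groups", {
  v <- rbind(
    rep(1, 10), # constant -> p 1, sign 0
    c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5) # identical multisets -> p 1
  )
  nm <- normalized_matrix(v,
    batch = rep("b", 10),
    group = rep(c("case", "control"), each = 5)
  )
  res <- wilcoxon_de(nm)
  expect_equal(res$pvalue, c(1, 1))
  expect_equal(res$sign, c(0L, 0L))
  # complete separation: p equals the normal-approximation extreme
  v2 <- rbind(c(6, 7, 8, 9, 1, 2, 3, 4))
  nm2 <- normalized_matrix(v2,
    batch = rep("b", 8),
    group = rep(c("case", "control"), each = 4)
  )
  res2 <- wilcoxon_de(nm2)
  expect_equal(res2$pvalue,
    stats::wilcox.test(v2[1, 1:4], v2[1, 5:8], exact = FALSE, correct = FALSE)$p.value,
    tolerance = 1e-10
  )
  expect_equal(res2$sign, 1L)
})

test_that("BH adjustment matches the step-up oracle and handles NA", {
  withr::with_seed(51, {
    for (n in c(4, 37, 1000)) {
      p <- runif(n)
      expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
    }
  })
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  q <- bh_adjust(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_bruteforce(c(0.01, 0.5)))
})

test_that("signed score follows -log10(p) * sign and flips with labels", {
  r <- toy_result(p = c(1, 0.01, 0.01), sign = c(1L, -1L, 1L))
  s <- signed_score(r)
  expect_equal(unname(s), c(0, -2, 2))
  expect_equal(unname(signed_score(toy_result(p = 0, sign = 1L))), 300)
})

test_that("covariate NB regression is null-calibrated and batch-aware", {
  s <- simulate_counts(splat_params(
    n_genes = 120, batch_sizes = c(80, 80), de_prob = 0,
    batch_facLoc = 0.1, batch_facScale = 0.1, dropout_mid = -Inf,
    libsize_loc = 9, seed = 61
  ))
  fit <- covariate_glm_de(s$counts, include_batch = TRUE)
  expect_true(all(fit$result$pvalue >= 0 & fit$result$pvalue <= 1))
  expect_true(all(fit$result$qvalue >= fit$result$pvalue - 1e-12))
  # B = 1: batch block is empty; include_batch is a no-op
  one <- subset_counts(s$counts, cells = s$counts$batch == "batch1")
  a <- covariate_glm_de(one, include_batch = TRUE)
  b <- covariate_glm_de(one, include_batch = FALSE)
  expect_equal(a$result$pvalue, b$result$pvalue, tolerance = 1e-8)
  expect_equal(a$fit$gamma, b$fit$gamma, tolerance = 1e-8)
  # unbalanced batch is a hard error naming the batch
  bad <- s$counts
  bad$group[bad$batch == "batch2"] <- factor("case", levels = c("control", "case"))
  expect_error(
    covariate_glm_de(bad, include_batch = TRUE),
    "batch2"
  )
})

test_that("pseudobulk aggregation conserves counts and enforces replication", {
  cm <- toy_counts(n_genes = 3, n_cells = 6, n_batches = 2, seed = 71)
  units <- factor(c("u1", "u1", "u2", "u3", "u3", "u4"))
  # make units nested in batch x group
  cm$batch <- factor(rep(c("b1", "b2"), each = 3))
  cm$group <- factor(c("case", "case", "control", "case", "case", "control"),
    levels = c("control", "case")
  )
  agg <- pseudobulk_aggregate(cm, units)
  expect_equal(sum(agg$counts), sum(cm$counts))
  m <- as.matrix(cm$counts)
  expect_equal(as.vector(agg$counts[, "u1"]), unname(m[, 1] + m[, 2]))
  expect_equal(as.vector(agg$counts[, "u3"]), unname(m[, 4] + m[, 5]))
  # one cell per unit reproduces the input matrix
  ident <- pseudobulk_aggregate(cm, factor(cm$cell_ids, levels = cm$cell_ids))
  expect_equal(unname(as.matrix(ident$counts)), unname(m))
  # a group with a single unit has no replication
  expect_error(
    pseudobulk_aggregate(cm, factor(c("u1", "u1", "u2", "u1", "u1", "u2"))),
    "nested|at least 2"
  )
})

test_that("pseudobulk t-test finds spiked genes and not identical profiles", {
  base <- matrix(rep(c(100L, 50L), each = 8), 2, 8, byrow = TRUE)
  cm <- count_matrix(
    rbind(base, base + 0L),
    batch = rep(sprintf("b%d", 1:4), each = 2),
    group = rep(c("case", "control"), 4)
  )
  res <- pseudobulk_de(cm)
  expect_true(all(res$pvalue == 1)) # identical unit profiles
  # spike gene 1 four-fold in case units with low within-group variance
  m <- rbind(
    c(400L, 100L, 410L, 102L, 395L, 99L, 405L, 101L),
    matrix(50L, 3, 8)
  )
  cm2 <- count_matrix(m,
    batch = rep(sprintf("b%d", 1:4), each = 2),
    group = rep(c("case", "control"), 4)
  )
  res2 <- pseudobulk_de(cm2)
  expect_lt(res2$pvalue[1], 0.05)
  expect_equal(res2$sign[1], 1L)
})

test_that("pseudobulk on null multi-batch simulations controls discoveries", {
  fd <- vapply(1:3, function(sd) {
    s <- simulate_counts(splat_params(
      n_genes = 150, batch_sizes = rep(40, 7), de_prob = 0,
      batch_facLoc = 0.1, batch_facScale = 0.1, dropout_mid = -Inf,
      libsize_loc = 8, seed = 100 + sd
    ))
    res <- pseudobulk_de(pseudobulk_aggregate(filter_genes(s$counts)))
    sum(res$qvalue < 0.05)
  }, numeric(1))
  expect_equal(median(fd), 0)
})

test_that("external result adapter validates and completes the schema", {
  d <- data.frame(
    gene_id = c("g1", "g2", "g3"), logfc = c(1, -2, 0.5),
    pvalue = c(0.01, 0.5, 0.2)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- read_external_result(f, method = "ext")
  expect_s3_class(r, "de_result")
  expect_equal(r$qvalue, bh_bruteforce(d$pvalue))
  expect_equal(r$sign, c(1L, -1L, 1L))
  # qvalue passed through unchanged when present
  d$qvalue <- c(0.9, 0.9, 0.9)
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_external_result(f)$qvalue, d$qvalue)
  # invalid p named by row; missing columns; duplicate ids
  d$qvalue <- NULL
  d$pvalue[2] <- 1.5
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_external_result(f), "row 2")
  write.table(d[, c("gene_id", "logfc")], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_external_result(f), "pvalue")
  d$pvalue[2] <- 0.5
  d$gene_id[2] <- "g1"
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_external_result(f), "duplicate")
})

test_that("DE results are invariant to gene row order", {
  cm <- toy_counts(n_genes = 30, n_cells = 24, seed = 81)
  nm <- log_normalize(cm)
  res <- wilcoxon_de(nm)
  perm <- withr::with_seed(1, sample(nrow(cm$counts)))
  cmp <- subset_counts(cm, genes = perm)
  resp <- wilcoxon_de(log_normalize(cmp))
  m <- match(res$gene_id, resp$gene_id)
  expect_equal(resp$pvalue[m], res$pvalue)
  expect_equal(resp$qvalue[m], res$qvalue)
})
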