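test_that("F-beta evaluates the defining formula and its limits", {
  expect_equal(f_beta(1, 1, 0.5), 1)
  expect_equal(f_beta(0.8, 0.2, 0.5), 0.5) # closed-form spot check
  for (x in c(0.2, 0.7)) expect_equal(f_beta(x, x, 2), x) # P = R = x -> x
  expect_equal(f_beta(0, 0, 0.5), 0)
  # beta -> 0 approaches precision, beta large approaches recall
  expect_equal(f_beta(0.9, 0.3, 0.01), 0.9, tolerance = 1e-3)
  expect_equal(f_beta(0.9, 0.3, 100), 0.3, tolerance = 1e-3)
})

test_that("PR curve counts sign-matched detections and pAUPR integrates steps", {
  # 4 genes, 2 positives ranked 1st and 3rd with correct signs
  r <- toy_result(p = c(0.01, 0.02, 0.03, 0.04), sign = c(1L, 1L, 1L, 1L))
  tr <- toy_truth(c("up", "null", "up", "null"))
  cur <- pr_curve(r, tr, "up")
  expect_equal(cur$recall, c(0.5, 0.5, 1, 1))
  expect_equal(cur$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(paupr(cur, T = 0.5), 1)
  # perfect ranking with correct signs: pAUPR = 1 at any T
  r2 <- toy_result(p = c(0.001, 0.002, 0.5, 0.6), sign = c(1L, 1L, 0L, 0L))
  tr2 <- toy_truth(c("up", "up", "null", "null"))
  expect_equal(paupr(pr_curve(r2, tr2, "up"), T = 0.3), 1)
  expect_equal(paupr(pr_curve(r2, tr2, "up"), T = 1), 1)
  # a wrong sign disqualifies the detection
  r3 <- toy_result(p = c(0.001, 0.002), sign = c(-1L, 1L))
  tr3 <- toy_truth(c("up", "up"))
  cur3 <- pr_curve(r3, tr3, "up")
  expect_equal(cur3$recall, c(0, 0.5))
  expect_error(pr_curve(r3, toy_truth(c("null", "null")), "up"), "no 'up' gene")
})

test_that("pAUPR matches a dense numeric integration oracle", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      n <- 60
      p <- runif(n)
      # 5 positives: recall jumps at multiples of 0.2, aligned with the
      # oracle's grid cells, so midpoint integration is exact
      status <- sample(rep(c("up", "null"), c(5, n - 5)))
      r <- toy_result(p = p, sign = rep(1L, n))
      tr <- toy_truth(status)
      cur <- pr_curve(r, tr, "up")
      got <- paupr(cur, T = 0.5)
      # oracle: evaluate the right-open step function on a fine recall grid
      jump <- which(c(cur$recall[1] > 0, diff(cur$recall) > 0))
      rk <- cur$recall[jump]
      pk <- cur$precision[jump]
      grid <- seq(0, 0.5, length.out = 1e4 + 1)
      grid <- grid[-1] - diff(grid)[1] / 2 # midpoints
      prec_at <- pk[findInterval(grid, c(0, rk[-length(rk)]), left.open = TRUE)]
      oracle <- mean(prec_at) # (1/T) * sum * dt over [0, T]
      expect_lt(abs(got - oracle), 1e-6)
    }
  })
})

test_that("error ratio counts sign flips among DE genes", {
  status <- c(rep("up", 5), rep("down", 5), rep("null", 5))
  sgn <- c(rep(1L, 5), rep(-1L, 5), rep(0L, 5))
  r <- toy_result(p = rep(0.01, 15), sign = sgn)
  tr <- toy_truth(status)
  expect_equal(error_ratio(r, tr, "all_de"), 0)
  sgn2 <- sgn
  sgn2[1:2] <- -1L # 2 flipped of 10
  r2 <- toy_result(p = rep(0.01, 15), sign = sgn2)
  expect_equal(error_ratio(r2, tr, "all_de"), 20)
  # detected-only scope: only correctly signed genes reach q < 0.05
  p3 <- c(rep(0.9, 2), rep(0.001, 8), rep(0.9, 5))
  r3 <- toy_result(p = p3, sign = sgn2)
  expect_equal(error_ratio(r3, tr, "detected"), 0)
  expect_gt(error_ratio(r3, tr, "all_de"), 0)
  # empty scope is reported as missing
  r4 <- toy_result(p = rep(0.9, 15), sign = sgn)
  expect_true(is.na(error_ratio(r4, tr, "detected")))
})

test_that("angular distortion evaluates the cosine distance to y = x", {
  tab <- function(lfc) data.frame(gene_id = sprintf("G%06d", seq_along(lfc)), logfc = lfc)
  expect_equal(distortion(tab(c(1, -2, 0.5)), tab(c(1, -2, 0.5))), 0, ignore_attr = TRUE)
  expect_equal(distortion(tab(c(1, -2)), tab(c(-1, 2))), 1, ignore_attr = TRUE)
  expect_equal(distortion(tab(1), tab(0)), 1 - 1 / sqrt(2), ignore_attr = TRUE)
  # bounded in [0, 2] and invariant under joint positive rescaling
  withr::with_seed(111, {
    x <- rnorm(50)
    y <- rnorm(50)
  })
  d <- distortion(tab(x), tab(y))
  expect_gte(as.numeric(d), 0)
  expect_lte(as.numeric(d), 2)
  expect_equal(
    as.numeric(distortion(tab(3 * x), tab(3 * y))), as.numeric(d),
    tolerance = 1e-12
  )
  # zero-norm points are excluded and counted
  d2 <- distortion(tab(c(1, 0)), tab(c(1, 0)))
  expect_equal(attr(d2, "n_dropped"), 1)
})

test_that("cumulative score curve and pAUC match hand enumeration", {
  # 10 genes; positives with weights 0.5 and 0.3 at ranks 2 and 5
  p <- seq(0.01, 0.1, by = 0.01)
  r <- toy_result(p = p)
  w <- c("G000002" = 0.5, "G000005" = 0.3)
  cur <- cumulative_score_curve(r, w)
  expect_equal(cur$cum_score, c(0, 0.625, 0.625, 0.625, 1, 1, 1, 1, 1, 1))
  # top 50%: observed area 0 + 3 * 0.625 + 1; ideal 0.625 + 4 * 1
  expect_equal(pauc(cur, 0.5), 2.875 / 4.625)
  # all positives at the top: maximal pAUC 1 needs all weight at rank 1
  r2 <- toy_result(p = p)
  w2 <- c("G000001" = 0.7)
  expect_equal(pauc(cumulative_score_curve(r2, w2), 0.2), 1)
  expect_error(cumulative_score_curve(r, c(ZZZ = 1)), "overlaps")
})

test_that("truncated KS reduces to the direct weighted statistic at top_fraction 1", {
  withr::with_seed(121, {
    for (rep in 1:8) {
      n <- sample(10:50, 1)
      p <- runif(n)
      r <- toy_result(p = p)
      k <- sample(2:5, 1)
      pos <- sample(r$gene_id, k)
      w <- setNames(runif(k, 0.1, 1), pos)
      got <- truncated_ks_test(r, w,
        top_fraction = 1, n_permutations = 10, seed = 1
      )
      ord <- order(p, -abs(signed_score(r)), r$gene_id)
      wvec <- setNames(rep(0, n), r$gene_id)
      wvec[pos] <- w
      expect_equal(got$statistic, weighted_ks_direct(unname(wvec[ord])),
        tolerance = 1e-12
      )
    }
  })
})

test_that("truncated KS detects top-concentrated positives and ignores spread ones", {
  n <- 2000
  p <- seq_len(n) / n
  r <- toy_result(p = p)
  # all positives inside the top 1%
  top <- r$gene_id[1:20]
  w <- setNames(rep(1, 20), top)
  ks <- truncated_ks_test(r, w, top_fraction = 0.2, n_permutations = 999, seed = 7)
  expect_lt(ks$p_value, 0.01)
  expect_gt(ks$statistic, 0.9)
  # positives spread evenly: statistic near 0, p near 1
  spread <- r$gene_id[seq(50, 2000, by = 100)]
  w2 <- setNames(rep(1, length(spread)), spread)
  ks2 <- truncated_ks_test(r, w2, top_fraction = 0.2, n_permutations = 999, seed = 7)
  expect_lt(ks2$statistic, 0.1)
  expect_gt(ks2$p_value, 0.2)
  # positives only in the tail cannot register under the bridge
  tail_genes <- r$gene_id[1900:1950]
  w3 <- setNames(rep(1, length(tail_genes)), tail_genes)
  ks3 <- truncated_ks_test(r, w3, top_fraction = 0.2, n_permutations = 99, seed = 7)
  expect_gt(ks3$p_value, 0.5)
})

test_that("false-call counter and rank similarity behave on toys", {
  r <- toy_result(p = c(0.01, 0.04, 0.049, 0.051, 0.9))
  fc <- count_false_calls(r)
  expect_equal(unname(fc["n_p"]), 3)
  expect_equal(unname(fc["reference"]), 0.25)
  expect_equal(unname(count_false_calls(toy_result(p = rep(1, 4)))[c(1, 2)]), c(0, 0))
  a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 5)
  expect_equal(rank_similarity(a, a), 1)
  expect_equal(rank_similarity(a, -a), -1)
  b <- c(g1 = 1, g2 = 2, g3 = 4, g4 = 3, g5 = 5) # one swap
  expect_equal(rank_similarity(a, b), cor(a, b, method = "spearman"))
  expect_error(rank_similarity(a[1:2], a[1:2]), "3 common")
})

test_that("evaluate_workflow assembles the per-workflow report", {
  status <- c(rep("up", 10), rep("down", 10), rep("null", 80))
  withr::with_seed(131, {
    p <- c(runif(20, 0, 0.01), runif(80))
  })
  r <- toy_result(p = p, sign = c(rep(1L, 10), rep(-1L, 10), rep(1L, 80)))
  tr <- toy_truth(status)
  w <- setNames(rep(1, 10), sprintf("G%06d", 1:10))
  rep_row <- evaluate_workflow(r,
    truth = tr, geneset = w,
    config = metric_config(n_permutations = 99), seed = 3
  )
  expect_s3_class(rep_row, "metric_report")
  expect_true(all(c(
    "f05_up", "f05_down", "paupr_up", "paupr_down",
    "error_ratio_all", "error_ratio_detected", "pauc", "ks_p"
  ) %in% names(rep_row)))
  expect_gt(rep_row$f05_up, 0.5)
  expect_equal(rep_row$error_ratio_all, 0)
})
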