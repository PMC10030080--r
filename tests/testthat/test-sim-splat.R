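test_that("simulated batches have the requested sizes and labels", {
  p <- splat_params(
    n_genes = 100, batch_sizes = c(300, 750), group_ratios = 0.3, seed = 5
  )
  s <- simulate_counts(p)
  expect_equal(dim(s$counts$counts), c(100, 1050))
  expect_equal(as.vector(table(s$counts$batch)), c(300, 750))
  # per-batch case counts follow the ratio with per-batch rounding
  tab <- table(s$counts$batch, s$counts$group)
  expect_equal(unname(tab[, "case"]), c(90, 225))
  expect_true(all(s$counts$counts@x >= 0))
})

test_that("simulation is bit-reproducible from the seed and batch-stable", {
  p <- splat_params(n_genes = 60, batch_sizes = c(40, 60), seed = 42)
  a <- simulate_counts(p)
  b <- simulate_counts(p)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth, b$truth)
  # adding a third batch must not perturb the first two (substreams)
  p3 <- splat_params(n_genes = 60, batch_sizes = c(40, 60, 30), seed = 42)
  c3 <- simulate_counts(p3)
  expect_identical(
    as.matrix(c3$counts$counts[, 1:100]),
    as.matrix(a$counts$counts)
  )
})

test_that("DE truth has the configured up/down split and folded factors", {
  p <- splat_params(n_genes = 1000, batch_sizes = c(50, 50), de_prob = 0.2)
  s <- simulate_counts(p)
  expect_equal(sum(s$truth$status == "up"), 100)
  expect_equal(sum(s$truth$status == "down"), 100)
  expect_true(all(s$truth$effect[s$truth$status == "null"] == 1))
  expect_true(all(s$truth$effect[s$truth$status == "up"] >= 1))
  expect_true(all(s$truth$effect[s$truth$status == "down"] <= 1))
  expect_warning(
    simulate_counts(splat_params(n_genes = 100, batch_sizes = c(10, 10), de_prob = 0.001)),
    "zero DE genes"
  )
})

test_that("null simulation shows no case/control mean difference", {
  p <- splat_params(
    n_genes = 200, batch_sizes = c(400, 400), de_prob = 0,
    batch_facLoc = 0, batch_facScale = 0, dropout_mid = -Inf,
    libsize_loc = 9, seed = 9
  )
  s <- simulate_counts(p)
  cm <- s$counts
  expect_true(all(s$truth$status == "null"))
  m_case <- Matrix::rowMeans(cm$counts[, cm$group == "case"])
  m_ctrl <- Matrix::rowMeans(cm$counts[, cm$group == "control"])
  # paired per-gene comparison: relative differences are Monte-Carlo noise
  expect_lt(median(abs(m_case - m_ctrl) / (m_case + m_ctrl)), 0.1)
  expect_gt(cor(m_case, m_ctrl), 0.99)
})

test_that("counts match the analytic NB mean when dropout is disabled", {
  p <- splat_params(
    n_genes = 150, batch_sizes = 3000, de_prob = 0,
    batch_facLoc = 0, batch_facScale = 0, dropout_mid = -Inf,
    libsize_scale = 0, libsize_loc = 9, dispersion = 0.5, seed = 21
  )
  s <- simulate_counts(p, keep_means = TRUE)
  mu <- rowMeans(s$means)
  emp <- Matrix::rowMeans(s$counts$counts)
  nb_var <- rowMeans(s$means + p$dispersion * s$means^2)
  se <- sqrt(nb_var / ncol(s$means))
  # analytic NB mean within 3 standard errors for nearly all genes
  expect_gte(mean(abs(emp - mu) <= 3 * se), 0.95)
})

test_that("lognormal factors behave at the degenerate scale and in median", {
  expect_equal(draw_lognormal_factors(0, 0, 5), rep(1, 5))
  expect_equal(draw_lognormal_factors(0.3, 0, 4), rep(exp(0.3), 4))
  withr::with_seed(1, {
    f <- draw_lognormal_factors(0.4, 0.4, 1e5)
  })
  expect_true(all(f > 0))
  expect_lt(abs(median(f) - exp(0.4)) / exp(0.4), 0.01)
  expect_error(draw_lognormal_factors(0, 0.1, 0), "positive")
})

test_that("logistic dropout hits the midpoint probability and is monotone in mid", {
  mu <- matrix(1, 200, 500) # ln mu = 0 at mid 0: drop probability 1/2
  withr::with_seed(2, {
    mask <- logistic_dropout(mu, mid = 0, shape = -1)
  })
  expect_lt(abs(mean(mask) - 0.5), 0.01)
  withr::with_seed(3, {
    none <- logistic_dropout(mu, mid = -1e6, shape = -1)
  })
  expect_equal(sum(none), 0)
  mu2 <- matrix(rlnorm(2e5, 1, 1), 400)
  withr::with_seed(4, {
    lo <- logistic_dropout(mu2, mid = 0.01, shape = -1)
    hi <- logistic_dropout(mu2, mid = 3.7, shape = -1)
  })
  expect_gt(mean(hi), mean(lo))
  expect_error(logistic_dropout(matrix(0, 2, 2), 0), "positive")
})

test_that("depth presets land near their nominal nonzero means", {
  targets <- c(
    "sparse80-depth77" = 77, "sparse80-depth10" = 10, "sparse80-depth4" = 4
  )
  for (nm in names(targets)) {
    s <- simulate_counts(splat_preset(nm, n_genes = 1000, seed = 3))
    f <- filter_genes(s$counts)
    depth <- mean(f$counts@x)
    expect_lt(abs(depth - targets[[nm]]) / targets[[nm]], 0.30,
      label = sprintf("%s depth %.1f", nm, depth)
    )
  }
})

test_that("parameter validation rejects impossible settings", {
  expect_error(splat_params(batch_sizes = c(100, 0)), "positive")
  expect_error(splat_params(group_ratios = 1.2), "\\(0, 1\\)")
  expect_error(splat_params(dispersion = 0), "positive")
  expect_error(splat_params(de_prob = 1.5), "\\[0, 1\\]")
})
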