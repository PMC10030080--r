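#' Principal variance component analysis
#'
#' Quantifies the fractions of expression variance attributable to batch,
#' group, their interaction and the residual. Principal components are
#' retained until their cumulative variance share reaches `var_threshold`
#' (capped at `max_pcs`); each retained PC is decomposed by a mixed model
#' with random batch, group and batch:group terms (REML, with an
#' ANOVA method-of-moments fallback when REML fails); the per-factor
#' components are averaged across PCs weighted by each PC's variance
#' share and normalized to sum to one.
#'
#' @param norm A `normalized_matrix`.
#' @param batch,group Per-cell factors (defaults: labels in `norm`);
#'   both need at least two levels.
#' @param var_threshold Cumulative variance share to retain, in (0,1\].
#' @param max_pcs Maximum number of PCs.
#' @param subsample Optional number of cells to randomly subsample
#'   before the PCA (a large-data shortcut).
#' @param seed Seed for the subsample.
#' @return List of class `pvca_result`: `proportions` (named vector over
#'   batch, group, batch_group, residual, summing to 1), `n_pcs`,
#'   `var_threshold`.
#' @export
pvca <- function(norm, batch = norm$batch, group = norm$group,
                 var_threshold = 0.6, max_pcs = 20, subsample = NULL,
                 seed = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  batch <- factor(as.character(batch))
  group <- factor(as.character(group))
  if (nlevels(batch) < 2) stop("batch needs at least two levels")
  if (nlevels(group) < 2) stop("group needs at least two levels")
  v <- norm$values
  n_cells <- ncol(v)
  if (n_cells < 10) stop("need at least 10 cells")
  if (!is.null(subsample) && subsample < n_cells) {
    pick <- with_substream(
      if (is.null(seed)) 0L else seed, "subsample",
      expr = sort(sample.int(n_cells, subsample))
    )
    v <- v[, pick, drop = FALSE]
    batch <- droplevels(batch[pick])
    group <- droplevels(group[pick])
    if (nlevels(batch) < 2 || nlevels(group) < 2) {
      stop("subsample lost a factor level")
    }
    n_cells <- ncol(v)
  }
  if (max_pcs >= n_cells) stop("fewer cells than requested PCs")

  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  var_share <- pc$sdev^2 / sum(pc$sdev^2)
  n_pcs <- min(max_pcs, which(cumsum(var_share) >= var_threshold)[1], na.rm = TRUE)
  if (is.na(n_pcs)) n_pcs <- min(max_pcs, length(var_share))
  n_pcs <- max(1L, n_pcs)

  comp <- matrix(0, n_pcs, 4,
    dimnames = list(NULL, c("batch", "group", "batch_group", "residual"))
  )
  dat <- data.frame(batch = batch, group = group)
  for (i in seq_len(n_pcs)) {
    dat$y <- pc$x[, i]
    vc <- tryCatch(
      {
        fit <- suppressMessages(suppressWarnings(lme4::lmer(
          y ~ (1 | batch) + (1 | group) + (1 | batch:group),
          data = dat,
          control = lme4::lmerControl(check.conv.singular = "ignore")
        )))
        vtab <- as.data.frame(lme4::VarCorr(fit))
        get <- function(g) {
          hit <- vtab$vcov[vtab$grp == g]
          if (length(hit)) hit else 0
        }
        c(
          batch = get("batch"), group = get("group"),
          batch_group = get("batch:group"), residual = get("Residual")
        )
      },
      error = function(e) pvca_moments(dat$y, batch, group)
    )
    comp[i, names(vc)] <- pmax(vc, 0)
  }
  wts <- var_share[seq_len(n_pcs)] / sum(var_share[seq_len(n_pcs)])
  raw <- colSums(comp * wts)
  props <- raw / sum(raw)
  structure(
    list(proportions = props, n_pcs = n_pcs, var_threshold = var_threshold),
    class = "pvca_result"
  )
}

# ANOVA method-of-moments fallback for one PC: mean squares from the
# crossed two-factor fit, negative components truncated at zero. Uses the
# average cell count per stratum as the expected-mean-square multiplier,
# which is exact for balanced designs and a standard approximation
# otherwise.
pvca_moments <- function(y, batch, group) {
  a <- nlevels(batch)
  b <- nlevels(group)
  fit <- stats::anova(stats::lm(y ~ batch * group))
  ms <- fit[["Mean Sq"]]
  names(ms) <- rownames(fit)
  n_bar <- length(y) / (a * b)
  mse <- ms[["Residuals"]]
  s_int <- max(0, (ms[["batch:group"]] - mse) / n_bar)
  s_batch <- max(0, (ms[["batch"]] - ms[["batch:group"]]) / (b * n_bar))
  s_group <- max(0, (ms[["group"]] - ms[["batch:group"]]) / (a * n_bar))
  c(batch = s_batch, group = s_group, batch_group = s_int, residual = mse)
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("PVCA over %d PCs (threshold %.2f):\n", x$n_pcs, x$var_threshold))
  print(round(x$proportions, 4))
  invisible(x)
}
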