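# Rule-based Good/Intermediate/Poor classification of DE workflows.
# All boundaries use strict inequalities on both sides, so values landing
# exactly on a threshold fall to Intermediate.

.category <- function(good, poor) {
  if (isTRUE(good)) "Good" else if (isTRUE(poor)) "Poor" else "Intermediate"
}

#' Classify standard-positive detection performance
#'
#' Good: truncated KS p < 0.01 and pAUC rank within the top 10 of the
#' evaluated workflow set; Poor: p > 0.01 or rank > 20; otherwise
#' Intermediate. Ranks are computed over the evaluated set with min-rank
#' for ties.
#'
#' @param ks_p Truncated KS p-value.
#' @param pauc_rank Rank of the workflow's pAUC (1 = best).
#' @return `"Good"`, `"Intermediate"` or `"Poor"`.
#' @export
classify_detection <- function(ks_p, pauc_rank) {
  if (is.na(ks_p) || is.na(pauc_rank)) stop("missing inputs")
  .category(ks_p < 0.01 && pauc_rank <= 10, ks_p > 0.01 || pauc_rank > 20)
}

#' Classify false-positive / false-discovery control
#'
#' Over repeated null-split runs at two depth regimes: Good when the
#' median false-discovery count is zero and the median false-positive
#' count is at most 5% of analyzed genes at both depths; Poor when the
#' median false-discovery count exceeds zero at both depths and the
#' median false-positive count exceeds 5% at either depth; otherwise
#' Intermediate.
#'
#' @param fp_counts,fd_counts Lists of two numeric vectors (counts per
#'   run) named by depth regime, e.g. `list(low = ..., moderate = ...)`.
#' @param n_genes Number of analyzed genes (scalar or one per regime).
#' @export
classify_fp_fd <- function(fp_counts, fd_counts, n_genes) {
  stopifnot(length(fp_counts) == 2, length(fd_counts) == 2)
  if (any(!lengths(fp_counts)) || any(!lengths(fd_counts))) {
    stop("a depth regime has no runs")
  }
  n_genes <- rep_len(n_genes, 2)
  med_fp <- vapply(fp_counts, stats::median, numeric(1))
  med_fd <- vapply(fd_counts, stats::median, numeric(1))
  .category(
    all(med_fd == 0) && all(med_fp <= 0.05 * n_genes),
    all(med_fd > 0) && any(med_fp > 0.05 * n_genes)
  )
}

#' Sign-preservation percentage and classification
#'
#' Aggregates the relative difference between two groups of performance
#' values (e.g. error ratios of two scenario families) as
#' `P = 100 * |median_a - median_b| / OVS`, where the overall visible
#' spread OVS is the whisker-to-whisker span across both groups (Tukey
#' 1.5 IQR whiskers clipped to the data, as drawn by box plots).
#'
#' @param a,b Nonempty numeric samples.
#' @return P (percent), with attribute `degenerate` flagging OVS = 0 with
#'   unequal medians.
#' @export
sign_preservation_P <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  sa <- grDevices::boxplot.stats(a)$stats
  sb <- grDevices::boxplot.stats(b)$stats
  ovs <- max(sa[5], sb[5]) - min(sa[1], sb[1])
  dbm <- abs(stats::median(a) - stats::median(b))
  if (ovs == 0) {
    out <- if (dbm == 0) 0 else NA_real_
    attr(out, "degenerate") <- dbm != 0
    return(out)
  }
  out <- 100 * dbm / ovs
  attr(out, "degenerate") <- FALSE
  out
}

#' Classify sign preservation from the percentage P
#'
#' Good: P < 30; Poor: P > 60; otherwise Intermediate.
#' @param P Percentage from [sign_preservation_P()].
#' @export
classify_sign_preservation <- function(P) {
  if (is.na(P)) stop("degenerate or missing P")
  .category(P < 30, P > 60)
}

#' Classify runtime
#'
#' Good when the large-fixture runtime stays below `good_large` seconds;
#' Poor when the small fixture exceeds `poor_small` or the large fixture
#' exceeds `poor_large`; otherwise Intermediate. Defaults encode the
#' 10 min / 30 min / 3 h rules used for the benchmark's moderate and
#' large reference datasets.
#'
#' @param runtime_small,runtime_large Runtimes in seconds on the
#'   designated small and large fixtures.
#' @param thresholds Named vector `good_large`, `poor_small`,
#'   `poor_large` (seconds).
#' @export
classify_speed <- function(runtime_small, runtime_large,
                           thresholds = c(
                             good_large = 600, poor_small = 1800,
                             poor_large = 10800
                           )) {
  if (is.na(runtime_small) || is.na(runtime_large)) stop("missing measurement")
  .category(
    runtime_large < thresholds[["good_large"]],
    runtime_small > thresholds[["poor_small"]] ||
      runtime_large > thresholds[["poor_large"]]
  )
}

#' Fit the scalability coefficient
#'
#' Least-squares fit through the origin of runtime against the square
#' root of the number of matrix entries: `T_i = alpha * sqrt(N_i * M_i)`,
#' so `alpha = sum(T_i s_i) / sum(s_i^2)` with `s_i = sqrt(N_i M_i)`.
#'
#' @param times Runtimes in seconds.
#' @param sizes Two-column matrix or data frame of (cells, genes) per
#'   observation.
#' @return List of class `scalability_fit`: `alpha`, `sizes` (the
#'   `s_i`), `times`, `residuals`.
#' @export
fit_scalability <- function(times, sizes) {
  sizes <- as.matrix(sizes)
  stopifnot(length(times) >= 1, nrow(sizes) == length(times), ncol(sizes) == 2)
  s <- sqrt(sizes[, 1] * sizes[, 2])
  if (all(s == 0)) stop("all sizes are zero")
  alpha <- sum(times * s) / sum(s^2)
  structure(
    list(alpha = alpha, sizes = s, times = times, residuals = times - alpha * s),
    class = "scalability_fit"
  )
}

#' Classify scalability from the fitted coefficient
#'
#' Good: alpha < 1; Poor: alpha > 2; otherwise Intermediate.
#' @param fit A `scalability_fit` (or a bare alpha value).
#' @export
classify_scalability <- function(fit) {
  alpha <- if (inherits(fit, "scalability_fit")) fit$alpha else fit
  .category(alpha < 1, alpha > 2)
}
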