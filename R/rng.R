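# Deterministic substream seeds: one master seed spawns independent streams
# per pipeline stage and per batch, so adding a batch never perturbs the
# draws of earlier batches.

.stage_codes <- c(
  means = 1L, libsize = 2L, batch_factors = 3L, de_select = 4L,
  de_factors = 5L, counts = 6L, dropout = 7L, split = 8L,
  downsample = 9L, subsample = 10L, permute = 11L, generic = 12L
)

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a named stage and batch index to a seed in
#' `[0, 2^31)`. The map is a fixed affine hash, so the same
#' (seed, stage, index) always yields the same substream.
#'
#' @param seed Master integer seed.
#' @param stage Stage name, one of `names(scDEbench:::.stage_codes)`.
#' @param index Nonnegative integer substream index (e.g. batch number).
#' @return A single integer seed.
#' @keywords internal
substream_seed <- function(seed, stage, index = 0L) {
  stopifnot(stage %in% names(.stage_codes))
  code <- .stage_codes[[stage]]
  # All products stay below 2^53 for |seed| < 2^31, so doubles are exact.
  as.integer((abs(as.numeric(seed)) * 48271 + code * 100003 + index * 1009) %%
               2147483629)
}

#' Evaluate an expression under a substream seed
#' @inheritParams substream_seed
#' @param expr Expression to evaluate.
#' @keywords internal
with_substream <- function(seed, stage, index = 0L, expr) {
  withr::with_seed(substream_seed(seed, stage, index), expr)
}
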