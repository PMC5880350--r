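#' Static block partition of an index range
#'
#' Splits the half-open range `[0, total)` into `workers` contiguous
#' blocks whose sizes differ by at most one, the first
#' `total %% workers` blocks being one item larger.  Empty blocks are
#' allowed when `workers > total`.  This is the rule used to distribute
#' seeded biclusters across completion workers.
#'
#' @param total number of items (>= 0).
#' @param workers number of blocks (>= 1).
#' @return a data frame with integer columns `start` (inclusive) and
#'   `end` (exclusive), 0-based, one row per worker.
#' @export
partition_range <- function(total, workers) {
  total <- as.integer(total)
  workers <- as.integer(workers)
  stopifnot(!is.na(total), total >= 0L, !is.na(workers), workers >= 1L)
  base <- total %/% workers
  rem <- total %% workers
  sizes <- rep(base, workers) + c(rep(1L, rem), rep(0L, workers - rem))
  ends <- cumsum(sizes)
  data.frame(start = c(0L, ends[-workers]), end = ends)
}
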