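#' Naive reference enumerator of pair-seeded biclusters
#'
#' A declarative, unoptimized restatement of the algorithm used as an
#' independent verification oracle: for every unordered row pair it
#' takes the exact set of columns that are one in both rows, keeps sets
#' of size at least `mnc`, deduplicates the column sets, extends each
#' surviving set with all rows containing it, and keeps results with at
#' least `mnr` rows.  Implemented entirely in R on the unpacked 0/1
#' matrix with no encoding, packing or hashing shared with [bibit()].
#' Intended for small instances (roughly m <= 60, n <= 20).
#'
#' @param x 0/1 numeric matrix.
#' @param mnr minimum rows per bicluster (>= 2).
#' @param mnc minimum columns per bicluster (>= 1).
#' @return a `"bibit"` object ordered identically to [bibit()] (patterns
#'   compared lexicographically on the column-bit sequence, column 1
#'   first).
#' @export
bibit_oracle <- function(x, mnr, mnc) {
  params <- validate_params(mnr, mnc)
  bin <- as_binary_matrix(x)
  m <- nrow(bin)
  n <- ncol(bin)

  colsets <- list()
  for (i in seq_len(m - 1L)) {
    for (k in seq(i + 1L, m)) {
      cols <- unname(which(bin[i, ] == 1L & bin[k, ] == 1L))
      if (length(cols) >= params$mnc) {
        key <- paste(cols, collapse = ",")
        if (is.null(colsets[[key]])) colsets[[key]] <- cols
      }
    }
  }

  bcs <- list()
  keys <- character(0)
  for (cols in colsets) {
    rows <- unname(which(rowSums(bin[, cols, drop = FALSE]) == length(cols)))
    if (length(rows) >= params$mnr) {
      bcs[[length(bcs) + 1L]] <- list(rows = rows, cols = cols)
      bits <- rep("0", n)
      bits[cols] <- "1"
      keys <- c(keys, paste(bits, collapse = ""))
    }
  }
  bcs <- bcs[order(keys, method = "radix")]

  structure(
    list(biclusters = bcs, row_names = rownames(bin),
         col_names = colnames(bin), dim = dim(bin),
         n_seeds = length(colsets), params = params),
    class = "bibit"
  )
}
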