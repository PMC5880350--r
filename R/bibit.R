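#' Enumerate all-ones biclusters with the bit-pattern algorithm
#'
#' Runs the full pipeline: (optional) binarization by a strict threshold,
#' word-packed encoding, seeding of one candidate per distinct row-pair
#' AND pattern with at least `mnc` set bits, completion of each pattern
#' with every row containing it, and the `mnr` minimum-row filter.
#'
#' Seeding considers every unordered pair of rows; the pattern of a pair
#' is the bitwise AND of the two rows, so a set bit marks a column that
#' is one in both.  Duplicate patterns are kept once (which pair seeds a
#' duplicate is irrelevant: completion recomputes the full row set from
#' the pattern alone).  A pattern that is a strict subset of another
#' reported pattern is still reported; deduplication is by identical
#' pattern only, with no maximality filter.
#'
#' Completion uses column-support bitset intersection: the rows of a
#' bicluster are the intersection of the row-support sets of the
#' pattern's columns, which equals the set of rows `r` with
#' `pattern AND r == pattern` (see [complete_bicluster()] for the direct
#' row-scan form).  Output is sorted by pattern, compared
#' lexicographically on the unpacked column-bit sequence (column 0
#' first), making results byte-deterministic across word widths and
#' worker counts.
#'
#' @param x numeric matrix; values must be 0/1 unless `threshold` is
#'   given, in which case values strictly greater than `threshold`
#'   become 1.
#' @param mnr minimum number of rows per reported bicluster (>= 2).
#' @param mnc minimum number of columns per reported bicluster (>= 1).
#' @param threshold optional binarization threshold for real-valued
#'   input.
#' @param word_width 32 or 64; a performance knob that never changes the
#'   output.
#' @param workers number of worker threads (>= 1).  Any worker count
#'   produces output identical to the serial run: seeding workers share
#'   one pattern set whose membership-test-plus-insert is atomic, and
#'   completion partitions seeds into independent blocks.
#' @param enumeration_order optional permutation of `1:nrow(x)` changing
#'   the order in which row pairs are enumerated; the output is
#'   invariant to it.
#' @return an object of class `"bibit"`: a list with `biclusters` (each
#'   a list with 1-based integer `rows` and `cols`), `row_names`,
#'   `col_names`, `dim`, `n_seeds` and `params`.
#' @examples
#' x <- rbind(A = c(1, 1, 0, 1), B = c(1, 1, 1, 0), C = c(0, 1, 1, 1),
#'            D = c(1, 1, 1, 1), E = c(1, 0, 0, 0))
#' res <- bibit(x, mnr = 2, mnc = 2)
#' res
#' @seealso [bibit_oracle()] for the naive reference enumerator,
#'   [write_biclusters()] for the output format.
#' @export
bibit <- function(x, mnr, mnc, threshold = NULL, word_width = 64L,
                  workers = 1L, enumeration_order = NULL) {
  validate_raw_matrix(x)
  params <- validate_params(mnr, mnc, word_width, workers, nrow(x), ncol(x))
  if (!is.null(threshold)) {
    x <- binarize(x, threshold)
  } else if (!is_binary_values(x)) {
    stop("input is not binary; supply `threshold` to binarize it",
         call. = FALSE)
  }
  bin <- as_binary_matrix(x)
  res <- cpp_run(bin, params$mnr, params$mnc, params$word_width,
                 params$workers,
                 if (is.null(enumeration_order)) NULL
                 else as.integer(enumeration_order))
  bcs <- mapply(function(r, co) list(rows = r, cols = co),
                res$rows, res$cols, SIMPLIFY = FALSE)
  structure(
    list(biclusters = bcs,
         row_names = rownames(bin), col_names = colnames(bin),
         dim = dim(bin), n_seeds = res$n_seeds,
         params = params),
    class = "bibit"
  )
}

validate_params <- function(mnr, mnc, word_width = 64L, workers = 1L,
                            m = NULL, n = NULL) {
  mnr <- as.integer(mnr)
  mnc <- as.integer(mnc)
  word_width <- as.integer(word_width)
  workers <- as.integer(workers)
  if (is.na(mnr) || mnr < 2L) stop("mnr must be an integer >= 2", call. = FALSE)
  if (is.na(mnc) || mnc < 1L) {
    stop("mnc must be an integer >= 1 (an all-zero pattern would match ",
         "every row)", call. = FALSE)
  }
  if (!word_width %in% c(32L, 64L)) stop("word_width must be 32 or 64",
                                         call. = FALSE)
  if (is.na(workers) || workers < 1L) stop("workers must be >= 1",
                                           call. = FALSE)
  list(mnr = mnr, mnc = mnc, word_width = word_width, workers = workers)
}

#' Joint pattern of a pair of rows
#'
#' Computes the bitwise AND of two encoded rows: bit `j` of the result
#' is set iff column `j` is one in both rows.
#'
#' @param enc a `"bibit_encoded"` matrix from [encode_matrix()].
#' @param i,k distinct 1-based row indices.
#' @return an object of class `"bibit_pattern"`: a list with `words`
#'   (raw bytes in the encoded layout), `ones` (set-bit count), `n`, and
#'   `word_width`.
#' @export
pair_pattern <- function(enc, i, k) {
  stopifnot(inherits(enc, "bibit_encoded"))
  i <- as.integer(i); k <- as.integer(k)
  m <- nrow(enc$words)
  if (anyNA(c(i, k)) || i < 1L || k < 1L || i > m || k > m || i == k) {
    stop("i and k must be distinct row indices in 1..", m, call. = FALSE)
  }
  res <- cpp_pair_pattern(enc$words, enc$n, enc$word_width, i - 1L, k - 1L)
  structure(list(words = res$bytes, ones = res$ones, n = enc$n,
                 word_width = enc$word_width),
            class = "bibit_pattern")
}

#' Columns selected by a pattern
#'
#' @param pattern a `"bibit_pattern"` object (or a raw vector in the
#'   encoded byte layout).
#' @param n number of columns; taken from the pattern object if absent.
#' @return 1-based integer indices of the set columns, ascending.
#' @export
pattern_columns <- function(pattern, n = NULL) {
  if (inherits(pattern, "bibit_pattern")) {
    n <- pattern$n
    pattern <- pattern$words
  }
  stopifnot(is.raw(pattern), !is.null(n))
  which(as.logical(rawToBits(pattern))[seq_len(n)])
}

#' @export
print.bibit_pattern <- function(x, ...) {
  cat("Bit pattern over ", x$n, " columns, ", x$ones, " set: {",
      paste(pattern_columns(x), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Seed candidate biclusters from all row pairs
#'
#' For every unordered pair of rows whose AND pattern has at least `mnc`
#' set bits, keeps one seed per distinct pattern (first-seen pair wins;
#' which pair that is never affects downstream results).  Intended for
#' inspection and small problems; [bibit()] runs seeding and completion
#' in one pass without materializing the seed set in R.
#'
#' @param enc a `"bibit_encoded"` matrix.
#' @param mnc minimum number of set bits per seed pattern (>= 1).
#' @param workers worker threads sharing one atomically-updated pattern
#'   set.
#' @param enumeration_order optional permutation of `1:m` changing pair
#'   enumeration order.
#' @return class `"bibit_seeds"`: a list with `patterns` (a seeds x
#'   nbytes raw matrix, canonically ordered), `seed_rows` (a seeds x 2
#'   integer matrix of 1-based seeding row indices), `ones`, `n`,
#'   `word_width`.
#' @export
initialize_biclusters <- function(enc, mnc, workers = 1L,
                                  enumeration_order = NULL) {
  stopifnot(inherits(enc, "bibit_encoded"))
  mnc <- as.integer(mnc)
  if (is.na(mnc) || mnc < 1L) stop("mnc must be an integer >= 1",
                                   call. = FALSE)
  res <- cpp_seed(enc$words, enc$n, enc$word_width, mnc,
                  as.integer(workers),
                  if (is.null(enumeration_order)) NULL
                  else as.integer(enumeration_order))
  structure(c(res, list(n = enc$n, word_width = enc$word_width)),
            class = "bibit_seeds")
}

#' @export
print.bibit_seeds <- function(x, ...) {
  cat("Seed set: ", nrow(x$patterns), " distinct patterns over ", x$n,
      " columns\n", sep = "")
  invisible(x)
}

#' Complete a seeded bicluster by direct row scan
#'
#' Returns all rows `r` of the encoded matrix with
#' `pattern AND r == pattern` (necessarily including any rows whose AND
#' produced the pattern), or `NULL` when fewer than `mnr` rows qualify.
#' The result depends only on the pattern, never on which pair seeded
#' it.  This is the direct row-scan form; [bibit()] computes the same
#' set by intersecting column-support bitsets.
#'
#' @param enc a `"bibit_encoded"` matrix.
#' @param pattern a `"bibit_pattern"` object or raw vector in the
#'   encoded byte layout.
#' @param mnr minimum number of rows (>= 2).
#' @return ascending 1-based integer row indices, or `NULL` (discard).
#' @export
complete_bicluster <- function(enc, pattern, mnr) {
  stopifnot(inherits(enc, "bibit_encoded"))
  if (inherits(pattern, "bibit_pattern")) pattern <- pattern$words
  stopifnot(is.raw(pattern))
  mnr <- as.integer(mnr)
  if (is.na(mnr) || mnr < 2L) stop("mnr must be an integer >= 2",
                                   call. = FALSE)
  rows <- cpp_complete_rowscan(enc$words, enc$n, enc$word_width, pattern)
  if (length(rows) < mnr) NULL else rows
}

#' @export
print.bibit <- function(x, ...) {
  cat("Bit-pattern biclustering of a ", x$dim[1L], " x ", x$dim[2L],
      " binary matrix\n", sep = "")
  cat("  mnr = ", x$params$mnr, ", mnc = ", x$params$mnc,
      "; seed patterns: ", format(x$n_seeds, big.mark = ","),
      "; biclusters: ", length(x$biclusters), "\n", sep = "")
  nshow <- min(5L, length(x$biclusters))
  for (i in seq_len(nshow)) {
    b <- x$biclusters[[i]]
    cat("  [", i, "] ", length(b$rows), " x ", length(b$cols), ": rows {",
        paste(utils::head(x$row_names[b$rows], 8L), collapse = ", "),
        if (length(b$rows) > 8L) ", ..." else "", "}, cols {",
        paste(x$col_names[b$cols], collapse = ", "), "}\n", sep = "")
  }
  if (length(x$biclusters) > nshow) {
    cat("  ... and ", length(x$biclusters) - nshow, " more\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.bibit <- function(object, ...) {
  nr <- vapply(object$biclusters, function(b) length(b$rows), integer(1))
  nc <- vapply(object$biclusters, function(b) length(b$cols), integer(1))
  out <- list(n_biclusters = length(object$biclusters),
              n_seeds = object$n_seeds, dim = object$dim,
              rows_summary = if (length(nr)) summary(nr) else NULL,
              cols_summary = if (length(nc)) summary(nc) else NULL,
              params = object$params)
  class(out) <- "summary.bibit"
  out
}

#' @export
print.summary.bibit <- function(x, ...) {
  cat("Biclusters found: ", x$n_biclusters, " (from ",
      format(x$n_seeds, big.mark = ","), " seed patterns; matrix ",
      x$dim[1L], " x ", x$dim[2L], ", mnr = ", x$params$mnr, ", mnc = ",
      x$params$mnc, ")\n", sep = "")
  if (!is.null(x$rows_summary)) {
    cat("Rows per bicluster:\n"); print(x$rows_summary)
    cat("Columns per bicluster:\n"); print(x$cols_summary)
  }
  invisible(x)
}

#' @export
as.data.frame.bibit <- function(x, ...) {
  data.frame(
    nr = vapply(x$biclusters, function(b) length(b$rows), integer(1)),
    nc = vapply(x$biclusters, function(b) length(b$cols), integer(1)),
    rows = vapply(x$biclusters, function(b)
      paste(x$row_names[b$rows], collapse = ","), character(1)),
    cols = vapply(x$biclusters, function(b)
      paste(x$col_names[b$cols], collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}
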