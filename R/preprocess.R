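#' Binarize a real-valued matrix with a strict threshold
#'
#' Every value strictly greater than `threshold` becomes 1, every other
#' value 0 (ties go to 0).  Dimnames are preserved.
#'
#' @param x numeric matrix.
#' @param threshold binarization threshold.
#' @return an integer 0/1 matrix of the same shape.
#' @export
binarize <- function(x, threshold) {
  validate_raw_matrix(x)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  b <- (x > threshold) + 0L
  dimnames(b) <- dimnames(x)
  storage.mode(b) <- "integer"
  ensure_dimnames(b)
}

#' Standardize each row to mean zero and unit variance
#'
#' Gene-wise (per-row) standardization with the population standard
#' deviation (denominator `n`, not `n - 1`), the convention for
#' expression matrices where each row is one gene profile.
#'
#' @param x numeric matrix; every row must have nonzero variance.
#' @param axis `"row"` (default) or `"column"`.
#' @return a numeric matrix of the same shape with per-axis mean 0 and
#'   population variance 1.
#' @export
standardize <- function(x, axis = c("row", "column")) {
  axis <- match.arg(axis)
  validate_raw_matrix(x)
  x <- ensure_dimnames(x)
  if (axis == "column") return(t(standardize(t(x), axis = "row")))
  mu <- rowMeans(x)
  cx <- x - mu
  sdev <- sqrt(rowMeans(cx^2))
  if (any(sdev == 0)) {
    stop("constant rows cannot be standardized: ",
         paste(rownames(x)[sdev == 0], collapse = ", "), call. = FALSE)
  }
  cx / sdev
}

#' Discretize a matrix into L equal-width global levels
#'
#' Bins the matrix-global range \[min, max\] into `levels` equal-width
#' bins; a value `x` maps to `floor(levels * (x - min) / (max - min))`,
#' clamped to `levels - 1` so the maximum falls in the top bin.
#'
#' @param x numeric matrix with non-constant values.
#' @param levels number of levels `L >= 2` (default 12, the usual choice
#'   for expression data).
#' @return an integer matrix with entries in `0 .. levels - 1` and
#'   attribute `"levels"` set to `L`.
#' @export
discretize_levels <- function(x, levels = 12L) {
  validate_raw_matrix(x)
  x <- ensure_dimnames(x)
  levels <- as.integer(levels)
  stopifnot(levels >= 2L)
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) stop("cannot discretize a constant matrix (min == max)",
                     call. = FALSE)
  lv <- pmin(floor(levels * (x - lo) / (hi - lo)), levels - 1L)
  storage.mode(lv) <- "integer"
  dimnames(lv) <- dimnames(x)
  attr(lv, "levels") <- levels
  lv
}

#' Binary matrices from the level cuts of a discretized matrix
#'
#' For each cut `l` in `1 .. L-1` produces the binary matrix with a 1
#' wherever the level is `>= l`.  With the default 12 levels this yields
#' 11 nested binary matrices (each successive matrix elementwise
#' contained in the previous one), which are then biclustered
#' independently.
#'
#' @param lv an integer level matrix from [discretize_levels()].
#' @return a list of `L - 1` integer 0/1 matrices.
#' @export
level_threshold_matrices <- function(lv) {
  L <- attr(lv, "levels")
  if (is.null(L)) L <- max(lv) + 1L
  stopifnot(L >= 2L, all(lv >= 0L), all(lv <= L - 1L))
  lapply(seq_len(L - 1L), function(cut) {
    b <- (lv >= cut) + 0L
    storage.mode(b) <- "integer"
    dimnames(b) <- dimnames(lv)
    b
  })
}

#' Pack a binary matrix into fixed-width words
#'
#' Packs each row's `n` column bits into `ceiling(n / W)` unsigned
#' `W`-bit words, column `j` (1-based) occupying bit `(j-1) %% W`
#' (least-significant bit first) of word `(j-1) %/% W`; padding bits
#' beyond column `n` are zero.  Words are stored as raw bytes in
#' little-endian order, so the byte stream is the row's bit string
#' packed 8 bits per byte.
#'
#' @param x integer/numeric 0/1 matrix.
#' @param word_width word width in bits, 32 or 64.  The two widths give
#'   byte-identical results whenever the padded lengths agree; width is a
#'   performance knob only and never changes biclustering output.
#' @return an object of class `"bibit_encoded"`: a list with `words` (an
#'   `m x nbytes` raw matrix), `n`, `word_width`, `nwords`, `row_names`,
#'   `col_names`.
#' @export
encode_matrix <- function(x, word_width = 64L) {
  x <- as_binary_matrix(x)
  word_width <- as.integer(word_width)
  if (!word_width %in% c(32L, 64L)) {
    stop("word_width must be 32 or 64", call. = FALSE)
  }
  n <- ncol(x)
  m <- nrow(x)
  nwords <- ceiling(n / word_width)
  nbits <- nwords * word_width
  words <- matrix(as.raw(0), nrow = m, ncol = nbits %/% 8L)
  pad <- logical(nbits - n)
  for (i in seq_len(m)) {
    words[i, ] <- packBits(c(as.logical(x[i, ]), pad), type = "raw")
  }
  structure(
    list(words = words, n = n, word_width = word_width,
         nwords = as.integer(nwords),
         row_names = rownames(x), col_names = colnames(x)),
    class = "bibit_encoded"
  )
}

#' Unpack an encoded matrix back to its binary form
#'
#' Inverse of [encode_matrix()]: `decode_matrix(encode_matrix(x))` is
#' identical to `x`.
#'
#' @param enc a `"bibit_encoded"` object.
#' @return an integer 0/1 matrix with the original dimnames.
#' @export
decode_matrix <- function(enc) {
  stopifnot(inherits(enc, "bibit_encoded"))
  m <- nrow(enc$words)
  x <- matrix(0L, nrow = m, ncol = enc$n,
              dimnames = list(enc$row_names, enc$col_names))
  for (i in seq_len(m)) {
    bits <- as.integer(rawToBits(enc$words[i, ]))
    x[i, ] <- bits[seq_len(enc$n)]
  }
  x
}

#' @export
print.bibit_encoded <- function(x, ...) {
  cat("Encoded binary matrix: ", length(x$row_names), " rows x ", x$n,
      " columns (", x$nwords, " word", if (x$nwords != 1L) "s",
      " of ", x$word_width, " bits per row)\n", sep = "")
  invisible(x)
}

#' Count set bits in nonnegative integers
#'
#' @param x a numeric/integer vector of nonnegative integral values
#'   (exact up to 2^53), or a raw vector (counted byte-wise as one
#'   total).
#' @return integer vector of set-bit counts (a single total for raw
#'   input).
#' @export
popcount <- function(x) {
  if (is.raw(x)) return(sum(as.integer(rawToBits(x))))
  stopifnot(is.numeric(x), all(is.finite(x)), all(x >= 0),
            all(x == floor(x)), all(x < 2^53))
  cpp_popcount(as.numeric(x))
}
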