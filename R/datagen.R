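#' Seeded random binary matrix with optional implanted biclusters
#'
#' Generates an `m x n` matrix whose cells are independently one with
#' probability `p` (i.i.d. Bernoulli draws from R's Mersenne-Twister
#' stream, so a given seed reproduces the matrix bit-for-bit across runs
#' and platforms), then forces every implant's submatrix to all ones.
#' This emulates the benchmark inputs used to characterize the
#' algorithm: uniform random 0/1 matrices of 12,800-51,200 attributes,
#' 100-200 samples, and 10-15% ones.
#'
#' With `exact_density = TRUE` exactly `round(p * m * n)` ones are
#' placed uniformly at random instead (a sensitivity-check mode; the
#' default i.i.d. model is the study condition).
#'
#' @param m,n matrix dimensions.
#' @param p per-cell one-probability in `[0, 1]`.
#' @param seed RNG seed (required; the caller's RNG state is restored on
#'   exit).
#' @param implants optional list of implants, each a list with integer
#'   fields `rows` and `cols` (1-based index sets forced to one).
#' @param exact_density place an exact global count of ones instead of
#'   i.i.d. draws.
#' @return an integer 0/1 matrix with `"row0"`.../`"col0"`... dimnames.
#' @export
random_binary_matrix <- function(m, n, p, seed, implants = NULL,
                                 exact_density = FALSE) {
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(m >= 2L, n >= 1L, is.numeric(p), p >= 0, p <= 1,
            is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  if (isTRUE(exact_density)) {
    x <- matrix(0L, m, n)
    ones <- round(p * m * n)
    if (ones > 0L) x[sample.int(m * n, ones)] <- 1L
  } else {
    x <- matrix(rbinom(m * n, 1L, p), m, n)
  }
  storage.mode(x) <- "integer"
  if (!is.null(implants)) {
    for (im in implants) {
      rows <- as.integer(im$rows); cols <- as.integer(im$cols)
      if (anyNA(rows) || anyNA(cols) || length(rows) == 0L ||
          length(cols) == 0L || min(rows) < 1L || max(rows) > m ||
          min(cols) < 1L || max(cols) > n) {
        stop("implant indices out of bounds for a ", m, "x", n, " matrix",
             call. = FALSE)
      }
      x[rows, cols] <- 1L
    }
  }
  ensure_dimnames(x)
}

#' Zero-background implant recovery fixture
#'
#' Builds an `m x n` all-zero matrix with a single all-ones block in its
#' first `rows` rows and `cols` columns, together with the bicluster the
#' algorithm must recover.  On a zero background every cross-pair AND
#' pattern is empty, so at `mnc >= 1` the implant is the only reportable
#' bicluster.
#'
#' @param rows,cols implant dimensions (`2 <= rows <= m`,
#'   `1 <= cols <= n`).
#' @param m,n matrix dimensions.
#' @return a list with `matrix` (integer 0/1) and `expected` (a list
#'   with 1-based `rows` and `cols` of the implant).
#' @export
implant_recovery_case <- function(rows, cols, m, n) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  m <- as.integer(m); n <- as.integer(n)
  if (is.na(rows) || is.na(cols) || rows < 2L || rows > m || cols < 1L ||
      cols > n) {
    stop("need 2 <= rows <= m and 1 <= cols <= n", call. = FALSE)
  }
  x <- matrix(0L, m, n)
  x[seq_len(rows), seq_len(cols)] <- 1L
  list(matrix = ensure_dimnames(x),
       expected = list(rows = seq_len(rows), cols = seq_len(cols)))
}

#' Serialize a binary matrix as a dense ARFF fixture
#'
#' Writes a dense ARFF file in the orientation [read_arff()] expects:
#' one `@attribute <colname> numeric` declaration per matrix column and
#' one `@data` line per matrix row.  `read_arff()` on the result
#' reproduces the matrix exactly (row names are positional,
#' `"row0"`...).
#'
#' @param x integer/numeric 0/1 matrix.
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
write_fixture_arff <- function(x, path) {
  x <- as_binary_matrix(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("@relation bibitr_fixture", "",
               paste0("@attribute ", colnames(x), " numeric"), "",
               "@data",
               apply(x, 1L, paste, collapse = ",")),
             con, sep = "\n")
  invisible(path)
}
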