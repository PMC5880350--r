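## Shared input validation for the numeric-matrix and binary-matrix
## contracts.  Matrices are plain base R matrices carrying dimnames.

validate_raw_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 2L || ncol(x) < 1L) {
    stop(what, " must have at least 2 rows and 1 column (got ",
         nrow(x), "x", ncol(x), ")", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(what, " contains a non-finite value at row ", bad[[1L]],
         ", column ", bad[[2L]], call. = FALSE)
  }
  rn <- rownames(x)
  cn <- colnames(x)
  if (!is.null(rn) && anyDuplicated(rn)) {
    stop("duplicate row names: ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(cn) && anyDuplicated(cn)) {
    stop("duplicate column names: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

## Ensure dimnames exist, synthesizing 0-based "rowI"/"colJ" defaults so
## that fixtures and outputs are deterministic.
ensure_dimnames <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)) - 1L)
  if (is.null(colnames(x))) colnames(x) <- paste0("col", seq_len(ncol(x)) - 1L)
  x
}

is_binary_values <- function(x) all(x == 0 | x == 1)

validate_binary_matrix <- function(x, what = "binary matrix") {
  validate_raw_matrix(x, what)
  if (!is_binary_values(x)) {
    bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)[1L, ]
    stop(what, " has a value other than 0/1 at row ", bad[[1L]],
         ", column ", bad[[2L]], call. = FALSE)
  }
  invisible(x)
}

## Binary matrices are carried as integer storage internally.
as_binary_matrix <- function(x) {
  validate_binary_matrix(x)
  x <- ensure_dimnames(x)
  storage.mode(x) <- "integer"
  x
}
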