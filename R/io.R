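#' Read a data matrix from a dense ARFF file
#'
#' Reads a dense ARFF file into a numeric matrix for biclustering.  Each
#' `@data` line becomes one matrix row (one attribute of the biclustering
#' problem) and each declared ARFF attribute becomes one matrix column
#' (one sample); sample names are taken from the `@attribute`
#' declarations in file order and row names are synthesized as
#' `"row0"`, `"row1"`, ... .  Only numeric and `{0,1}` nominal attribute
#' types are accepted; sparse ARFF, strings and dates are rejected.
#'
#' This orientation (instances are attributes/rows of the biclustering
#' problem) can be flipped with `transpose = TRUE`, in which case ARFF
#' attributes become biclustering rows.
#'
#' @param path path to an ARFF file.
#' @param transpose flip the orientation (declared ARFF attributes become
#'   biclustering rows).
#' @return a numeric matrix with unique row and column names.
#' @seealso [read_delimited()], [write_fixture_arff()]
#' @export
read_arff <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  low <- tolower(trimws(lines))
  if (!any(startsWith(low, "@data"))) {
    stop("parse error in ", path, ": no @data section found (scanned ",
         length(lines), " lines)", call. = FALSE)
  }
  decl <- lines[startsWith(low, "@attribute")]
  if (any(grepl("\\b(string|date|relational)\\b",
                tolower(sub("^\\S+\\s+\\S+\\s*", "", decl))))) {
    stop("parse error in ", path,
         ": only numeric or {0,1} nominal attributes are supported",
         call. = FALSE)
  }
  first_data <- which(startsWith(low, "@data"))[1L]
  if (any(grepl("^\\{", trimws(lines[-seq_len(first_data)])))) {
    stop("parse error in ", path, ": sparse ARFF @data is not supported",
         call. = FALSE)
  }
  df <- foreign::read.arff(path)
  if (ncol(df) < 1L) stop("parse error in ", path, ": no attributes declared",
                          call. = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.factor(col)) {
      if (!all(levels(col) %in% c("0", "1"))) {
        stop("parse error in ", path, ": nominal attribute ", names(df)[j],
             " is not {0,1}", call. = FALSE)
      }
      col <- as.numeric(as.character(col))
    }
    if (!is.numeric(col)) {
      stop("parse error in ", path, ": attribute ", names(df)[j],
           " is not numeric", call. = FALSE)
    }
    if (anyNA(col)) {
      stop("parse error in ", path, ": missing or non-numeric value in column ",
           names(df)[j], " (data row ", which(is.na(col))[1L], ")",
           call. = FALSE)
    }
    df[[j]] <- col
  }
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  rownames(x) <- paste0("row", seq_len(nrow(x)) - 1L)
  if (isTRUE(transpose)) x <- t(x)
  x <- ensure_dimnames(x)
  validate_raw_matrix(x, paste0("matrix read from ", path))
  x
}

#' Read a data matrix from a delimited text file
#'
#' @param path path to the file.
#' @param delimiter single field-separator character (default tab).
#' @param has_header if `TRUE` the first line holds sample (column) names.
#' @param has_row_names if `TRUE` the first field of each data line holds
#'   the attribute (row) name.
#' @return a numeric matrix with unique row and column names; missing
#'   names are synthesized as `"row0"`.../`"col0"`... .
#' @export
read_delimited <- function(path, delimiter = "\t", has_header = FALSE,
                           has_row_names = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = delimiter, quote = "",
                            comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L) stop("empty file: ", path, call. = FALSE)
  body_nf <- if (has_header) nf[-1L] else nf
  if (length(body_nf) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (length(unique(nf)) > 1L &&
      !(has_header && has_row_names && length(unique(body_nf)) == 1L &&
        nf[1L] %in% c(body_nf[1L], body_nf[1L] - 1L))) {
    stop("parse error in ", path, ": rows have unequal field counts (",
         paste(unique(nf), collapse = ", "), ")", call. = FALSE)
  }
  df <- utils::read.table(path, sep = delimiter, header = has_header,
                          row.names = if (has_row_names) 1L else NULL,
                          check.names = FALSE, quote = "",
                          comment.char = "", colClasses = NA)
  x <- as.matrix(df)
  if (!is.numeric(x)) {
    stop("parse error in ", path, ": non-numeric value encountered",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!has_header) colnames(x) <- NULL
  if (!has_row_names) rownames(x) <- NULL
  x <- ensure_dimnames(x)
  validate_raw_matrix(x, paste0("matrix read from ", path))
  x
}

#' Write biclusters in the semicolon-separated interchange format
#'
#' Writes one line per bicluster with, separated by semicolons: `nr` (row
#' count), `nc` (column count), the `nr` attribute names of the
#' bicluster's rows in ascending row-index order, then the `nc` sample
#' names of the pattern's set columns in ascending column-index order.
#' Lines end with `"\n"`; there is no trailing semicolon.
#'
#' @param x a [bibit()] result, or a list of biclusters each with integer
#'   fields `rows` and `cols` (1-based indices into `row_names` /
#'   `col_names`).
#' @param path output file path.
#' @param row_names,col_names name vectors used to resolve indices; taken
#'   from `x` when it is a `bibit` result.
#' @return (invisibly) the number of lines written.
#' @export
write_biclusters <- function(x, path, row_names = NULL, col_names = NULL) {
  if (inherits(x, "bibit")) {
    row_names <- x$row_names
    col_names <- x$col_names
    bcs <- x$biclusters
  } else {
    bcs <- x
  }
  if (is.null(row_names) || is.null(col_names)) {
    stop("row_names and col_names are required", call. = FALSE)
  }
  lines <- vapply(bcs, function(b) {
    rows <- sort(as.integer(b$rows))
    cols <- sort(as.integer(b$cols))
    if (length(rows) && (min(rows) < 1L || max(rows) > length(row_names))) {
      stop("bicluster row index out of range 1..", length(row_names),
           call. = FALSE)
    }
    if (length(cols) && (min(cols) < 1L || max(cols) > length(col_names))) {
      stop("bicluster column index out of range 1..", length(col_names),
           call. = FALSE)
    }
    paste(c(length(rows), length(cols), row_names[rows], col_names[cols]),
          collapse = ";")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(length(lines))
}

## Parse the semicolon format back into (rows, cols) name lists; used by
## round-trip tests and the oracle CLI subcommand.
read_biclusters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, ";", fixed = TRUE)[[1L]]
    nr <- as.integer(parts[1L])
    nc <- as.integer(parts[2L])
    stopifnot(length(parts) == 2L + nr + nc)
    list(nr = nr, nc = nc,
         row_names = parts[2L + seq_len(nr)],
         col_names = parts[2L + nr + seq_len(nc)])
  })
}
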