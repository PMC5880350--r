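# The 5x4 worked-example matrix used throughout the tests.
toy_matrix <- function() {
  rbind(A = c(1, 1, 0, 1),
        B = c(1, 1, 1, 0),
        C = c(0, 1, 1, 1),
        D = c(1, 1, 1, 1),
        E = c(1, 0, 0, 0))
}

# Expected toy biclusters at mnr = 2, mnc = 2, in canonical pattern
# order (lexicographic on the column-bit string, column 1 first):
# 0101 < 0110 < 0111 < 1100 < 1101 < 1110.
toy_expected_mnr2 <- function() {
  list(list(rows = c(1L, 3L, 4L), cols = c(2L, 4L)),      # ACD x {2,4}
       list(rows = c(2L, 3L, 4L), cols = c(2L, 3L)),      # BCD x {2,3}
       list(rows = c(3L, 4L),     cols = c(2L, 3L, 4L)),  # CD  x {2,3,4}
       list(rows = c(1L, 2L, 4L), cols = c(1L, 2L)),      # ABD x {1,2}
       list(rows = c(1L, 4L),     cols = c(1L, 2L, 4L)),  # AD  x {1,2,4}
       list(rows = c(2L, 4L),     cols = c(1L, 2L, 3L)))  # BD  x {1,2,3}
}

toy_expected_mnr3 <- function() {
  keep <- vapply(toy_expected_mnr2(), function(b) length(b$rows) >= 3L,
                 logical(1))
  toy_expected_mnr2()[keep]
}

# Strip everything but (rows, cols) so result lists compare with
# identical().
bc_list <- function(res) {
  lapply(res$biclusters,
         function(b) list(rows = as.integer(b$rows),
                          cols = as.integer(b$cols)))
}

random_01 <- function(m, n, p) matrix(rbinom(m * n, 1L, p), m, n)

# Deterministic output file for byte-level comparisons.
run_to_file <- function(x, mnr, mnc, ...) {
  f <- tempfile(fileext = ".txt")
  write_biclusters(bibit(x, mnr = mnr, mnc = mnc, ...), f)
  f
}
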