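test_that("pair_pattern is the bitwise AND of two rows", {
  x <- rbind(c(1, 1, 0, 1), c(1, 1, 1, 0), c(0, 0, 1, 0))
  enc <- encode_matrix(x)
  p <- pair_pattern(enc, 1, 2)
  expect_identical(pattern_columns(p), c(1L, 2L))
  expect_identical(p$ones, 2L)
  p12 <- pair_pattern(enc, 2, 1)          # symmetric
  expect_identical(p$words, p12$words)

  dup <- encode_matrix(rbind(c(1, 1, 0, 1), c(1, 1, 0, 1)))
  pd <- pair_pattern(dup, 1, 2)           # AND idempotent on equal rows
  expect_identical(pattern_columns(pd), c(1L, 2L, 4L))
  expect_identical(pd$ones, 3L)

  dis <- encode_matrix(rbind(c(1, 0), c(0, 1)))
  expect_identical(pair_pattern(dis, 1, 2)$ones, 0L)

  expect_error(pair_pattern(enc, 2, 2), "distinct")
  expect_error(pair_pattern(enc, 1, 9), "distinct|1\\.\\.")
})

test_that("seeding keeps one seed per distinct qualifying pattern", {
  enc <- encode_matrix(toy_matrix())
  seeds <- initialize_biclusters(enc, mnc = 2)
  expect_identical(nrow(seeds$patterns), 6L)
  got <- apply(seeds$patterns, 1L, function(w)
    paste(as.integer(rawToBits(w))[1:4], collapse = ""))
  expect_setequal(got, c("1100", "0101", "1101", "0110", "1110", "0111"))
  # every seed pattern really is the AND of its recorded pair
  for (i in seq_len(nrow(seeds$patterns))) {
    p <- pair_pattern(enc, seeds$seed_rows[i, 1], seeds$seed_rows[i, 2])
    expect_identical(as.raw(seeds$patterns[i, ]), p$words)
  }

  expect_identical(nrow(initialize_biclusters(enc, mnc = 5)$patterns), 0L)

  ones <- encode_matrix(matrix(1L, 3, 4))
  s1 <- initialize_biclusters(ones, mnc = 2)
  expect_identical(nrow(s1$patterns), 1L)
  expect_identical(s1$ones, 4L)
})

test_that("completion returns all containing rows or a discard", {
  enc <- encode_matrix(toy_matrix())
  p <- pair_pattern(enc, 1, 2)                      # pattern {1,2}
  expect_identical(complete_bicluster(enc, p, mnr = 2), c(1L, 2L, 4L))
  expect_null(complete_bicluster(enc, p, mnr = 4))
  ones <- encode_matrix(matrix(1L, 3, 4))
  expect_identical(complete_bicluster(ones, pair_pattern(ones, 1, 2), 2),
                   1:3)
})

test_that("the toy matrix yields the worked-example biclusters", {
  res2 <- bibit(toy_matrix(), mnr = 2, mnc = 2)
  expect_identical(bc_list(res2), toy_expected_mnr2())
  res3 <- bibit(toy_matrix(), mnr = 3, mnc = 2)
  expect_identical(bc_list(res3), toy_expected_mnr3())
})

test_that("reported biclusters are valid, complete, unique and thresholded", {
  set.seed(61)
  for (t in 1:25) {
    m <- sample(4:40, 1); n <- sample(2:16, 1)
    p <- runif(1, 0.2, 0.8)
    mnr <- sample(2:4, 1); mnc <- sample(1:3, 1)
    x <- random_01(m, n, p)
    res <- bibit(x, mnr, mnc)
    keys <- character(0)
    for (b in res$biclusters) {
      expect_true(all(x[b$rows, b$cols] == 1))            # all-ones
      expect_gte(length(b$rows), mnr)
      expect_gte(length(b$cols), mnc)
      outside <- setdiff(seq_len(m), b$rows)
      if (length(outside)) {                              # row-complete
        contains <- rowSums(x[outside, b$cols, drop = FALSE]) ==
          length(b$cols)
        expect_false(any(contains))
      }
      keys <- c(keys, paste(b$cols, collapse = ","))
    }
    expect_false(anyDuplicated(keys) > 0)                 # unique patterns
  }
})

test_that("vectorized completion agrees with the direct row scan", {
  set.seed(71)
  for (t in 1:10) {
    x <- random_01(30, 12, runif(1, 0.3, 0.7))
    enc <- encode_matrix(x)
    seeds <- initialize_biclusters(enc, mnc = 2)
    res <- bibit(x, mnr = 2, mnc = 2)
    got <- bc_list(res)
    scan <- list()
    for (i in seq_len(nrow(seeds$patterns))) {
      pat <- as.raw(seeds$patterns[i, ])
      rows <- complete_bicluster(enc, pat, mnr = 2)
      if (!is.null(rows)) {
        scan[[length(scan) + 1L]] <-
          list(rows = rows, cols = pattern_columns(pat, n = 12L))
      }
    }
    expect_identical(got, scan)  # seeds are already canonically ordered
  }
})

test_that("row and column permutations act equivariantly on the output", {
  set.seed(81)
  x <- random_01(20, 10, 0.5)
  dimnames(x) <- list(paste0("g", 1:20), paste0("s", 1:10))
  res <- bibit(x, 2, 2)
  pr <- sample(20); pc <- sample(10)
  resp <- bibit(x[pr, pc], 2, 2)
  named <- function(r) {
    out <- lapply(r$biclusters, function(b)
      list(rows = sort(r$row_names[b$rows]), cols = sort(r$col_names[b$cols])))
    out[order(vapply(out, function(b) paste(c(b$cols, b$rows), collapse = ";"),
                     character(1)))]
  }
  expect_identical(named(res), named(resp))
})

test_that("rows with fewer than mnc ones can be removed without effect", {
  set.seed(91)
  x <- random_01(30, 8, 0.25)
  mnc <- 3L
  keep <- rowSums(x) >= mnc
  keep_idx <- which(keep)
  res_all <- bibit(x, 2, mnc)
  res_kept <- bibit(x[keep, , drop = FALSE], 2, mnc)
  remap <- lapply(res_kept$biclusters, function(b)
    list(rows = keep_idx[b$rows], cols = b$cols))
  expect_identical(bc_list(res_all),
                   lapply(remap, function(b)
                     list(rows = as.integer(b$rows),
                          cols = as.integer(b$cols))))
})

test_that("parameter validation rejects degenerate settings", {
  x <- toy_matrix()
  expect_error(bibit(x, mnr = 1, mnc = 2), "mnr")
  expect_error(bibit(x, mnr = 2, mnc = 0), "mnc")
  expect_error(bibit(x, mnr = 2, mnc = 2, word_width = 16), "word_width")
  expect_error(bibit(x, mnr = 2, mnc = 2, workers = 0), "workers")
  expect_error(bibit(matrix(0.5, 3, 3), 2, 1), "threshold")
  expect_identical(bc_list(bibit(matrix(0.7, 3, 3), 2, 1, threshold = 0.5)),
                   list(list(rows = 1:3, cols = 1:3)))
})
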