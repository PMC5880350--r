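test_that("binarize uses a strict threshold and is monotone", {
  x <- rbind(c(0.2, 0.9), c(1.5, -1.0))
  expect_identical(unname(binarize(x, 0.5)), rbind(c(0L, 1L), c(1L, 0L)))
  expect_true(all(binarize(x, max(x)) == 0L))            # ties go to 0
  b <- rbind(c(0, 1), c(1, 0))
  expect_identical(unname(binarize(b, 0.5)), rbind(c(0L, 1L), c(1L, 0L)))
  set.seed(21)
  y <- matrix(runif(200, -1, 1), 20, 10)
  thr <- sort(runif(5, -1, 1))
  for (i in seq_len(length(thr) - 1L)) {
    lo <- binarize(y, thr[i])
    hi <- binarize(y, thr[i + 1L])
    expect_true(all(hi <= lo))  # raising the threshold never creates a 1
  }
})

test_that("standardize centers rows with the population sd", {
  x <- rbind(a = c(1, 2, 3), b = c(10, 20, 60))
  s <- standardize(x)
  expect_equal(s["a", ], c(-1.224745, 0, 1.224745),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(s)) < 1e-9))
  expect_true(all(abs(rowMeans(s^2) - 1) < 1e-9))   # population variance
  expect_equal(standardize(s), s, tolerance = 1e-9) # idempotent
  expect_error(standardize(rbind(a = c(5, 5, 5), b = c(1, 2, 3))), "a")
})

test_that("discretize_levels bins the global range with clamping", {
  x <- matrix(0:11, 2, 6)
  lv <- discretize_levels(x, 12)
  expect_identical(as.vector(lv), 0:11)
  expect_identical(max(lv), 11L)                      # max clamped to L-1
  y <- matrix(c(0, 4.9, 5.1, 10), 2, 2)
  lv2 <- discretize_levels(y, 2)
  expect_identical(as.vector(lv2), c(0L, 0L, 1L, 1L))
  expect_error(discretize_levels(matrix(3, 2, 2), 12), "constant")
})

test_that("level cuts give L-1 nested binary matrices", {
  set.seed(31)
  x <- matrix(rnorm(60), 6, 10)
  lv <- discretize_levels(x, 12)
  cuts <- level_threshold_matrices(lv)
  expect_length(cuts, 11L)
  for (l in seq_len(10L)) {
    expect_true(all(cuts[[l + 1L]] <= cuts[[l]]))  # nested
    expect_identical(unname(cuts[[l]]), unname((lv >= l) + 0L))
  }
  hi <- matrix(11L, 3, 3)
  attr(hi, "levels") <- 12L
  expect_true(all(vapply(level_threshold_matrices(hi),
                         function(m) all(m == 1L), logical(1))))
  lo <- matrix(0L, 3, 3)
  attr(lo, "levels") <- 12L
  expect_true(all(vapply(level_threshold_matrices(lo),
                         function(m) all(m == 0L), logical(1))))
})

test_that("encoding packs LSB-first with zero padding and decodes exactly", {
  x <- rbind(c(1, 1, 0, 1), c(0, 0, 0, 0))
  enc <- encode_matrix(x, 32)
  expect_identical(enc$nwords, 1L)
  # bits 0,1,3 set -> first byte 0b00001011 = 11, rest zero padding
  expect_identical(as.integer(enc$words[1, ]), c(11L, 0L, 0L, 0L))
  expect_true(all(enc$words[2, ] == as.raw(0)))

  set.seed(41)
  wide <- random_01(3, 33, 0.5)
  e32 <- encode_matrix(wide, 32)
  expect_identical(e32$nwords, 2L)
  one33 <- matrix(0L, 2, 33); one33[, 33] <- 1L
  e <- encode_matrix(one33, 32)
  expect_identical(as.integer(e$words[1, 5]), 1L)  # bit 0 of word 1

  for (W in c(32L, 64L)) {
    for (n in c(1L, 7L, 31L, 32L, 33L, 64L, 65L, 100L)) {
      m <- random_01(5, n, 0.5)
      storage.mode(m) <- "integer"
      m <- bibitr:::ensure_dimnames(m)
      expect_identical(decode_matrix(encode_matrix(m, W)), m)
    }
  }
})

test_that("popcount counts set bits and respects the AND/OR identity", {
  expect_identical(popcount(c(0, 11, 2^32 - 1)), c(0L, 3L, 32L))
  expect_identical(popcount(as.raw(c(0x0b, 0x00))), 3L)
  set.seed(51)
  a <- sample.int(2^30, 50)
  b <- sample.int(2^30, 50)
  expect_identical(popcount(a) + popcount(b),
                   popcount(bitwAnd(a, b)) + popcount(bitwOr(a, b)))
})
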