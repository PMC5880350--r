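test_that("random_binary_matrix honors p, seed and implants", {
  expect_true(all(random_binary_matrix(10, 10, 0, seed = 1) == 0L))
  expect_true(all(random_binary_matrix(10, 10, 1, seed = 1) == 1L))

  x <- random_binary_matrix(1000, 100, 0.1, seed = 7)
  # binomial concentration: 4 sd over 100,000 cells
  expect_lt(abs(mean(x) - 0.1), 4 * sqrt(0.1 * 0.9 / 1e5))

  expect_identical(random_binary_matrix(50, 20, 0.3, seed = 9),
                   random_binary_matrix(50, 20, 0.3, seed = 9))
  expect_false(identical(random_binary_matrix(50, 20, 0.3, seed = 9),
                         random_binary_matrix(50, 20, 0.3, seed = 10)))

  # implant dominance regardless of background draws
  im <- list(rows = 3:7, cols = 2:4)
  x <- random_binary_matrix(20, 10, 0.2, seed = 11, implants = list(im))
  expect_true(all(x[im$rows, im$cols] == 1L))
  expect_error(random_binary_matrix(5, 5, 0.1, seed = 1,
                                    implants = list(list(rows = 1:9,
                                                         cols = 1))),
               "out of bounds")

  xe <- random_binary_matrix(40, 25, 0.13, seed = 13, exact_density = TRUE)
  expect_identical(sum(xe), as.integer(round(0.13 * 40 * 25)))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(42)
  a <- runif(1)
  set.seed(42)
  invisible(random_binary_matrix(10, 10, 0.5, seed = 99))
  expect_identical(runif(1), a)
})

test_that("implant recovery cases return exactly the implant", {
  case <- implant_recovery_case(5, 3, 20, 10)
  res <- bibit(case$matrix, mnr = 5, mnc = 3)
  expect_length(res$biclusters, 1L)
  expect_identical(res$biclusters[[1L]]$rows, case$expected$rows)
  expect_identical(res$biclusters[[1L]]$cols, case$expected$cols)

  res6 <- bibit(case$matrix, mnr = 6, mnc = 3)   # implant has only 5 rows
  expect_length(res6$biclusters, 0L)

  tiny <- implant_recovery_case(2, 1, 4, 4)
  res2 <- bibit(tiny$matrix, mnr = 2, mnc = 1)
  expect_identical(bc_list(res2), list(list(rows = 1:2, cols = 1L)))

  expect_error(implant_recovery_case(1, 3, 20, 10), "rows")
  expect_error(implant_recovery_case(5, 11, 20, 10), "rows|cols")
})

test_that("ARFF fixture writer round-trips generated matrices", {
  x <- random_binary_matrix(100, 64, 0.35, seed = 17)
  f <- tempfile(fileext = ".arff")
  write_fixture_arff(x, f)
  got <- read_arff(f)
  storage.mode(got) <- "integer"
  expect_identical(unname(got), unname(x))
  expect_identical(colnames(got), colnames(x))
})
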