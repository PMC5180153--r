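test_that("NODF endpoints: perfect staircase, identity, full matrix", {
  expect_identical(nodf(max_nested_matrix(10, 10, 55)), 1)
  expect_identical(nodf(diag(2)), 0)          # equal degrees, no overlap
  expect_identical(nodf(matrix(1, 3, 3)), 0)  # all degrees tied
  expect_error(nodf(matrix(0, 3, 3)), "all-zero")
  expect_error(nodf(matrix(c(0, 2), 1, 2)), "binary")
})

test_that("nodf agrees with the pairwise-overlap oracle on all small matrices", {
  for (M in all_binary_matrices(2, 2)) {
    expect_equal(nodf(M), nodf_oracle(M))
  }
  for (M in all_binary_matrices(3, 3)) {
    expect_equal(nodf(M), nodf_oracle(M))
  }
  for (M in all_binary_matrices(2, 4)) {
    expect_equal(nodf(M), nodf_oracle(M))
  }
  set.seed(41)
  for (i in 1:500) {
    M <- matrix(rbinom(16, 1, runif(1, 0.2, 0.8)), 4, 4)
    if (sum(M) == 0) next
    expect_equal(nodf(M), nodf_oracle(M))
  }
})

test_that("nodf matches vegan's NODF on random matrices", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (i in 1:20) {
    M <- matrix(rbinom(100, 1, 0.3), 10, 10)
    if (any(rowSums(M) == 0) || any(colSums(M) == 0)) next
    ref <- unname(vegan::nestednodf(M, order = TRUE)$statistic["NODF"])
    expect_equal(nodf(M), ref / 100, tolerance = 1e-10)
  }
})

test_that("nodf is invariant under row and column permutations", {
  set.seed(11)
  M <- random_infection_matrix(8, 6, 20, seed = 11)
  for (i in 1:10) {
    Mp <- M[sample(8), sample(6)]
    expect_equal(nodf(Mp), nodf(M))
  }
})

test_that("no matrix beats the staircase at its own shape and fill", {
  # exhaustively at 3x3, by random search at 10x10
  for (fill in 5:9) {
    cap <- nodf(max_nested_matrix(3, 3, fill))
    for (M in all_binary_matrices(3, 3)) {
      if (sum(M) != fill) next
      expect_lte(nodf(M), cap + 1e-12)
    }
  }
  cap20 <- nodf(max_nested_matrix(10, 10, 20))
  set.seed(5)
  for (i in 1:50) {
    M <- random_infection_matrix(10, 10, 20, seed = i)
    expect_lte(nodf(M), cap20 + 1e-12)
  }
})

test_that("max_nested_matrix handles boundary fills and rejects infeasible ones", {
  expect_identical(max_nested_matrix(2, 2, 3),
                   matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_identical(max_nested_matrix(3, 3, 9), matrix(1, 3, 3))
  M <- max_nested_matrix(10, 10, 20)
  expect_identical(sum(M), 20)
  expect_true(all(rowSums(M) > 0) && all(colSums(M) > 0))
  expect_error(max_nested_matrix(3, 3, 4), "infeasible")
  expect_error(max_nested_matrix(3, 3, 10), "infeasible")
})

test_that("modular matrices are block-diagonal with conserved fill", {
  M <- modular_matrix(10, 10, 5)
  expect_identical(sum(M), 20)
  expect_identical(M[1:2, 1:2], matrix(1, 2, 2))
  expect_identical(sum(M[1:2, 3:10]), 0)
  expect_lt(nodf(M), 0.4)
  M2 <- modular_matrix(4, 4, 2)
  expect_identical(sum(M2), 8)
  expect_error(modular_matrix(4, 4, 5), "n_modules")
})

test_that("nestedness ensembles span the spectrum monotonically and reproducibly", {
  ens <- nestedness_ensemble(10, 10, 5, n_matrices = 25, seed = 21)
  expect_length(ens$matrices, 25)
  expect_false(is.unsorted(ens$nodf_values))
  expect_lt(ens$nodf_values[1], 0.4)
  expect_equal(ens$nodf_values[25], nodf(max_nested_matrix(10, 10, 20)),
               tolerance = 1e-12)
  fills <- vapply(ens$matrices, sum, 0)
  expect_true(all(fills == 20))
  for (M in ens$matrices) {
    expect_true(all(rowSums(M) > 0) && all(colSums(M) > 0))
  }
  expect_equal(ens$nodf_values, vapply(ens$matrices, nodf, 0))
  ens2 <- nestedness_ensemble(10, 10, 5, n_matrices = 25, seed = 21)
  expect_identical(ens, ens2)
})

test_that("ensembles round-trip through the CSV + JSON directory format", {
  dir <- withr::local_tempdir()
  ens <- nestedness_ensemble(6, 6, 3, n_matrices = 5, seed = 2)
  write_ensemble(ens, dir)
  back <- read_ensemble(dir)
  for (k in 1:5) {
    Mk <- back$matrices[[k]]
    attr(Mk, "kind") <- NULL
    expect_equal(Mk, ens$matrices[[k]])
  }
  expect_equal(back$nodf_values, ens$nodf_values)
})
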