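make_ts <- function(times, H, V) {
  structure(list(times = times, H = H, V = V,
                 meta = list(dt = diff(times)[1], T = max(times),
                             snr_db = Inf)),
            class = "community_ts")
}

test_that("regression assembly has the documented shape and conventions", {
  M <- random_infection_matrix(10, 10, 20, seed = 1)
  params <- feasible_parameters(M, seed = 2)
  ts <- simulate_community(params, M, experiment_design(dt = 0.1, T = 96),
                           seed = 3)
  sys <- build_regression(ts)
  expect_identical(dim(sys$W), c(10L, 960L))
  expect_identical(dim(sys$H_aug), c(11L, 960L))
  expect_true(all(sys$H_aug[11, ] == 1))
  expect_equal(sys$H_aug[1:10, 1], (ts$H[, 1] + ts$H[, 2]) / 2)
  left <- build_regression(ts, hosts = "left")
  expect_equal(left$H_aug[1:10, ], ts$H[, 1:960])
  # W does not depend on the host convention
  expect_identical(left$W, sys$W)
  expect_equal(sys$W[, 1],
               (log(ts$V[, 2]) - log(ts$V[, 1])) / 0.1)
})

test_that("degenerate series are rejected or give zero log-derivatives", {
  flat <- make_ts((0:10) * 0.5, matrix(1e3, 2, 11), matrix(1e6, 2, 11))
  sys <- build_regression(flat)
  expect_true(all(sys$W == 0))
  bad <- flat
  bad$V[1, 4] <- 0
  expect_error(build_regression(bad), "positive")
  expect_error(build_regression(make_ts(0, matrix(1, 1, 1), matrix(1, 1, 1))),
               "2 samples")
})

test_that("log-differences of an exponential decay are exact at any step", {
  m <- 0.37
  times <- (0:40) * 0.7
  V <- matrix(2e6 * exp(-m * times), 1)
  H <- matrix(1e3 * exp(0.05 * times), 1)
  sys <- build_regression(make_ts(times, H, V))
  expect_equal(as.vector(sys$W), rep(-m, 40), tolerance = 1e-12)
})

test_that("concatenation is the identity for one block and sums columns", {
  sys <- small_system(seed = 4)
  d <- experiment_design(dt = 0.1, T = 4.8)
  blocks <- lapply(1:20, function(e) {
    build_regression(simulate_community(sys$params, sys$M, d, seed = 100 + e))
  })
  expect_identical(concat_regressions(blocks[1]), blocks[[1]])
  all20 <- concat_regressions(blocks)
  expect_identical(ncol(all20$W), 960L)
  expect_identical(ncol(all20$H_aug), 960L)
  expect_true(all(all20$H_aug[nrow(all20$H_aug), ] == 1))
  expect_identical(all20$W[, 49:96], blocks[[2]]$W)

  # the solver's optimum is invariant under block reordering
  fwd <- solve_network(all20)
  rev_ <- solve_network(concat_regressions(rev(blocks)))
  expect_equal(rev_$objective, fwd$objective, tolerance = 1e-8)
  expect_equal(rev_$M_tilde, fwd$M_tilde, tolerance = 1e-6)

  expect_error(concat_regressions(list(blocks[[1]],
                                       build_regression(simulate_community(
                                         feasible_parameters(modular_matrix(6, 6, 3), seed = 1),
                                         modular_matrix(6, 6, 3), d, seed = 2)))),
               "mismatch")
})

test_that("exact analytic derivatives are recovered to working precision", {
  # with W built from the true linear relation, constrained least squares
  # must attain zero residual at the truth
  set.seed(6)
  n_h <- 6; n_v <- 5
  M <- random_infection_matrix(n_h, n_v, 14, seed = 6)
  M_tilde <- M * matrix(runif(n_h * n_v, 1e-7, 5e-6), n_h, n_v)
  m <- runif(n_v, 0.01, 0.5)
  H <- matrix(runif(n_h * 80, 1e3, 1e4), n_h)
  sys <- structure(list(W = crossprod(M_tilde, H) - m,
                        H_aug = rbind(H, 1), hosts = "midpoint",
                        block_cols = 80L),
                   class = "regression_system")
  sol <- solve_network(sys)
  expect_equal(sol$M_tilde, M_tilde, tolerance = 1e-8)
  expect_equal(sol$m, m, tolerance = 1e-8)
  expect_lt(sol$objective, 1e-16)
})

test_that("zero log-derivatives yield the zero network", {
  set.seed(7)
  H <- matrix(runif(240, 1e3, 1e4), 3)
  sys <- structure(list(W = matrix(0, 4, 80), H_aug = rbind(H, 1),
                        hosts = "midpoint", block_cols = 80L),
                   class = "regression_system")
  sol <- solve_network(sys)
  expect_identical(sol$M_tilde, matrix(0, 3, 4))
  expect_identical(sol$m, rep(0, 4))
})

test_that("the active-set solver matches brute-force enumeration and pracma", {
  set.seed(8)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    C <- matrix(rnorm(12 * n), 12, n)
    x_true <- ifelse(runif(n) < 0.5, 0, runif(n, 0.5, 2))
    d <- drop(C %*% x_true) + rnorm(12, 0, 0.3)
    got <- phagenet:::nnls_solve(C, d)
    oracle <- nnls_oracle(C, d)
    expect_equal(got$objective, oracle$obj, tolerance = 1e-9)
    expect_equal(got$x, oracle$x, tolerance = 1e-6)
    expect_true(all(got$x >= 0))
  }
  skip_if_not_installed("pracma")
  set.seed(9)
  for (i in 1:20) {
    C <- matrix(rnorm(60), 12, 5)
    d <- rnorm(12)
    got <- phagenet:::nnls_solve(C, d)
    ref <- pracma::lsqnonneg(C, d)
    expect_equal(got$x, ref$x, tolerance = 1e-8)
  }
})

test_that("underdetermined and rank-deficient designs raise warnings", {
  set.seed(10)
  H3 <- matrix(runif(9, 1e3, 1e4), 3)  # 3 columns < 3 hosts + 1 coefficients
  sysU <- structure(list(W = matrix(0.1, 2, 3), H_aug = rbind(H3, 1),
                         hosts = "midpoint", block_cols = 3L),
                    class = "regression_system")
  expect_warning(expect_warning(solve_network(sysU), "underdetermined"),
                 "rank deficient")

  H4 <- matrix(runif(8, 1e3, 1e4), 2)
  Hdup <- rbind(H4[1, ], H4[1, ], H4[2, ], 1)  # duplicated host row
  sysD <- structure(list(W = matrix(0.1, 2, 4), H_aug = Hdup,
                         hosts = "midpoint", block_cols = 4L),
                    class = "regression_system")
  expect_warning(solve_network(sysD), "rank deficient")
})

test_that("the error metric behaves like a normalized distance", {
  Mt <- matrix(c(0, 2e-6, 1e-7, 0), 2, 2)
  expect_identical(reconstruction_error(Mt, Mt), 0)
  expect_identical(reconstruction_error(Mt, 0 * Mt), 1)
  expect_identical(reconstruction_error(Mt, 2 * Mt), 1)
  expect_error(reconstruction_error(Mt, matrix(0, 3, 2)), "shape")
  expect_error(reconstruction_error(0 * Mt, Mt), "zero norm")
})
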