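test_that("perturbed initial states follow the two-point displacement law", {
  expect_equal(perturbed_initial_state(c(1e3, 2e3), 1e6, 0, seed = 1),
               list(h = c(1e3, 2e3), v = 1e6))
  st <- perturbed_initial_state(rep(1e4, 50), rep(1e6, 50), 0.5, seed = 2)
  expect_true(all(st$h %in% c(5e3, 1.5e4)))
  expect_true(all(st$v %in% c(5e5, 1.5e6)))
  expect_identical(st, perturbed_initial_state(rep(1e4, 50), rep(1e6, 50),
                                               0.5, seed = 2))
  expect_error(perturbed_initial_state(1e4, 1e6, 1), "delta")
  expect_error(perturbed_initial_state(1e4, 1e6, -0.1), "delta")
})

test_that("displacement signs are balanced", {
  st <- perturbed_initial_state(rep(1, 10000), numeric(0), 0.5, seed = 3)
  frac_up <- mean(st$h > 1)
  expect_gt(frac_up, 0.48)
  expect_lt(frac_up, 0.52)
})

test_that("the integrator holds a feasible equilibrium for 96 hours", {
  M <- random_infection_matrix(10, 10, 20, seed = 4)
  params <- feasible_parameters(M, seed = 44)
  ts <- integrate_and_sample(params, M,
                             list(h = params$H_star, v = params$V_star),
                             dt = 0.5, T = 96)
  rel_h <- abs(ts$H / params$H_star - 1)
  rel_v <- abs(ts$V / params$V_star - 1)
  expect_lt(max(rel_h, rel_v), 1e-6)
})

test_that("an unattacked virus decays exponentially on the sample grid", {
  # M = 1 but phi = 0 decouples the virus; closed form v(t) = v0 exp(-m t)
  p <- system_params(r = 0.3, a = matrix(1, 1, 1), K = 1e6,
                     phi = matrix(0, 1, 1), beta = matrix(20, 1, 1),
                     m = 0.5, H_star = 1e4, V_star = 1e6)
  ts <- integrate_and_sample(p, matrix(1, 1, 1),
                             list(h = 5e3, v = 2e6), dt = 0.25, T = 12)
  expect_equal(as.vector(ts$V), 2e6 * exp(-0.5 * ts$times),
               tolerance = 1e-6)
})

test_that("the sampling grid is exact arithmetic regardless of solver steps", {
  sys <- small_system(seed = 5)
  ts <- simulate_community(sys$params, sys$M,
                           experiment_design(dt = 0.1, T = 96), seed = 6)
  expect_length(ts$times, 961)
  expect_identical(ts$times, (0:960) * 0.1)
  expect_true(all(ts$H > 0) && all(ts$V > 0))
})

test_that("infinite SNR leaves a series untouched and finite SNR hits its target", {
  sys <- small_system(seed = 7)
  ts <- simulate_community(sys$params, sys$M,
                           experiment_design(dt = 0.1, T = 72), seed = 8)
  expect_identical(add_measurement_noise(ts, Inf, seed = 1), ts)
  noisy <- add_measurement_noise(ts, 20, seed = 9)
  expect_identical(noisy, add_measurement_noise(ts, 20, seed = 9))
  expect_true(all(noisy$H > 0) && all(noisy$V > 0))

  # estimator concentration, checked on series of bounded dynamic range
  # where the clipping floor never engages: empirical SNR of each
  # injected-noise series within 0.5 dB of the requested value
  times <- (0:800) * 0.1
  smooth <- structure(list(
    times = times,
    H = rbind(1e4 * (1 + 0.4 * sin(0.2 * times)),
              3e3 * (1 + 0.4 * cos(0.13 * times))),
    V = rbind(2e6 * (1 + 0.4 * sin(0.08 * times + 1)),
              8e6 * (1 + 0.4 * cos(0.21 * times))),
    meta = list(dt = 0.1, T = 80, snr_db = Inf)), class = "community_ts")
  corrupted <- add_measurement_noise(smooth, 20, seed = 10)
  for (nm in c("H", "V")) {
    for (i in 1:2) {
      clean <- smooth[[nm]][i, ]
      snr_hat <- 10 * log10(mean(clean^2) /
                              mean((corrupted[[nm]][i, ] - clean)^2))
      expect_lt(abs(snr_hat - 20), 0.5)
    }
  }
})

test_that("10 dB noise injects one tenth of the signal power", {
  sys <- small_system(seed = 10)
  ts <- simulate_community(sys$params, sys$M,
                           experiment_design(dt = 0.05, T = 96), seed = 11)
  noisy <- add_measurement_noise(ts, 10, seed = 12, targets = "viruses")
  expect_identical(noisy$H, ts$H)  # hosts untouched in viruses-only mode
  ratio <- mean((noisy$V[1, ] - ts$V[1, ])^2) / mean(ts$V[1, ]^2)
  expect_equal(ratio, 0.1, tolerance = 0.05)
})

test_that("heavy noise is clipped to a positive floor", {
  sys <- small_system(seed = 13)
  ts <- simulate_community(sys$params, sys$M,
                           experiment_design(dt = 0.1, T = 24), seed = 14)
  noisy <- add_measurement_noise(ts, -20, seed = 15)
  expect_true(all(noisy$H > 0) && all(noisy$V > 0))
  expect_gte(min(noisy$V[1, ]), 1e-6 * min(ts$V[1, ]))
})

test_that("simulations with the same seed are bit-reproducible", {
  sys <- small_system(seed = 16)
  d <- experiment_design(dt = 0.2, T = 48, snr_db = 25)
  a <- simulate_community(sys$params, sys$M, d, seed = 17)
  b <- simulate_community(sys$params, sys$M, d, seed = 17)
  expect_identical(a, b)
})
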