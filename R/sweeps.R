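# In silico evaluation protocols: reconstruction error over matrix ensembles
# as a function of perturbation size, experiment count, sampling design and
# measurement noise.  Every sweep is a pure function of (ensemble, design,
# seed): sub-seeds for parameter draws, initial conditions and noise are
# derived from the master seed with seed_array(), so reruns are
# bit-reproducible.  Comparisons across a grid are paired: each matrix gets
# one pool of initial-condition seeds reused at every grid point (the same
# replicate experiments evaluated under every design), so the grid effect is
# not confounded with initial-condition resampling; only the injected
# measurement noise is redrawn per grid point.

ensemble_matrices <- function(ensemble) {
  if (inherits(ensemble, "matrix_ensemble")) {
    ensemble$matrices
  } else if (is.list(ensemble)) {
    lapply(ensemble, function(M) {
      validate_infection_matrix(M)
      M
    })
  } else {
    stop_input("'ensemble' must be a matrix_ensemble or a list of infection matrices")
  }
}

# One reconstruction under a given design: p experiments differing only in
# their initial-condition seed, n_cols regression columns kept per
# experiment, optional measurement noise, concatenated and solved.
run_design <- function(M, params, delta, dt, n_cols, p, snr_db, ic_seeds,
                       noise_seeds = ic_seeds + 1L, hosts = "midpoint") {
  systems <- vector("list", p)
  for (e in seq_len(p)) {
    init <- perturbed_initial_state(params$H_star, params$V_star, delta,
                                    seed = ic_seeds[e])
    ts <- integrate_and_sample(params, M, init, dt = dt, T = n_cols * dt)
    if (is.finite(snr_db)) {
      ts <- add_measurement_noise(ts, snr_db, seed = noise_seeds[e])
    }
    systems[[e]] <- build_regression(ts, hosts = hosts)
  }
  fit_infection_network(concat_regressions(systems),
                        truth = quantitative_network(M, params))
}

sweep_result <- function(axis, grid, errs, meta) {
  structure(list(
    axis = axis, grid = grid,
    per_matrix_errors = errs,
    mean_error = colMeans(errs, na.rm = TRUE),
    sd_error = apply(errs, 2L, stats::sd, na.rm = TRUE),
    meta = meta
  ), class = "infnet_sweep")
}

# Shared scaffolding: draw per-matrix feasible parameters, loop over a grid,
# catch per-run failures as NA.  `ic` hands the body the per-matrix pool of
# initial-condition seeds (constant across the grid) and `noise` a grid-
# specific seed vector for measurement noise.
sweep_over <- function(matrices, grid_len, seed, ranges, granularity,
                       max_runs_per_cell, body) {
  n_mat <- length(matrices)
  par_seeds <- seed_array(seed, n_mat)
  ic_seeds <- seed_array(if (is.null(seed)) NULL else seed + 1L,
                         c(n_mat, max_runs_per_cell))
  noise_seeds <- seed_array(if (is.null(seed)) NULL else seed + 2L,
                            c(n_mat, grid_len, max_runs_per_cell))
  errs <- matrix(NA_real_, n_mat, grid_len)
  failures <- 0L
  for (k in seq_len(n_mat)) {
    params <- feasible_parameters(matrices[[k]], ranges = ranges,
                                  seed = par_seeds[k],
                                  granularity = granularity)
    for (g in seq_len(grid_len)) {
      errs[k, g] <- tryCatch(
        body(matrices[[k]], params, g, ic_seeds[k, ], noise_seeds[k, g, ]),
        error = function(e) {
          failures <<- failures + 1L
          NA_real_
        })
    }
  }
  list(errs = errs, failures = failures)
}

#' Reconstruction error versus distance from equilibrium
#'
#' For every matrix in the ensemble, draws a feasible parameter set, then
#' for every `delta` in the grid simulates a `delta`-perturbed experiment
#' (or several, per `design$n_experiments`), reconstructs the network and
#' scores it.  At `delta = 0` the community sits at its fixed point, the
#' host columns are identical and the reconstruction is degenerate; error
#' decreases as the initial conditions move away from equilibrium.
#'
#' @param ensemble a `"matrix_ensemble"` or list of infection matrices.
#' @param delta_grid numeric vector of perturbation fractions in `[0, 1)`.
#' @param design an [experiment_design()]; `delta` is overridden by the
#'   grid.
#' @param ranges,granularity passed to [feasible_parameters()].
#' @param seed master seed.
#' @return An `"infnet_sweep"`: per-matrix errors (matrices x grid), their
#'   ensemble mean and standard deviation, and provenance metadata.
#' @export
sweep_delta <- function(ensemble, delta_grid, design = experiment_design(),
                        ranges = parameter_ranges(), seed = NULL,
                        granularity = "pair") {
  matrices <- ensemble_matrices(ensemble)
  n_cols <- round(design$T / design$dt)
  p <- design$n_experiments
  res <- sweep_over(matrices, length(delta_grid), seed, ranges, granularity,
                    p, function(M, params, g, ic, noise) {
    suppressWarnings(
      run_design(M, params, delta_grid[g], design$dt, n_cols, p,
                 design$snr_db, ic, noise)$error)
  })
  sweep_result("delta", delta_grid, res$errs,
               list(design = unclass(design), seed = seed,
                    n_matrices = length(matrices), failures = res$failures))
}

#' Reconstruction error versus number of experiments at fixed budget
#'
#' Splits a fixed total measurement budget across `p` shorter experiments
#' that differ only in their initial conditions: each of the `p` runs
#' contributes the first `floor(total_columns / p)` regression columns.
#' More experiments probe more of state space (better conditioning) at the
#' cost of shorter trajectories per run.
#'
#' @inheritParams sweep_delta
#' @param total_columns total number of regression columns (e.g. 960 for
#'   96 h sampled every 6 min).
#' @param counts integer vector of experiment counts `p` to try.
#' @return An `"infnet_sweep"` over `counts`; `meta$columns_used` records
#'   the actual budget `p * floor(total_columns / p)` per grid point.
#' @export
sweep_experiment_count <- function(ensemble, total_columns = 960,
                                   counts = 1:20,
                                   design = experiment_design(),
                                   ranges = parameter_ranges(), seed = NULL,
                                   granularity = "pair") {
  stopifnot(all(counts >= 1), all(counts == round(counts)))
  matrices <- ensemble_matrices(ensemble)
  res <- sweep_over(matrices, length(counts), seed, ranges, granularity,
                    max(counts), function(M, params, g, ic, noise) {
    p <- counts[g]
    suppressWarnings(
      run_design(M, params, design$delta, design$dt,
                 floor(total_columns / p), p, design$snr_db, ic, noise)$error)
  })
  sweep_result("n_experiments", counts, res$errs,
               list(design = unclass(design), seed = seed,
                    total_columns = total_columns,
                    columns_used = counts * (total_columns %/% counts),
                    n_matrices = length(matrices), failures = res$failures))
}

#' Reconstruction error over the sampling-interval x horizon plane
#'
#' Single-experiment reconstructions for every combination of sampling
#' interval `dt` and total horizon `T` (pairs with `T < dt` are skipped).
#' At fixed `dt`, longer horizons reduce error; at a fixed measurement
#' budget (`T / dt` constant) there is an interior optimal interval: too
#' short and the trajectories barely move between start and end, too long
#' and the linearization of the log-derivative degrades.
#'
#' @inheritParams sweep_delta
#' @param dt_grid sampling intervals, hours.
#' @param T_grid horizons, hours.
#' @return An `"infnet_sweep"` whose `grid` is a data frame with columns
#'   `dt`, `T` and `n_measurements = round(T / dt)`; fixed-budget slices
#'   can be extracted by filtering on `n_measurements`.
#' @export
sweep_dt_T <- function(ensemble, dt_grid, T_grid,
                       design = experiment_design(),
                       ranges = parameter_ranges(), seed = NULL,
                       granularity = "pair") {
  grid <- expand.grid(dt = dt_grid, T = T_grid)
  grid <- grid[grid$T >= grid$dt, , drop = FALSE]
  rownames(grid) <- NULL
  grid$n_measurements <- round(grid$T / grid$dt)
  matrices <- ensemble_matrices(ensemble)
  res <- sweep_over(matrices, nrow(grid), seed, ranges, granularity,
                    1L, function(M, params, g, ic, noise) {
    suppressWarnings(
      run_design(M, params, design$delta, grid$dt[g], grid$n_measurements[g],
                 1L, design$snr_db, ic, noise)$error)
  })
  sweep_result("dt_T", grid, res$errs,
               list(design = unclass(design), seed = seed,
                    n_matrices = length(matrices), failures = res$failures))
}

#' Fixed-budget slice of the sampling-design plane
#'
#' Convenience wrapper around [sweep_dt_T()]: for a fixed number of
#' measurements, sweeps the sampling interval with the horizon tied as
#' `T = n_measurements * dt`.
#'
#' @inheritParams sweep_dt_T
#' @param n_measurements the fixed measurement budget.
#' @export
sweep_budget_dt <- function(ensemble, n_measurements, dt_grid,
                            design = experiment_design(),
                            ranges = parameter_ranges(), seed = NULL,
                            granularity = "pair") {
  matrices <- ensemble_matrices(ensemble)
  res <- sweep_over(matrices, length(dt_grid), seed, ranges, granularity,
                    1L, function(M, params, g, ic, noise) {
    suppressWarnings(
      run_design(M, params, design$delta, dt_grid[g], n_measurements,
                 1L, design$snr_db, ic, noise)$error)
  })
  sweep_result("dt", dt_grid, res$errs,
               list(design = unclass(design), seed = seed,
                    n_measurements = n_measurements,
                    n_matrices = length(matrices), failures = res$failures))
}

#' Reconstruction error versus measurement noise
#'
#' Multi-experiment reconstructions (by default 20 runs of 48 columns each,
#' sampled every 6 min) with white Gaussian measurement noise injected at
#' each SNR in the grid.
#'
#' @inheritParams sweep_delta
#' @param snr_db_grid signal-to-noise ratios in dB (may include `Inf`).
#' @param design defaults to the 20 x 4.8 h multi-experiment design.
#' @export
sweep_snr <- function(ensemble, snr_db_grid,
                      design = experiment_design(T = 4.8,
                                                 n_experiments = 20L),
                      ranges = parameter_ranges(), seed = NULL,
                      granularity = "pair") {
  matrices <- ensemble_matrices(ensemble)
  n_cols <- round(design$T / design$dt)
  p <- design$n_experiments
  res <- sweep_over(matrices, length(snr_db_grid), seed, ranges, granularity,
                    p, function(M, params, g, ic, noise) {
    suppressWarnings(
      run_design(M, params, design$delta, design$dt, n_cols, p,
                 snr_db_grid[g], ic, noise)$error)
  })
  sweep_result("snr_db", snr_db_grid, res$errs,
               list(design = unclass(design), seed = seed,
                    n_matrices = length(matrices), failures = res$failures))
}

#' @export
print.infnet_sweep <- function(x, ...) {
  ng <- if (is.data.frame(x$grid)) nrow(x$grid) else length(x$grid)
  cat(sprintf("Reconstruction-error sweep over '%s': %d grid points x %d matrices\n",
              x$axis, ng, nrow(x$per_matrix_errors)))
  cat(sprintf("Mean error range: %.4g - %.4g\n",
              min(x$mean_error, na.rm = TRUE),
              max(x$mean_error, na.rm = TRUE)))
  if (x$meta$failures > 0) {
    cat(sprintf("(%d run(s) failed and were recorded as NA)\n",
                x$meta$failures))
  }
  invisible(x)
}

#' @export
plot.infnet_sweep <- function(x, log = "y", ...) {
  if (is.data.frame(x$grid)) {
    stop_input("2-D design sweeps have no default plot; filter a fixed-budget slice")
  }
  gx <- x$grid
  if (any(is.infinite(gx))) gx[is.infinite(gx)] <- max(gx[is.finite(gx)]) * 2
  graphics::plot(gx, x$mean_error, type = "b", pch = 16, log = log,
                 xlab = x$axis, ylab = "mean reconstruction error", ...)
  graphics::arrows(gx, pmax(x$mean_error - x$sd_error, .Machine$double.xmin),
                   gx, x$mean_error + x$sd_error,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' @export
as.data.frame.infnet_sweep <- function(x, ...) {
  n_mat <- nrow(x$per_matrix_errors)
  if (is.data.frame(x$grid)) {
    out <- x$grid[rep(seq_len(nrow(x$grid)), each = n_mat), , drop = FALSE]
  } else {
    out <- data.frame(value = rep(x$grid, each = n_mat))
    names(out) <- x$axis
  }
  out$matrix <- rep(seq_len(n_mat), times = ncol(x$per_matrix_errors))
  out$error <- as.vector(x$per_matrix_errors)
  rownames(out) <- NULL
  out
}
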