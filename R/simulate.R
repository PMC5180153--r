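#' Experiment design descriptor
#'
#' Bundles the knobs of an in silico measurement campaign: how far from
#' equilibrium the community starts, how often and how long it is sampled,
#' how many replicate experiments are run and how noisy the measurements
#' are.
#'
#' @param delta fractional displacement of the initial densities from
#'   equilibrium; each population starts at `x_eq * (1 +/- delta)` with an
#'   independent random sign.  Must satisfy `0 <= delta < 1`.
#' @param dt sampling interval, hours.
#' @param T total sampled horizon, hours (so each experiment yields
#'   `T / dt` usable regression columns).
#' @param snr_db signal-to-noise ratio of the measurements in dB
#'   (`Inf` = noiseless).
#' @param n_experiments number of replicate experiments differing only in
#'   their initial conditions.
#' @return A list of class `"experiment_design"`.
#' @export
experiment_design <- function(delta = 0.5, dt = 0.1, T = 96,
                              snr_db = Inf, n_experiments = 1L) {
  if (!is.numeric(delta) || delta < 0 || delta >= 1) {
    stop_input("'delta' must satisfy 0 <= delta < 1")
  }
  if (dt <= 0 || T < dt) stop_input("need dt > 0 and T >= dt")
  if (!is_count(n_experiments)) stop_input("'n_experiments' must be a positive integer")
  structure(list(delta = delta, dt = dt, T = T, snr_db = snr_db,
                 n_experiments = as.integer(n_experiments)),
            class = "experiment_design")
}

#' Initial state displaced from equilibrium
#'
#' Sets every host and virus density independently to `x_eq * (1 + delta)`
#' or `x_eq * (1 - delta)` with equal probability.  `delta` controls the
#' variability of the resulting transient and hence the conditioning of the
#' network reconstruction: at `delta = 0` the community sits at its fixed
#' point and the regression is degenerate.
#'
#' @param H_star,V_star equilibrium densities.
#' @param delta fractional displacement in `[0, 1)`.
#' @param seed integer seed for the sign draws.
#' @return A list with components `h` and `v`.
#' @export
perturbed_initial_state <- function(H_star, V_star, delta, seed = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1) {
    stop_input("'delta' must satisfy 0 <= delta < 1 (densities stay positive)")
  }
  n_h <- length(H_star); n_v <- length(V_star)
  with_seed(seed, {
    signs <- sample(c(-1, 1), n_h + n_v, replace = TRUE)
    list(h = H_star * (1 + delta * signs[seq_len(n_h)]),
         v = V_star * (1 + delta * signs[n_h + seq_len(n_v)]))
  })
}

#' Simulate and sample community dynamics
#'
#' Integrates the community model with an adaptive Dormand-Prince
#' Runge-Kutta scheme (deSolve's `"ode45"`) and returns the solution sampled
#' on the regular grid `t = 0, dt, 2 dt, ..., T` (hours).  The initial state
#' defaults to a `delta`-perturbed equilibrium via
#' [perturbed_initial_state()]; measurement noise, if requested, is added by
#' [add_measurement_noise()].
#'
#' @param params a `"system_params"` object.
#' @param M binary infection matrix.
#' @param design an [experiment_design()]; its `delta`, `dt`, `T` and
#'   `snr_db` are used.
#' @param init optional explicit initial state (list with `h`, `v`);
#'   overrides `design$delta`.
#' @param seed integer seed controlling the initial-condition signs and the
#'   measurement noise.
#' @param rtol relative integration tolerance.
#' @param atol_scale absolute tolerance, expressed as a fraction of each
#'   type's equilibrium density.
#' @return A `"community_ts"` object: list with `times` (hours), `H`
#'   (`n_h` x `n_samples`), `V` (`n_v` x `n_samples`) and `meta`.
#' @examples
#' M <- modular_matrix(4, 4, 2)
#' p <- feasible_parameters(M, seed = 1)
#' ts <- simulate_community(p, M, experiment_design(T = 24), seed = 2)
#' ts
#' @export
simulate_community <- function(params, M, design = experiment_design(),
                               init = NULL, seed = NULL,
                               rtol = 1e-8, atol_scale = 1e-8) {
  stopifnot(inherits(params, "system_params"),
            inherits(design, "experiment_design"))
  validate_infection_matrix(M)
  if (is.null(init)) {
    init <- perturbed_initial_state(params$H_star, params$V_star,
                                    design$delta, seed = seed)
  }
  if (any(init$h <= 0) || any(init$v <= 0)) {
    stop_input("initial densities must be strictly positive")
  }
  ts <- integrate_and_sample(params, M, init, dt = design$dt, T = design$T,
                             rtol = rtol, atol_scale = atol_scale)
  ts$meta$seed <- seed
  ts$meta$delta <- design$delta
  if (is.finite(design$snr_db)) {
    noise_seed <- if (is.null(seed)) NULL else seed + 1L
    ts <- add_measurement_noise(ts, design$snr_db, seed = noise_seed)
  }
  ts
}

#' @rdname simulate_community
#' @param dt,T sampling interval and horizon, hours.
#' @export
integrate_and_sample <- function(params, M, init, dt, T,
                                 rtol = 1e-8, atol_scale = 1e-8) {
  stopifnot(inherits(params, "system_params"))
  if (dt <= 0 || T < dt) stop_input("need dt > 0 and T >= dt")
  n_h <- length(params$r); n_v <- length(params$m)
  n_steps <- round(T / dt)
  times <- (0:n_steps) * dt
  ctx <- list(params = params, n_h = n_h, n_v = n_v,
              loss = M * params$phi,
              gain = M * params$phi * params$beta)
  y0 <- c(init$h, init$v)
  atol <- atol_scale * c(params$H_star, params$V_star)
  sol <- deSolve::ode(y0, times, rhs_desolve, ctx, method = "ode45",
                      rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")
  if ((!is.null(istate) && istate[1L] < 0) || nrow(sol) < length(times)) {
    stop("integration failed before t = ", T, " h; last time reached: ",
         sol[nrow(sol), 1L], call. = FALSE)
  }
  Hm <- t(sol[, 1L + seq_len(n_h), drop = FALSE])
  Vm <- t(sol[, 1L + n_h + seq_len(n_v), drop = FALSE])
  if (any(Hm <= 0) || any(Vm <= 0)) {
    stop("integration produced non-positive densities (population collapse ",
         "at this perturbation); log-derivatives are undefined", call. = FALSE)
  }
  dimnames(Hm) <- list(paste0("h", seq_len(n_h)), NULL)
  dimnames(Vm) <- list(paste0("v", seq_len(n_v)), NULL)
  structure(list(
    times = times, H = Hm, V = Vm,
    meta = list(dt = dt, T = T, snr_db = Inf, rtol = rtol,
                atol_scale = atol_scale)
  ), class = "community_ts")
}

#' Add white Gaussian measurement noise at a prescribed SNR
#'
#' For each host and virus trajectory independently, adds zero-mean Gaussian
#' noise with variance `P_signal / 10^(snr_db / 10)`, where `P_signal` is
#' the mean squared density of that series (so `snr_db = 10` makes the noise
#' power 10% of the signal power).  Noisy values that fall to zero or below
#' are clipped to `floor_frac` times the smallest noiseless value of the
#' series, keeping logarithms finite.
#'
#' @param ts a `"community_ts"` object.
#' @param snr_db signal-to-noise ratio in dB; `Inf` returns `ts` unchanged.
#' @param seed integer seed for the noise draws.
#' @param targets `"both"` (default) corrupts host and virus measurements;
#'   `"viruses"` restricts noise to the virus series.
#' @param floor_frac clipping floor as a fraction of each series' minimum
#'   noiseless value.
#' @return A `"community_ts"` with corrupted densities; `meta$snr_db`
#'   records the requested SNR.
#' @export
add_measurement_noise <- function(ts, snr_db, seed = NULL,
                                  targets = c("both", "viruses"),
                                  floor_frac = 1e-6) {
  stopifnot(inherits(ts, "community_ts"))
  targets <- match.arg(targets)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    stop_input("'snr_db' must be a single finite number or Inf")
  }
  if (is.infinite(snr_db)) {
    return(ts)
  }
  corrupt <- function(X) {
    t(apply(X, 1L, function(x) {
      sigma <- sqrt(mean(x^2) / 10^(snr_db / 10))
      y <- x + stats::rnorm(length(x), 0, sigma)
      pmax(y, floor_frac * min(x))
    }))
  }
  with_seed(seed, {
    if (targets == "both") ts$H <- corrupt(ts$H)
    ts$V <- corrupt(ts$V)
  })
  ts$meta$snr_db <- snr_db
  ts$meta$noise_targets <- targets
  ts$meta$noise_floor_frac <- floor_frac
  ts
}

#' @export
print.community_ts <- function(x, ...) {
  cat(sprintf(
    "Community time series: %d hosts, %d viruses, %d samples (dt = %g h, T = %g h)%s\n",
    nrow(x$H), nrow(x$V), length(x$times), x$meta$dt, x$meta$T,
    if (is.finite(x$meta$snr_db)) sprintf(", SNR = %g dB", x$meta$snr_db) else ""))
  invisible(x)
}

#' @export
plot.community_ts <- function(x, log = "y", ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$times, t(x$H), type = "l", lty = 1, log = log,
                    xlab = "time (h)", ylab = "hosts (cells/ml)", ...)
  graphics::matplot(x$times, t(x$V), type = "l", lty = 1, log = log,
                    xlab = "time (h)", ylab = "viruses (virions/ml)", ...)
  invisible(x)
}
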