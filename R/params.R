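#' Parameter and target-equilibrium sampling ranges
#'
#' Ranges of the uniform distributions used to draw adsorption rates,
#' burst sizes and target steady-state densities when building a feasible
#' parameter set.  Defaults are the standard ranges for marine-type
#' phage-bacteria communities: adsorption rates of 1e-8 to 1e-7 ml per virus
#' per hour, burst sizes of 10-50 viruses per cell, host equilibria of
#' 1e3-1e4 cells/ml and virus equilibria of 1e6-1e7 virions/ml.  The
#' system-wide carrying capacity is tied to the drawn host equilibria as
#' `K = K_multiplier * max(H_star)` (1e6 cells/ml at the default ranges).
#'
#' @param phi adsorption-rate interval, ml/(virus h).
#' @param beta burst-size interval, viruses/cell.
#' @param H_star host equilibrium interval, cells/ml.
#' @param V_star virus equilibrium interval, virions/ml.
#' @param K_multiplier carrying capacity as a multiple of the largest host
#'   equilibrium.
#' @return An object of class `"parameter_ranges"`.
#' @export
parameter_ranges <- function(phi = c(1e-8, 1e-7),
                             beta = c(10, 50),
                             H_star = c(1e3, 1e4),
                             V_star = c(1e6, 1e7),
                             K_multiplier = 100) {
  rng <- list(phi = phi, beta = beta, H_star = H_star, V_star = V_star,
              K_multiplier = K_multiplier)
  for (nm in c("phi", "beta", "H_star", "V_star")) {
    iv <- rng[[nm]]
    if (length(iv) != 2L || !is.numeric(iv) || iv[1] <= 0 || iv[1] > iv[2]) {
      stop_input(sprintf("range '%s' must be a positive interval c(lo, hi)", nm))
    }
  }
  if (!is.numeric(K_multiplier) || length(K_multiplier) != 1L ||
      K_multiplier <= 0) {
    stop_input("'K_multiplier' must be a positive number")
  }
  structure(rng, class = "parameter_ranges")
}

#' Draw rates and target equilibria from their ranges
#'
#' Draws adsorption rates `phi`, burst sizes `beta`, target host equilibria
#' `H_star` and target virus equilibria `V_star` uniformly from the intervals
#' in `ranges`, and sets `K = K_multiplier * max(H_star)`.
#'
#' By default `phi` and `beta` are drawn independently per host-virus pair
#' (`granularity = "pair"`).  Per-virus draws broadcast down the columns are
#' available (`granularity = "virus"`), but note that per-virus rates make
#' hosts with identical infection-matrix rows dynamically indistinguishable
#' -- their trajectories are exactly proportional under feasibility-derived
#' growth rates -- so the network is then not identifiable for matrices with
#' duplicated rows (e.g. modular matrices with blocks of two or more hosts).
#'
#' @param ranges a [parameter_ranges()] object.
#' @param n_h,n_v numbers of host and virus types.
#' @param seed integer seed; identical seeds give identical draws.
#' @param granularity `"pair"` (default) or `"virus"`.
#' @return A list with `phi`, `beta` (`n_h` x `n_v` matrices), `H_star`,
#'   `V_star` (vectors) and `K` (scalar).
#' @export
sample_parameter_ranges <- function(ranges = parameter_ranges(), n_h, n_v,
                                    seed = NULL,
                                    granularity = c("pair", "virus")) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  granularity <- match.arg(granularity)
  if (!is_count(n_h) || !is_count(n_v)) {
    stop_input("'n_h' and 'n_v' must be positive integers")
  }
  with_seed(seed, {
    if (granularity == "pair") {
      phi <- matrix(stats::runif(n_h * n_v, ranges$phi[1], ranges$phi[2]),
                    n_h, n_v)
      beta <- matrix(stats::runif(n_h * n_v, ranges$beta[1], ranges$beta[2]),
                     n_h, n_v)
    } else {
      phi <- matrix(rep(stats::runif(n_v, ranges$phi[1], ranges$phi[2]),
                        each = n_h), n_h, n_v)
      beta <- matrix(rep(stats::runif(n_v, ranges$beta[1], ranges$beta[2]),
                         each = n_h), n_h, n_v)
    }
    H_star <- stats::runif(n_h, ranges$H_star[1], ranges$H_star[2])
    V_star <- stats::runif(n_v, ranges$V_star[1], ranges$V_star[2])
    list(phi = phi, beta = beta, H_star = H_star, V_star = V_star,
         K = ranges$K_multiplier * max(H_star))
  })
}

#' Solve the steady-state equations for growth and decay rates
#'
#' Given an infection matrix, rates, target equilibria, carrying capacity and
#' competition matrix, returns the host growth rates `r` and viral decay
#' rates `m` that make `(H_star, V_star)` an exact coexistence equilibrium of
#' the community model:
#' \deqn{m_j = \sum_i M_{ij} \beta_{ij} \phi_{ij} H^*_i}
#' \deqn{r_i = \frac{\sum_j M_{ij} \phi_{ij} V^*_j}{1 - \sum_{i'} a_{ii'} H^*_{i'} / K}}
#'
#' An empty row or column of `M` is rejected (it would force `r_i = 0` or
#' `m_j = 0`), as is a non-positive feasibility denominator
#' `1 - sum(a[i, ] * H_star) / K`.
#'
#' @param M binary infection matrix.
#' @param phi,beta `n_h` x `n_v` rate matrices.
#' @param H_star,V_star target equilibrium densities.
#' @param K carrying capacity, cells/ml.
#' @param a `n_h` x `n_h` competition matrix (default: all ones, i.e. a
#'   single shared carrying capacity).
#' @return A list with vectors `r` (length `n_h`, 1/h) and `m` (length
#'   `n_v`, 1/h), both strictly positive.
#' @examples
#' derive_growth_decay(matrix(1, 1, 1), phi = matrix(1e-7, 1, 1),
#'                     beta = matrix(20, 1, 1), H_star = 1e4,
#'                     V_star = 1e6, K = 1e6)  # m = 0.02, r ~ 0.101
#' @export
derive_growth_decay <- function(M, phi, beta, H_star, V_star, K,
                                a = NULL) {
  validate_infection_matrix(M)
  n_h <- nrow(M); n_v <- ncol(M)
  if (is.null(a)) a <- matrix(1, n_h, n_h)
  stopifnot(nrow(phi) == n_h, ncol(phi) == n_v,
            nrow(beta) == n_h, ncol(beta) == n_v,
            length(H_star) == n_h, length(V_star) == n_v,
            nrow(a) == n_h, ncol(a) == n_h, length(K) == 1L)
  denom <- 1 - as.vector(a %*% H_star) / K
  if (any(denom <= 0)) {
    stop_input("infeasible: competition term 1 - sum(a * H_star)/K is not positive")
  }
  m <- as.vector(crossprod(M * beta * phi, H_star))
  r <- as.vector((M * phi) %*% V_star) / denom
  if (any(m <= 0) || any(r <= 0)) {
    stop_input("infeasible: derived growth or decay rates are not all positive")
  }
  list(r = r, m = m)
}

#' Feasible parameter set for an infection matrix
#'
#' Draws rates and target equilibria from `ranges` and solves the
#' steady-state equations for the remaining parameters, so that the returned
#' set admits `(H_star, V_star)` as an exact coexistence equilibrium.
#'
#' @inheritParams sample_parameter_ranges
#' @param M binary infection matrix (hosts x viruses).
#' @param a competition matrix; default all ones (shared carrying capacity).
#' @return An object of class `"system_params"`: a list with elements `r`,
#'   `a`, `K`, `phi`, `beta`, `m`, `H_star`, `V_star`.  Time unit: hours.
#' @examples
#' M <- modular_matrix(4, 4, 2)
#' p <- feasible_parameters(M, seed = 1)
#' d <- ode_rhs(p$H_star, p$V_star, p, M)
#' max(abs(c(d$dh, d$dv)))  # numerically zero
#' @export
feasible_parameters <- function(M, ranges = parameter_ranges(), a = NULL,
                                seed = NULL,
                                granularity = c("pair", "virus")) {
  validate_infection_matrix(M)
  granularity <- match.arg(granularity)
  n_h <- nrow(M); n_v <- ncol(M)
  if (is.null(a)) a <- matrix(1, n_h, n_h)
  drawn <- sample_parameter_ranges(ranges, n_h, n_v, seed = seed,
                                   granularity = granularity)
  rates <- derive_growth_decay(M, drawn$phi, drawn$beta, drawn$H_star,
                               drawn$V_star, drawn$K, a)
  system_params(r = rates$r, a = a, K = drawn$K, phi = drawn$phi,
                beta = drawn$beta, m = rates$m, H_star = drawn$H_star,
                V_star = drawn$V_star)
}

#' Construct and validate a full parameter set
#'
#' Bundles all rate constants of the community model.  All rates are per
#' hour; densities per ml.
#'
#' @param r host growth rates, 1/h (length `n_h`).
#' @param a competition matrix, dimensionless (`n_h` x `n_h`).
#' @param K carrying capacity, cells/ml.
#' @param phi adsorption rates, ml/(virus h) (`n_h` x `n_v`).
#' @param beta burst sizes, viruses/cell (`n_h` x `n_v`).
#' @param m viral decay rates, 1/h (length `n_v`).
#' @param H_star,V_star target equilibrium densities.
#' @return An object of class `"system_params"`.
#' @export
system_params <- function(r, a, K, phi, beta, m, H_star, V_star) {
  n_h <- length(r); n_v <- length(m)
  check_matrix(a, "a"); check_matrix(phi, "phi"); check_matrix(beta, "beta")
  if (!all(dim(a) == c(n_h, n_h)) || !all(dim(phi) == c(n_h, n_v)) ||
      !all(dim(beta) == c(n_h, n_v))) {
    stop_input("parameter dimensions disagree")
  }
  if (length(H_star) != n_h || length(V_star) != n_v) {
    stop_input("'H_star'/'V_star' lengths disagree with 'r'/'m'")
  }
  if (any(r <= 0) || any(m <= 0) || K <= 0) {
    stop_input("'r', 'm' and 'K' must be strictly positive")
  }
  if (any(phi < 0) || any(beta < 0) || any(a < 0) ||
      any(H_star < 0) || any(V_star < 0)) {
    stop_input("'phi', 'beta', 'a', 'H_star' and 'V_star' must be non-negative")
  }
  if (any(1 - as.vector(a %*% H_star) / K <= 0)) {
    stop_input("infeasible: competition term 1 - sum(a * H_star)/K is not positive")
  }
  structure(list(r = r, a = a, K = K, phi = phi, beta = beta, m = m,
                 H_star = H_star, V_star = V_star),
            class = "system_params")
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf("Community model parameters: %d hosts, %d viruses (rates per hour)\n",
              length(x$r), length(x$m)))
  cat(sprintf("  r in [%.3g, %.3g] 1/h, m in [%.3g, %.3g] 1/h, K = %.3g cells/ml\n",
              min(x$r), max(x$r), min(x$m), max(x$m), x$K))
  cat(sprintf("  phi in [%.3g, %.3g] ml/(virus h), beta in [%.3g, %.3g]\n",
              min(x$phi), max(x$phi), min(x$beta), max(x$beta)))
  cat(sprintf("  H* in [%.3g, %.3g] cells/ml, V* in [%.3g, %.3g] virions/ml\n",
              min(x$H_star), max(x$H_star), min(x$V_star), max(x$V_star)))
  invisible(x)
}

#' Write or read a parameter set as JSON
#'
#' The JSON document stores every field of the parameter set (matrices as
#' nested arrays) plus a `units` block.
#'
#' @param params a `"system_params"` object.
#' @param path file path.
#' @return `read_params_json()` returns a `"system_params"` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "system_params"))
  doc <- list(
    n_h = length(params$r), n_v = length(params$m),
    r = params$r, a = params$a, K = params$K, phi = params$phi,
    beta = params$beta, m = params$m, H_star = params$H_star,
    V_star = params$V_star,
    units = list(time = "hours", r = "1/h", m = "1/h",
                 phi = "ml/(virus h)", beta = "viruses/cell",
                 K = "cells/ml", H_star = "cells/ml", V_star = "virions/ml")
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else as.matrix(x)
  system_params(r = doc$r, a = as_mat(doc$a), K = doc$K,
                phi = as_mat(doc$phi), beta = as_mat(doc$beta), m = doc$m,
                H_star = doc$H_star, V_star = doc$V_star)
}
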