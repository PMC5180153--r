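#' Community model vector field
#'
#' Right-hand side of the multi-host, multi-virus generalized Lotka-Volterra
#' model.  Host `i` grows logistically against a shared carrying capacity and
#' is lysed by the viruses that infect it; virus `j` is produced by lysis of
#' its hosts and decays at rate `m_j`:
#' \deqn{\dot h_i = r_i h_i \left(1 - \sum_{i'} a_{ii'} h_{i'} / K\right)
#'   - h_i \sum_j M_{ij} \phi_{ij} v_j}
#' \deqn{\dot v_j = v_j \sum_i \beta_{ij} \phi_{ij} M_{ij} h_i - m_j v_j}
#'
#' Every term carries the focal density as a factor, so the field never
#' drives a zero density negative and the all-extinct state is a fixed
#' point.  For parameters built by [feasible_parameters()], the target
#' equilibrium `(H_star, V_star)` is an exact root.
#'
#' @param h host densities, cells/ml (length `n_h`).
#' @param v virus densities, virions/ml (length `n_v`).
#' @param params a `"system_params"` object.
#' @param M binary infection matrix (`n_h` x `n_v`).
#' @return A list with `dh` and `dv`, time derivatives per hour.
#' @export
ode_rhs <- function(h, v, params, M) {
  stopifnot(inherits(params, "system_params"))
  validate_infection_matrix(M, require_cover = FALSE)
  n_h <- length(params$r); n_v <- length(params$m)
  if (length(h) != n_h || length(v) != n_v ||
      nrow(M) != n_h || ncol(M) != n_v) {
    stop_input("dimensions of 'h', 'v', 'params' and 'M' disagree")
  }
  if (any(h < 0) || any(v < 0)) {
    stop_input("densities must be non-negative")
  }
  dh <- params$r * h * (1 - as.vector(params$a %*% h) / params$K) -
    h * as.vector((M * params$phi) %*% v)
  dv <- v * as.vector(crossprod(M * params$phi * params$beta, h)) -
    params$m * v
  list(dh = dh, dv = dv)
}

# deSolve-compatible wrapper.  State is the concatenated vector
# c(h, v) -- hosts first, then viruses; this ordering is fixed everywhere.
rhs_desolve <- function(t, y, ctx) {
  p <- ctx$params
  h <- y[seq_len(ctx$n_h)]
  v <- y[ctx$n_h + seq_len(ctx$n_v)]
  dh <- p$r * h * (1 - as.vector(p$a %*% h) / p$K) -
    h * as.vector(ctx$loss %*% v)
  dv <- v * as.vector(crossprod(ctx$gain, h)) - p$m * v
  list(c(dh, dv))
}

#' Quantitative infection network implied by a parameter set
#'
#' The quantitative network multiplies the binary infection matrix by the
#' per-pair effective infection rates: `M_tilde[i, j] = M[i, j] * phi[i, j] *
#' beta[i, j]`.  Its zero pattern is exactly the complement of `M`, and its
#' non-zero entries are the targets of the reconstruction.
#'
#' @inheritParams ode_rhs
#' @return A non-negative `n_h` x `n_v` matrix, units ml viruses /(cell h).
#' @export
quantitative_network <- function(M, params) {
  stopifnot(inherits(params, "system_params"))
  validate_infection_matrix(M, require_cover = FALSE)
  M * params$phi * params$beta
}
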