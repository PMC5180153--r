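#' Assemble the log-derivative regression system
#'
#' Discretizing the virus equations of the community model gives, for every
#' sampling interval `[t_n, t_{n+1}]`,
#' \deqn{\frac{\Delta \ln v_j(t_n)}{\Delta t_n} \approx
#'   \sum_i \tilde M_{ij} h_i(t_n) - m_j,}
#' a linear relation between the observed host densities and the unknown
#' quantitative network and decay rates.  This function stacks those
#' relations: `W[j, n]` holds the discrete log-derivative of virus `j` over
#' interval `n`, and `H_aug` holds the host densities with a row of ones
#' appended (the intercept carrying `-m`).
#'
#' The centred log-difference is a second-order accurate estimate of the
#' derivative at the interval *midpoint*, so by default the host densities
#' are also taken at the midpoint (average of the two endpoints;
#' `hosts = "midpoint"`).  `hosts = "left"` pairs the log-difference with
#' the left-endpoint densities instead; that first-order convention leaves a
#' visible discretization bias at typical sampling intervals.
#'
#' @param ts a `"community_ts"` object with at least 2 samples and strictly
#'   positive densities.
#' @param hosts `"midpoint"` (default) or `"left"`: where the host
#'   densities are evaluated within each interval.
#' @return An object of class `"regression_system"`: list with `W`
#'   (`n_v` x `N`), `H_aug` (`(n_h + 1)` x `N`, last row all ones), the
#'   host convention, and per-block column counts.  `N = n_samples - 1`.
#' @export
build_regression <- function(ts, hosts = c("midpoint", "left")) {
  stopifnot(inherits(ts, "community_ts"))
  hosts <- match.arg(hosts)
  n <- length(ts$times)
  if (n < 2L) stop_input("need at least 2 samples to form a log-derivative")
  if (any(ts$H <= 0) || any(ts$V <= 0)) {
    stop_input("all densities must be strictly positive (log undefined)")
  }
  dt <- diff(ts$times)
  N <- n - 1L
  W <- (log(ts$V[, -1L, drop = FALSE]) -
          log(ts$V[, -n, drop = FALSE])) / rep(dt, each = nrow(ts$V))
  Hn <- ts$H[, -n, drop = FALSE]
  if (hosts == "midpoint") {
    Hn <- (Hn + ts$H[, -1L, drop = FALSE]) / 2
  }
  H_aug <- rbind(Hn, rep(1, N))
  rn <- rownames(Hn)
  if (is.null(rn)) rn <- paste0("h", seq_len(nrow(Hn)))
  rownames(H_aug) <- c(rn, "1")
  structure(list(W = W, H_aug = H_aug, hosts = hosts, block_cols = N),
            class = "regression_system")
}

#' Concatenate regression systems from multiple experiments
#'
#' Experiments that share the same community (same infection network and
#' parameters) but different initial conditions probe different regions of
#' state space; stacking their regression columns side by side,
#' \deqn{(W_1 W_2 \ldots W_p) \approx (\tilde M^\top\; -m)
#'   \begin{pmatrix} H_1 H_2 \ldots H_p \\ 1 \end{pmatrix},}
#' yields a single better-conditioned problem at the same total measurement
#' budget.
#'
#' @param systems a list of `"regression_system"` objects with identical
#'   numbers of hosts, viruses and host conventions.
#' @return A single `"regression_system"`; its column count is the sum of
#'   the block column counts.
#' @export
concat_regressions <- function(systems) {
  if (inherits(systems, "regression_system")) {
    return(systems)
  }
  stopifnot(is.list(systems), length(systems) >= 1L,
            all(vapply(systems, inherits, TRUE, "regression_system")))
  if (length(systems) == 1L) {
    return(systems[[1L]])
  }
  ref <- systems[[1L]]
  for (s in systems[-1L]) {
    if (nrow(s$W) != nrow(ref$W) || nrow(s$H_aug) != nrow(ref$H_aug)) {
      stop_input("regression systems have mismatched numbers of hosts or viruses")
    }
    if (s$hosts != ref$hosts) {
      stop_input("regression systems mix host-pairing conventions")
    }
  }
  structure(list(
    W = do.call(cbind, lapply(systems, `[[`, "W")),
    H_aug = do.call(cbind, lapply(systems, `[[`, "H_aug")),
    hosts = ref$hosts,
    block_cols = unlist(lapply(systems, `[[`, "block_cols"))
  ), class = "regression_system")
}

# Lawson-Hanson active-set non-negative least squares: minimize ||C x - d||
# subject to x >= 0.  Written here because the constrained solve is the
# workhorse of the reconstruction and must cope with the very ill-conditioned
# systems produced near delta = 0 (generic NNLS routines with a small fixed
# iteration cap stall on these).  Columns are assumed pre-equilibrated by the
# caller.
nnls_solve <- function(C, d, itmax = NULL) {
  n <- ncol(C)
  if (is.null(itmax)) itmax <- 100L * n
  tol <- 10 * .Machine$double.eps * max(svd(C, nu = 0, nv = 0)$d) * (max(dim(C)) + 1)
  x <- numeric(n)
  P <- logical(n)
  w <- drop(crossprod(C, d))
  it <- 0L
  converged <- TRUE
  while (any(!P) && any(w[!P] > tol)) {
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- numeric(n)
      z[P] <- qr.coef(qr(C[, P, drop = FALSE]), d)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > 0)) break
      it <- it + 1L
      if (it > itmax) {
        converged <- FALSE
        break
      }
      Q <- P & (z <= 0)
      ratio <- x[Q] / (x[Q] - z[Q])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      P <- P & (x > tol)
    }
    if (!converged) break
    x <- z
    w <- drop(crossprod(C, d - C %*% x))
  }
  resid <- d - C %*% x
  list(x = x, objective = sum(resid^2), converged = converged)
}

#' Solve the constrained network reconstruction
#'
#' Minimizes the Frobenius residual
#' `|| W - (M_tilde' | -m) H_aug ||` over entrywise non-negative `M_tilde`
#' and `m`.  The objective separates across virus rows, so the solve
#' decomposes into `n_v` independent non-negative least-squares problems of
#' dimension `n_h + 1` (the decay coefficient enters with its sign flipped),
#' each solved by a Lawson-Hanson active-set method on column-equilibrated
#' data.
#'
#' @param sys a `"regression_system"` (single- or multi-experiment).
#' @return A list with `M_tilde` (`n_h` x `n_v`, non-negative), `m`
#'   (length `n_v`, non-negative), `objective` (total squared residual),
#'   `row_objectives`, `kappa` (condition number of the scaled design) and
#'   `converged`.  Warns when the system is underdetermined
#'   (`N < n_h + 1`) or numerically rank deficient.
#' @export
solve_network <- function(sys) {
  stopifnot(inherits(sys, "regression_system"))
  n_aug <- nrow(sys$H_aug)
  n_h <- n_aug - 1L
  n_v <- nrow(sys$W)
  N <- ncol(sys$H_aug)
  if (N < n_aug) {
    warning("regression system is underdetermined: ", N,
            " columns for ", n_aug, " coefficients per virus")
  }
  # design: host columns, then the negated intercept so that all
  # coefficients (network entries and decay rate) are >= 0
  C <- cbind(t(sys$H_aug[seq_len(n_h), , drop = FALSE]), -1)
  scale <- sqrt(colSums(C^2))
  scale[scale == 0] <- 1
  Cs <- sweep(C, 2L, scale, "/")
  kappa <- if (nrow(Cs) < ncol(Cs)) {
    Inf  # fewer columns than coefficients: structurally rank deficient
  } else {
    sv <- svd(Cs, nu = 0, nv = 0)$d
    if (min(sv) == 0) Inf else max(sv) / min(sv)
  }
  if (kappa > 1e12) {
    warning(sprintf(
      "regression design is numerically rank deficient (condition number %.3g); reconstruction is not unique",
      kappa))
  }
  M_tilde <- matrix(0, n_h, n_v)
  m <- numeric(n_v)
  row_obj <- numeric(n_v)
  conv <- logical(n_v)
  for (j in seq_len(n_v)) {
    fit <- nnls_solve(Cs, sys$W[j, ])
    xj <- fit$x / scale
    M_tilde[, j] <- xj[seq_len(n_h)]
    m[j] <- xj[n_aug]
    row_obj[j] <- fit$objective
    conv[j] <- fit$converged
  }
  if (!all(conv)) {
    warning("NNLS iteration budget exhausted for ", sum(!conv),
            " virus row(s); solution may be inexact")
  }
  list(M_tilde = M_tilde, m = m, objective = sum(row_obj),
       row_objectives = row_obj, kappa = kappa, converged = all(conv))
}

#' Normalized Frobenius reconstruction error
#'
#' The package's reconstruction-quality metric:
#' `||M_tilde - M_tilde_rec||_F / ||M_tilde||_F`.  A perfect reconstruction
#' scores 0; the all-zero reconstruction scores 1.
#'
#' @param M_tilde true quantitative network.
#' @param M_tilde_rec reconstructed quantitative network, same shape.
#' @return A non-negative number.
#' @export
reconstruction_error <- function(M_tilde, M_tilde_rec) {
  check_matrix(M_tilde, "M_tilde")
  check_matrix(M_tilde_rec, "M_tilde_rec")
  if (!all(dim(M_tilde) == dim(M_tilde_rec))) {
    stop_input("matrices must have the same shape")
  }
  ref <- norm(M_tilde, "F")
  if (ref == 0) stop_input("reference network has zero norm")
  norm(M_tilde - M_tilde_rec, "F") / ref
}

#' Binary support of a quantitative network
#'
#' Thresholds a quantitative network at a fraction of its largest entry,
#' recovering the inferred binary infection matrix.
#'
#' @param M_tilde non-negative matrix (or an `"infnet_fit"`).
#' @param frac threshold as a fraction of the maximum entry.
#' @return A binary matrix of the same shape.
#' @export
support_matrix <- function(M_tilde, frac = 1e-2) {
  if (inherits(M_tilde, "infnet_fit")) M_tilde <- M_tilde$M_tilde
  check_matrix(M_tilde, "M_tilde")
  (M_tilde > frac * max(M_tilde)) + 0
}
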