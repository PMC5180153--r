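# Independent oracles and fixture builders, kept deliberately naive: the
# oracles re-state the definitions directly and share no code with the
# implementation they check.

# NODF by its definition: loop over every unordered pair of rows and of
# columns; a pair with equal (or zero) degrees contributes nothing, an
# unequal pair contributes the fraction of the sparser line's interactions
# also present in the denser line.
nodf_oracle <- function(M) {
  contrib <- function(a, b) {
    da <- sum(a); db <- sum(b)
    if (da == db || min(da, db) == 0) return(0)
    if (da < db) { sp <- a; dn <- b } else { sp <- b; dn <- a }
    sum(sp == 1 & dn == 1) / sum(sp)
  }
  s <- 0
  n_r <- nrow(M); n_c <- ncol(M)
  if (n_r > 1) {
    for (i in 1:(n_r - 1)) for (k in (i + 1):n_r) {
      s <- s + contrib(M[i, ], M[k, ])
    }
  }
  if (n_c > 1) {
    for (i in 1:(n_c - 1)) for (k in (i + 1):n_c) {
      s <- s + contrib(M[, i], M[, k])
    }
  }
  s / (choose(n_r, 2) + choose(n_c, 2))
}

# Brute-force non-negative least squares: enumerate every support set,
# solve the unconstrained problem on it, keep feasible candidates and
# return the one with the smallest residual.  Exact for small n.
nnls_oracle <- function(C, d) {
  n <- ncol(C)
  best <- list(x = numeric(n), obj = sum(d^2))
  for (mask in 1:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- numeric(n)
    cf <- tryCatch(qr.coef(qr(C[, S, drop = FALSE]), d),
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    if (any(cf < 0)) next
    x[S] <- cf
    obj <- sum((d - C %*% x)^2)
    if (obj < best$obj - 1e-12) best <- list(x = x, obj = obj)
  }
  best
}

# Uniformly random binary matrix with a fixed number of interactions and no
# empty row or column (rejection sampling).
random_infection_matrix <- function(n_h, n_v, n_interactions, seed) {
  set.seed(seed)
  repeat {
    M <- matrix(0, n_h, n_v)
    M[sample(n_h * n_v, n_interactions)] <- 1
    if (all(rowSums(M) > 0) && all(colSums(M) > 0)) return(M)
  }
}

# Small feasible community reused across test files.
small_system <- function(seed = 1, n_h = 4, n_v = 4, n_modules = 2) {
  M <- modular_matrix(n_h, n_v, n_modules)
  params <- feasible_parameters(M, seed = seed)
  list(M = M, params = params)
}

# All binary matrices of a given shape with at least one interaction.
all_binary_matrices <- function(n_r, n_c) {
  n <- n_r * n_c
  lapply(1:(2^n - 1), function(mask) {
    matrix(as.integer(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0), n_r, n_c)
  })
}
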