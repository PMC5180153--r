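#' Ensemble of infection matrices spanning a nestedness spectrum
#'
#' Generates a sequence of binary infection matrices of fixed shape and fixed
#' interaction count whose NODF nestedness grows from a perfectly modular
#' start to the maximally nested configuration achievable at that fill.
#' The spectrum is traced by a random single-interaction rewiring bridge
#' between [modular_matrix()] and [max_nested_matrix()] at the same fill:
#' successive matrices differ by moving one interaction to an empty cell,
#' NODF never decreases along the returned sequence, no move empties a row
#' or column, and tie-breaking among candidate cells is random.  Snapshots
#' of the trajectory are taken on an (as nearly as achievable) even NODF
#' grid.
#'
#' Note that the attainable NODF ceiling depends on the fill: NODF = 1
#' requires strictly decreasing row and column degrees, which in an
#' `n x n` matrix needs `n(n+1)/2` interactions.  The default 10 x 10,
#' 5-module ensemble carries 20 interactions and therefore tops out at the
#' NODF of `max_nested_matrix(10, 10, 20)` (17/45).
#'
#' @param n_h,n_v numbers of host and virus types.
#' @param n_modules module count of the starting matrix.
#' @param n_matrices number of snapshots to return (at least 2).
#' @param seed integer seed; identical seeds reproduce identical ensembles.
#' @param max_iter proposal budget for the rewiring process.
#' @return An object of class `"matrix_ensemble"`: a list with elements
#'   `matrices` (list of binary matrices), `nodf_values` (non-decreasing
#'   numeric vector) and `meta` (shape, fill, seed, convergence flag).
#' @examples
#' ens <- nestedness_ensemble(10, 10, 5, n_matrices = 10, seed = 1)
#' ens$nodf_values
#' @export
nestedness_ensemble <- function(n_h = 10, n_v = 10, n_modules = 5,
                                n_matrices = 100, seed = NULL,
                                max_iter = 20000) {
  if (!is_count(n_matrices) || n_matrices < 2) {
    stop_input("'n_matrices' must be an integer >= 2")
  }
  M0 <- modular_matrix(n_h, n_v, n_modules)
  fill <- sum(M0)
  target <- nodf(max_nested_matrix(n_h, n_v, fill))
  with_seed(seed, {
    traj <- rewire_towards_nested(M0, target, max_iter)
  })
  reached <- length(traj$matrices) >= ceiling(n_matrices / 2)
  if (!reached) {
    warning("rewiring trajectory has only ", length(traj$matrices),
            " states for ", n_matrices, " requested snapshots; ",
            "snapshots are heavily duplicated")
  }
  grid <- seq(traj$nodf[1L], traj$nodf[length(traj$nodf)],
              length.out = n_matrices)
  idx <- vapply(grid, function(g) which(traj$nodf >= g - 1e-12)[1L], 1L)
  structure(list(
    matrices = traj$matrices[idx],
    nodf_values = traj$nodf[idx],
    meta = list(n_h = n_h, n_v = n_v, n_modules = n_modules,
                n_interactions = fill, seed = seed,
                converged = reached, proposals = traj$proposals)
  ), class = "matrix_ensemble")
}

# Single-interaction rewiring bridge between the modular and maximally
# nested configurations of the same fill.  The chain walks DOWN from the
# nested end: at each step a random donor interaction is moved to the empty
# cell giving the smallest available strict NODF decrease (fill conserved,
# no row or column emptied).  Reversing the recorded trajectory yields a
# monotone non-decreasing sequence of single-move neighbours ending exactly
# at the maximally nested matrix; the modular matrix is prepended as the
# canonical low-nestedness end.  (A direct ascending chain that only accepts
# non-decreasing moves strands on a local maximum well below the ceiling,
# which is why the bridge is built from the top.)
rewire_towards_nested <- function(M, target, max_iter) {
  n_h <- nrow(M); n_v <- ncol(M)
  npair <- choose(n_h, 2) + choose(n_v, 2)
  # same metric as nodf(), with pair indices hoisted out of the move loop
  utri <- function(n) {
    idx <- which(upper.tri(diag(n)))
    list(i = (idx - 1L) %% n + 1L, k = (idx - 1L) %/% n + 1L)
  }
  ur <- utri(n_h); uc <- utri(n_v)
  nodf_q <- function(X) {
    dr <- rowSums(X); dc <- colSums(X)
    ovr <- tcrossprod(X)[upper.tri(diag(n_h))]
    ovc <- crossprod(X)[upper.tri(diag(n_v))]
    mr <- pmin(dr[ur$i], dr[ur$k])
    mc <- pmin(dc[uc$i], dc[uc$k])
    keep_r <- dr[ur$i] != dr[ur$k] & mr > 0
    keep_c <- dc[uc$i] != dc[uc$k] & mc > 0
    (sum(ovr[keep_r] / mr[keep_r]) + sum(ovc[keep_c] / mc[keep_c])) / npair
  }
  Mc <- max_nested_matrix(n_h, n_v, sum(M))
  cur <- nodf_q(Mc)
  mats <- list(Mc)
  vals <- cur
  floor_val <- nodf_q(M)
  it <- 0L
  miss <- 0L
  while (cur > floor_val + 1e-12 && it < max_iter && miss < 50L) {
    it <- it + 1L
    filled <- which(Mc == 1)
    donors <- filled[vapply(filled, function(from) {
      fi <- (from - 1L) %% n_h + 1L
      fj <- (from - 1L) %/% n_h + 1L
      sum(Mc[fi, ]) > 1 && sum(Mc[, fj]) > 1
    }, TRUE)]
    if (length(donors) == 0L) break
    if (length(donors) > 8L) donors <- sample(donors, 8L)
    empty <- which(Mc == 0)
    # slowest descent: over the sampled donors, the move with the smallest
    # strict NODF decrease, random tie-breaking
    best <- -Inf
    best_moves <- NULL
    for (from in donors) {
      Mc[from] <- 0
      cand <- vapply(empty, function(to) {
        Mc[to] <- 1
        nodf_q(Mc)
      }, 0)
      Mc[from] <- 1
      lower <- which(cand < cur - 1e-15)
      if (length(lower) == 0L) next
      top <- max(cand[lower])
      if (top > best + 1e-15) {
        best <- top
        best_moves <- cbind(from, empty[lower[cand[lower] >= top - 1e-15]])
      } else if (top > best - 1e-15) {
        best_moves <- rbind(best_moves,
                            cbind(from, empty[lower[cand[lower] >= top - 1e-15]]))
      }
    }
    if (is.null(best_moves)) {
      miss <- miss + 1L
      next
    }
    pick <- best_moves[sample.int(nrow(best_moves), 1L), ]
    Mc[pick[1L]] <- 0
    Mc[pick[2L]] <- 1
    cur <- best
    mats[[length(mats) + 1L]] <- Mc
    vals <- c(vals, cur)
    miss <- 0L
  }
  # reverse into an ascending trajectory and seed it with the modular matrix
  mats <- rev(mats)
  vals <- rev(vals)
  if (vals[1L] > floor_val + 1e-12) {
    mats <- c(list(M), mats)
    vals <- c(floor_val, vals)
  }
  list(matrices = mats, nodf = vals, proposals = it)
}

#' @export
print.matrix_ensemble <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "Infection-matrix ensemble: %d matrices, %d hosts x %d viruses, %d interactions\n",
    length(x$matrices), m$n_h, m$n_v, m$n_interactions))
  cat(sprintf("NODF range: %.4f - %.4f%s\n",
              min(x$nodf_values), max(x$nodf_values),
              if (isTRUE(m$converged)) "" else " (ceiling not reached)"))
  invisible(x)
}

#' Write or read a matrix ensemble as CSV files plus a JSON index
#'
#' Each matrix is stored as a headerless 0/1 CSV (`matrix_001.csv`, ...);
#' `index.json` records the shape, fill, seed and the NODF value of every
#' matrix.
#'
#' @param ensemble a `"matrix_ensemble"` object.
#' @param dir directory to write to (created if missing).
#' @return `write_ensemble()` returns `dir` invisibly; `read_ensemble()`
#'   returns a `"matrix_ensemble"`.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "matrix_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("matrix_%03d.csv", seq_along(ensemble$matrices))
  for (k in seq_along(files)) {
    write_matrix_csv(ensemble$matrices[[k]], file.path(dir, files[k]))
  }
  idx <- c(ensemble$meta, list(files = files, nodf = ensemble$nodf_values))
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  mats <- lapply(file.path(dir, idx$files), read_matrix_csv)
  meta <- idx[setdiff(names(idx), c("files", "nodf"))]
  structure(list(matrices = mats, nodf_values = idx$nodf, meta = meta),
            class = "matrix_ensemble")
}
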