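#' Validate a binary infection matrix
#'
#' An infection matrix `M` encodes who infects whom: rows are host types,
#' columns are virus types, and `M[i, j] = 1` when virus `j` can infect and
#' lyse host `i`.  A usable matrix has no all-zero row and no all-zero column:
#' every host must be infected by at least one virus and every virus must have
#' at least one host, otherwise no coexistence equilibrium with all types
#' present exists (see [derive_growth_decay()]).
#'
#' @param M matrix of 0/1 values, hosts in rows, viruses in columns.
#' @param require_cover if `TRUE` (default), reject matrices with an empty row
#'   or column.
#' @return `M`, invisibly, after validation.
#' @seealso [modular_matrix()], [max_nested_matrix()], [nodf()]
#' @export
validate_infection_matrix <- function(M, require_cover = TRUE) {
  check_matrix(M, "M")
  if (any(M != 0 & M != 1)) {
    stop_input("infection matrix entries must all be 0 or 1")
  }
  if (require_cover) {
    if (any(rowSums(M) == 0)) {
      stop_input("infection matrix has an all-zero row (host with no virus)")
    }
    if (any(colSums(M) == 0)) {
      stop_input("infection matrix has an all-zero column (virus with no host)")
    }
  }
  invisible(M)
}

#' Block-diagonal (modular) infection matrix
#'
#' Builds a perfectly modular bipartite network: hosts and viruses are split
#' into `n_modules` contiguous groups of near-equal size and each module is
#' fully connected internally, with no interactions between modules.  This is
#' the canonical low-nestedness end of the nestedness spectrum and the seed of
#' [nestedness_ensemble()].
#'
#' @param n_h,n_v numbers of host and virus types.
#' @param n_modules number of modules; must not exceed `min(n_h, n_v)`.
#' @return A binary `n_h` x `n_v` matrix.
#' @examples
#' modular_matrix(10, 10, 5)  # five 2x2 all-ones blocks, 20 interactions
#' @export
modular_matrix <- function(n_h, n_v, n_modules) {
  if (!is_count(n_h) || !is_count(n_v) || !is_count(n_modules)) {
    stop_input("'n_h', 'n_v' and 'n_modules' must be positive integers")
  }
  if (n_modules > min(n_h, n_v)) {
    stop_input("'n_modules' must not exceed min(n_h, n_v)")
  }
  row_grp <- sort(rep_len(seq_len(n_modules), n_h))
  col_grp <- sort(rep_len(seq_len(n_modules), n_v))
  M <- matrix(0, n_h, n_v)
  for (b in seq_len(n_modules)) {
    M[row_grp == b, col_grp == b] <- 1
  }
  validate_infection_matrix(M)
  M
}

#' Maximally nested infection matrix at a given fill
#'
#' Constructs an upper-left-justified staircase matrix: row lengths are
#' non-increasing, every row is a prefix of the columns, and the lengths are
#' kept as close to strictly decreasing as the requested number of
#' interactions allows.  Among matrices with that shape and fill this profile
#' maximizes the NODF nestedness metric; when the fill admits strictly
#' decreasing row and column degrees (e.g. 55 interactions in a 10 x 10
#' matrix), the result scores exactly `nodf = 1`.
#'
#' @param n_h,n_v numbers of host and virus types.
#' @param n_interactions total number of 1 entries.  Must be at least
#'   `n_h + n_v - 1` (the sparsest staircase covering every row and column)
#'   and at most `n_h * n_v`.
#' @return A binary `n_h` x `n_v` matrix with no empty row or column.
#' @examples
#' max_nested_matrix(2, 2, 3)          # rows 11 / 10
#' nodf(max_nested_matrix(10, 10, 55)) # exactly 1
#' @export
max_nested_matrix <- function(n_h, n_v, n_interactions) {
  if (!is_count(n_h) || !is_count(n_v) || !is_count(n_interactions)) {
    stop_input("'n_h', 'n_v' and 'n_interactions' must be positive integers")
  }
  if (n_interactions < n_h + n_v - 1 || n_interactions > n_h * n_v) {
    stop_input(sprintf(
      "infeasible fill: need between %d and %d interactions for a %d x %d staircase",
      n_h + n_v - 1, n_h * n_v, n_h, n_v
    ))
  }
  # Row-length profile: first row spans all columns (so every virus has a
  # host), every later row keeps at least one interaction, and the surplus is
  # spent making consecutive lengths differ (strict decrease scores, ties do
  # not -- see nodf()).
  len <- rep(1L, n_h)
  len[1L] <- n_v
  rem <- n_interactions - n_v - (n_h - 1L)
  for (i in seq_len(n_h)[-1L]) {
    if (rem <= 0L) break
    up <- min(len[i - 1L] - len[i] - 1L, rem)
    if (i == n_h) up <- min(len[i - 1L] - len[i], rem)  # last row may tie
    if (up > 0L) {
      len[i] <- len[i] + up
      rem <- rem - up
    }
  }
  # Any remainder that strict decrease could not absorb is stacked greedily
  # from the top while preserving monotonicity.
  for (i in seq_len(n_h)[-1L]) {
    if (rem <= 0L) break
    up <- min(len[i - 1L] - len[i], rem)
    len[i] <- len[i] + up
    rem <- rem - up
  }
  M <- matrix(0, n_h, n_v)
  for (i in seq_len(n_h)) M[i, seq_len(len[i])] <- 1
  validate_infection_matrix(M)
  M
}
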