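#' NODF nestedness of a binary matrix
#'
#' Nestedness by Overlap and Decreasing Fill, normalized to `[0, 1]`.  For
#' every unordered pair of rows the pair contributes 0 when the two row
#' degrees are equal (or the sparser row is empty), and otherwise contributes
#' the fraction of the sparser row's interactions that are shared with the
#' denser row; column pairs contribute analogously.  NODF is the mean
#' contribution over all row pairs and column pairs.  A value of 1 means
#' every pair of lines has strictly different degrees and the sparser line is
#' a perfect subset of the denser one.
#'
#' The strict "decreasing fill" rule (degree ties score zero) follows the
#' original definition of the metric; [vegan::nestednodf()] computes the same
#' quantity on a 0-100 scale.
#'
#' @param M binary matrix (rows = hosts, columns = viruses).  Empty rows or
#'   columns are allowed here -- they simply contribute zero -- but the
#'   matrix must contain at least one interaction.
#' @return A single number in `[0, 1]`.
#' @examples
#' nodf(max_nested_matrix(10, 10, 55))  # 1
#' nodf(diag(2))                        # 0: equal degrees, no overlap
#' nodf(matrix(1, 3, 3))                # 0: all degrees tied
#' @export
nodf <- function(M) {
  check_matrix(M, "M")
  if (any(M != 0 & M != 1)) {
    stop_input("'M' must be a binary (0/1) matrix")
  }
  if (sum(M) == 0) {
    stop_input("NODF is undefined for an all-zero matrix")
  }
  storage.mode(M) <- "double"
  total <- pair_sum(M) + pair_sum(t(M))
  n_pairs <- choose(nrow(M), 2) + choose(ncol(M), 2)
  if (n_pairs == 0) {
    return(0)
  }
  total / n_pairs
}

# Sum of pairwise row contributions: overlap / min degree for strictly
# unequal degrees, zero otherwise.
pair_sum <- function(M) {
  deg <- rowSums(M)
  if (length(deg) < 2L) {
    return(0)
  }
  ov <- tcrossprod(M)           # shared interactions per row pair
  mindeg <- outer(deg, deg, pmin)
  unequal <- outer(deg, deg, "!=") & mindeg > 0
  contrib <- ifelse(unequal, ov / ifelse(mindeg > 0, mindeg, 1), 0)
  sum(contrib[upper.tri(contrib)])
}
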