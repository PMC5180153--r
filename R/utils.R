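# Internal helpers shared across the package.

# Evaluate `code` with a temporary RNG state seeded by `seed`.
# `seed = NULL` uses (and advances) the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed array derived from a master seed via one draw of
# sample.int().  Every stochastic step of a sweep indexes into such an array,
# so grid points are statistically independent but fully reproducible.
seed_array <- function(master, dims) {
  n <- prod(dims)
  s <- with_seed(master, sample.int(2147483646L, n, replace = FALSE))
  array(s, dim = dims)
}

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Rectangular numeric matrix check with a contextual error.
check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_input(sprintf("'%s' must be a numeric matrix", name))
  }
  x
}
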