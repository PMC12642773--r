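# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Halton low-discrepancy sequence (radical inverse in the first `dim` primes),
# with a seeded random shift modulo 1 so multistart searches are reproducible
# but not pinned to one lattice.
halton_points <- function(n, dim, seed = NULL) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (dim > length(primes)) stop("halton_points supports at most 12 dimensions")
  radical_inverse <- function(i, base) {
    f <- 1 / base
    r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  pts <- vapply(seq_len(dim), function(d) {
    vapply(seq_len(n), radical_inverse, numeric(1), base = primes[d])
  }, numeric(n))
  pts <- matrix(pts, nrow = n, ncol = dim)
  if (!is.null(seed)) {
    shift <- with_seed(seed, stats::runif(dim))
    pts <- sweep(pts, 2, shift, "+") %% 1
  }
  pts
}

# Fixed 12-significant-digit formatting used by every exporter, so identical
# runs produce byte-identical artifacts.
fmt_num <- function(x) {
  formatC(x, digits = 12, format = "g", width = 1)
}

stop_viadeco <- function(message, class, ...) {
  stop(structure(
    class = c(class, "viadeco_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
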