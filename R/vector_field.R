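#' Define an autonomous vector field
#'
#' A `VectorField` is the right-hand side of an autonomous ODE system
#' \eqn{\dot x = f(x)} over an `n`-dimensional state space, optionally with an
#' analytic Jacobian. When no Jacobian is supplied a scale-aware central
#' finite difference with step `h = 1e-6 * max(1, ||x||)` is used; the step
#' rule is recorded on the object.
#'
#' @param rhs Function mapping a length-`n` numeric state to its length-`n`
#'   derivative.
#' @param dimension Positive integer, the state-space dimension `n`.
#' @param jacobian Optional function mapping a state to the `n x n` Jacobian
#'   matrix of `rhs`.
#' @param names Optional character vector of variable labels (length `n`).
#' @return An object of class `VectorField`.
#' @examples
#' f <- vector_field(function(x) -(x - c(0.5, 0.5)), dimension = 2)
#' eval_field(f, c(1, 0))
#' @export
vector_field <- function(rhs, dimension, jacobian = NULL, names = NULL) {
  stopifnot(is.function(rhs), length(dimension) == 1, dimension >= 1,
            dimension == as.integer(dimension))
  if (!is.null(names) && length(names) != dimension) {
    stop("names must have length `dimension`")
  }
  test <- rhs(rep(0.5, dimension))
  if (length(test) != dimension) {
    stop("rhs output length must equal `dimension`")
  }
  structure(
    list(dimension = as.integer(dimension), rhs = rhs, jacobian = jacobian,
         names = names, fd_step = "1e-6 * max(1, ||x||)"),
    class = "VectorField"
  )
}

#' Linear vector field \eqn{\dot x = A (x - c)}
#'
#' Convenience constructor for affine fields centred at `center`; the analytic
#' Jacobian (`A`) is attached automatically.
#'
#' @param A Square coefficient matrix.
#' @param center Numeric vector, the equilibrium of the field.
#' @param names Optional variable labels.
#' @return A `VectorField`.
#' @export
linear_field <- function(A, center = rep(0, nrow(A)), names = NULL) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), length(center) == nrow(A))
  force(A); force(center)
  vector_field(
    rhs = function(x) as.numeric(A %*% (x - center)),
    dimension = nrow(A),
    jacobian = function(x) A,
    names = names
  )
}

#' Evaluate a vector field
#'
#' @param field A `VectorField`.
#' @param x Numeric state of the field's dimension.
#' @return The derivative vector `f(x)`.
#' @export
eval_field <- function(field, x) {
  stopifnot(inherits(field, "VectorField"))
  if (length(x) != field$dimension) {
    stop_viadeco("state length does not match field dimension", "dimension_mismatch")
  }
  field$rhs(as.numeric(x))
}

#' Jacobian of a vector field at a state
#'
#' Uses the analytic Jacobian when present, otherwise the recorded central
#' finite-difference rule.
#'
#' @inheritParams eval_field
#' @return An `n x n` numeric matrix.
#' @export
field_jacobian <- function(field, x) {
  stopifnot(inherits(field, "VectorField"))
  x <- as.numeric(x)
  if (!is.null(field$jacobian)) {
    return(as.matrix(field$jacobian(x)))
  }
  n <- field$dimension
  h <- 1e-6 * max(1, sqrt(sum(x^2)))
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h
    J[, j] <- (field$rhs(x + e) - field$rhs(x - e)) / (2 * h)
  }
  J
}

#' @export
print.VectorField <- function(x, ...) {
  cat("<VectorField> dimension", x$dimension,
      if (is.null(x$jacobian)) "(finite-difference Jacobian)" else "(analytic Jacobian)",
      "\n")
  invisible(x)
}
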