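#' Locate equilibria of a vector field by seeded multistart root finding
#'
#' Damped Newton iterations are launched from a seeded low-discrepancy
#' (Halton) point set inside `search_box`. Converged roots within the merge
#' radius of one another are collapsed. Multistart search gives no
#' completeness guarantee: the returned list may miss equilibria, it only ever
#' contains genuine roots.
#'
#' @param field A [vector_field()].
#' @param search_box List with numeric `lower` and `upper` (finite, per
#'   variable).
#' @param n_starts Number of start points (>= 1).
#' @param seed Integer seed for the start-point shift.
#' @param tol Root tolerance on `||f(x)||`.
#' @param merge_radius Roots closer than this are treated as duplicates.
#' @return List of `Equilibrium` objects (possibly empty).
#' @export
find_equilibria <- function(field, search_box, n_starts = 32, seed = 1,
                            tol = 1e-9, merge_radius = 1e-6) {
  stopifnot(inherits(field, "VectorField"), n_starts >= 1)
  lo <- as.numeric(search_box$lower)
  hi <- as.numeric(search_box$upper)
  stopifnot(length(lo) == field$dimension, length(hi) == field$dimension,
            all(is.finite(lo)), all(is.finite(hi)), all(lo < hi))
  u <- halton_points(n_starts, field$dimension, seed = seed)
  starts <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  roots <- list()
  for (i in seq_len(n_starts)) {
    x <- newton_root(field, starts[i, ], tol = tol)
    if (is.null(x)) next
    dup <- any(vapply(roots, function(r) sqrt(sum((r - x)^2)) < merge_radius,
                      logical(1)))
    if (!dup) roots <- c(roots, list(x))
  }
  lapply(roots, function(r) stability(field, r, tol = max(tol, 1e-8)))
}

newton_root <- function(field, x0, tol = 1e-9, maxit = 100) {
  x <- as.numeric(x0)
  for (i in seq_len(maxit)) {
    fx <- tryCatch(field$rhs(x), error = function(e) NULL)
    if (is.null(fx) || !all(is.finite(fx))) return(NULL)
    if (sqrt(sum(fx^2)) < tol) return(x)
    J <- tryCatch(field_jacobian(field, x), error = function(e) NULL)
    if (is.null(J) || !all(is.finite(J))) return(NULL)
    dx <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    # backtracking line search on ||f||^2
    lam <- 1
    f2 <- sum(fx^2)
    repeat {
      xn <- x - lam * dx
      fn <- tryCatch(field$rhs(xn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) && sum(fn^2) < f2) break
      lam <- lam / 2
      if (lam < 1e-8) return(NULL)
    }
    x <- xn
  }
  fx <- field$rhs(x)
  if (sqrt(sum(fx^2)) < tol) x else NULL
}

#' Linear stability of an equilibrium
#'
#' Classifies an equilibrium by the eigenvalues of the Jacobian at the point.
#' Labels: `stable_node` (all real parts negative, real spectrum),
#' `stable_spiral` (all real parts negative, complex pair), `saddle` (mixed
#' signs), `unstable` (all positive), `center` (real parts within `tol` of
#' zero; flagged `degenerate` when the imaginary parts also vanish).
#'
#' @param field A [vector_field()].
#' @param x_eq Candidate equilibrium state.
#' @param tol Tolerance both on `||f(x_eq)||` and on treating a real part as
#'   zero.
#' @return An `Equilibrium`: list with `location`, `eigenvalues`, `stability`,
#'   and `degenerate` flag.
#' @export
stability <- function(field, x_eq, tol = 1e-8) {
  stopifnot(inherits(field, "VectorField"))
  x_eq <- as.numeric(x_eq)
  res <- sqrt(sum(field$rhs(x_eq)^2))
  if (res > tol * max(1, sqrt(sum(x_eq^2)))) {
    stop_viadeco(sprintf("||f(x)|| = %.3e exceeds tolerance: not an equilibrium", res),
                 "not_an_equilibrium")
  }
  ev <- eigen(field_jacobian(field, x_eq), only.values = TRUE)$values
  ev <- as.complex(ev)
  re <- Re(ev)
  has_imag <- any(abs(Im(ev)) > tol)
  label <- if (all(abs(re) <= tol)) {
    "center"
  } else if (all(re < -tol)) {
    if (has_imag) "stable_spiral" else "stable_node"
  } else if (all(re > tol)) {
    "unstable"
  } else if (any(re > tol) && any(re < -tol)) {
    "saddle"
  } else {
    "center" # some real parts at zero, others signed: degenerate boundary case
  }
  degenerate <- all(abs(re) <= tol) && !has_imag || (any(abs(re) <= tol) && !all(abs(re) <= tol))
  structure(
    list(location = x_eq, eigenvalues = ev, stability = label,
         degenerate = degenerate, residual = res),
    class = "Equilibrium"
  )
}

#' @export
print.Equilibrium <- function(x, ...) {
  cat("<Equilibrium> (", paste(signif(x$location, 6), collapse = ", "), ") ",
      x$stability, if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}
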