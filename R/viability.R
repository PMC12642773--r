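#' Viability constraints and regions
#'
#' A viability region is the set of states in which a model cell counts as
#' alive. It is specified as a list of constraints, each of which is either a
#' box constraint (one bound on one variable) or a smooth scalar constraint
#' `g(x) <= 0`. The region is the set of states satisfying every constraint;
#' the closed convention is used throughout, so states exactly on the boundary
#' are members.
#'
#' @param index Variable index the bound applies to.
#' @param side `"lower"` or `"upper"`.
#' @param threshold Bound value; may be `-Inf`/`Inf` (an infinite bound is
#'   never violated).
#' @param id Stable label for the constraint; generated from index/side when
#'   omitted.
#' @return A `Constraint` object.
#' @export
box_constraint <- function(index, side = c("lower", "upper"), threshold, id = NULL) {
  side <- match.arg(side)
  id <- id %||% sprintf("x%d_%s", index, side)
  structure(
    list(type = "box", index = as.integer(index), side = side,
         threshold = threshold, id = id),
    class = "Constraint"
  )
}

#' @rdname box_constraint
#' @param g Scalar function with `g(x) <= 0` on viable states.
#' @param gradient Optional gradient function of `g`.
#' @export
smooth_constraint <- function(g, gradient = NULL, id) {
  structure(
    list(type = "smooth", g = g, gradient = gradient, id = id),
    class = "Constraint"
  )
}

#' Assemble a viability region from constraints
#'
#' @param constraints List of `Constraint` objects; at least one must be
#'   finite.
#' @param dimension State-space dimension the region lives in.
#' @return A `ViabilityRegion`.
#' @seealso [box_region()] for the common all-box case.
#' @export
viability_region <- function(constraints, dimension) {
  stopifnot(length(constraints) >= 1,
            all(vapply(constraints, inherits, logical(1), "Constraint")))
  finite <- vapply(constraints, function(k) {
    k$type == "smooth" || is.finite(k$threshold)
  }, logical(1))
  if (!any(finite)) stop("at least one constraint must be finite")
  ids <- vapply(constraints, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("constraint ids must be unique")
  structure(
    list(constraints = constraints, dimension = as.integer(dimension), ids = ids),
    class = "ViabilityRegion"
  )
}

#' Axis-aligned box viability region
#'
#' @param lower,upper Numeric vectors of per-variable bounds (may contain
#'   `-Inf`/`Inf`; infinite bounds generate no constraint).
#' @param names Optional variable labels used in constraint ids.
#' @return A `ViabilityRegion` whose constraints are the finite bounds.
#' @examples
#' box_region(c(0, 0), c(1, 1))
#' @export
box_region <- function(lower, upper, names = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  n <- length(lower)
  labs <- names %||% paste0("x", seq_len(n))
  cons <- list()
  for (i in seq_len(n)) {
    if (is.finite(lower[i])) {
      cons <- c(cons, list(box_constraint(i, "lower", lower[i],
                                          id = paste0(labs[i], "_lower"))))
    }
    if (is.finite(upper[i])) {
      cons <- c(cons, list(box_constraint(i, "upper", upper[i],
                                          id = paste0(labs[i], "_upper"))))
    }
  }
  viability_region(cons, dimension = n)
}

# Signed constraint value: negative inside, zero on the facet, positive when
# violated. Box constraints have unit-gradient values, so -value is the
# Euclidean distance to the facet.
constraint_value <- function(con, x) {
  if (con$type == "box") {
    if (!is.finite(con$threshold)) return(-Inf)
    if (con$side == "lower") con$threshold - x[con$index] else x[con$index] - con$threshold
  } else {
    con$g(x)
  }
}

region_values <- function(region, x) {
  v <- vapply(region$constraints, constraint_value, numeric(1), x = x)
  names(v) <- region$ids
  v
}

# Outward unit normal of a constraint's facet at x.
constraint_normal <- function(con, x, dimension) {
  if (con$type == "box") {
    n <- rep(0, dimension)
    n[con$index] <- if (con$side == "lower") -1 else 1
    n
  } else {
    if (is.null(con$gradient)) {
      h <- 1e-6 * max(1, sqrt(sum(x^2)))
      g <- vapply(seq_len(dimension), function(j) {
        e <- rep(0, dimension); e[j] <- h
        (con$g(x + e) - con$g(x - e)) / (2 * h)
      }, numeric(1))
    } else {
      g <- con$gradient(x)
    }
    g / sqrt(sum(g^2))
  }
}

#' Test membership of a state in a viability region
#'
#' Boundary states are members (closed-region convention).
#'
#' @param region A `ViabilityRegion`.
#' @param x Numeric state.
#' @param tol Slack allowed on constraint values (default exact).
#' @return Logical flag.
#' @export
region_contains <- function(region, x, tol = 0) {
  if (length(x) != region$dimension) {
    stop_viadeco("state length does not match region dimension", "dimension_mismatch")
  }
  all(region_values(region, x) <= tol)
}

# Distance from an interior state to the nearest facet (exact for box
# constraints, first-order for smooth ones).
boundary_distance <- function(region, x) {
  d <- vapply(region$constraints, function(con) {
    v <- constraint_value(con, x)
    if (con$type == "box") return(-v)
    # first-order distance estimate for smooth constraints
    g <- constraint_normal(con, x, region$dimension) # unit vector
    gn <- sqrt(sum((con$gradient %||% function(z) g)(x)^2))
    if (!is.finite(gn) || gn == 0) gn <- 1
    -v / gn
  }, numeric(1))
  min(d)
}

# Per-variable finite bounds implied by the box constraints (Inf when absent).
box_hull <- function(region) {
  lo <- rep(-Inf, region$dimension)
  hi <- rep(Inf, region$dimension)
  for (con in region$constraints) {
    if (con$type != "box" || !is.finite(con$threshold)) next
    if (con$side == "lower") lo[con$index] <- max(lo[con$index], con$threshold)
    else hi[con$index] <- min(hi[con$index], con$threshold)
  }
  list(lower = lo, upper = hi)
}

#' @export
print.ViabilityRegion <- function(x, ...) {
  cat("<ViabilityRegion> dimension", x$dimension, "with",
      length(x$constraints), "constraints:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}
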