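#' Classify a state as asymptotically or transiently viable
#'
#' The brute-force classifier: integrate forward from `x0` with stopping
#' events on the region's constraints and on convergence to a supplied viable
#' attractor.
#'
#' * `nonmember` — `x0` is outside the (closed) region.
#' * `transiently_viable` — the trajectory crosses a constraint in finite
#'   time; `violated` holds every constraint id crossing within `tie_tol` of
#'   the first crossing (a joint fatality), `death_time` the refined crossing
#'   time.
#' * `asymptotically_viable` — the trajectory comes within `conv_tol` of a
#'   viable attractor (an attractor strictly inside the region).
#' * `undecided` — the horizon was reached without either outcome. A slow
#'   transient is never silently reported as survival.
#'
#' @param field A [vector_field()].
#' @param region A [viability_region()].
#' @param x0 Initial state.
#' @param horizon Positive simulation horizon (default 50 time units).
#' @param attractors List of `Equilibrium` objects or states; only those
#'   inside the region count as viable convergence targets.
#' @param conv_tol Convergence radius around an attractor.
#' @param tie_tol Constraints crossing within this window of the first
#'   crossing are reported together.
#' @param rtol,atol Solver tolerances.
#' @return A `ViabilityLabel`: list with `status`, and per status `violated`,
#'   `death_time`, or `attractor`.
#' @export
classify_state <- function(field, region, x0, horizon = 50, attractors = list(),
                           conv_tol = 1e-2, tie_tol = 1e-9,
                           rtol = 1e-8, atol = 1e-10) {
  if (horizon <= 0) stop("horizon must be positive")
  x0 <- as.numeric(x0)
  if (!region_contains(region, x0)) {
    v <- region_values(region, x0)
    return(new_label("nonmember", violated = names(v)[v > 0]))
  }
  viable_att <- Filter(function(a) {
    loc <- if (inherits(a, "Equilibrium")) a$location else as.numeric(a)
    region_contains(region, loc)
  }, attractors)
  # a start already inside the convergence radius never crosses it
  for (a in viable_att) {
    loc <- if (inherits(a, "Equilibrium")) a$location else as.numeric(a)
    if (sqrt(sum((x0 - loc)^2)) <= conv_tol) {
      return(new_label("asymptotically_viable", attractor = a))
    }
  }
  traj <- integrate_field(field, x0, duration = horizon, direction = "forward",
                          events = region, attractors = viable_att,
                          conv_tol = conv_tol, rtol = rtol, atol = atol)
  term <- traj$termination
  if (term$type == "event") {
    xe <- trajectory_end(traj)
    ids <- union(term$constraint_ids, tied_constraints(field, region, xe, tie_tol))
    return(new_label("transiently_viable", violated = ids,
                     death_time = term$time, trajectory = traj))
  }
  if (term$type == "attractor_converged") {
    att <- viable_att[[term$attractor_index]]
    return(new_label("asymptotically_viable", attractor = att, trajectory = traj))
  }
  new_label("undecided", trajectory = traj)
}

# Constraints whose facet the state sits on (|value| small) and whose
# time-to-crossing at the current outward rate is within tie_tol: these cross
# "simultaneously" with the event that halted integration.
tied_constraints <- function(field, region, x, tie_tol) {
  f <- eval_field(field, x)
  hits <- character(0)
  for (con in region$constraints) {
    v <- constraint_value(con, x)
    if (!is.finite(v)) next
    nrm <- constraint_normal(con, x, region$dimension)
    rate <- sum(f * nrm)
    if (abs(v) <= 1e-12 || (rate > 0 && -v / rate <= tie_tol)) {
      hits <- c(hits, con$id)
    }
  }
  hits
}

new_label <- function(status, violated = NULL, death_time = NULL,
                      attractor = NULL, trajectory = NULL) {
  structure(
    list(status = status, violated = violated, death_time = death_time,
         attractor = attractor, trajectory = trajectory),
    class = "ViabilityLabel"
  )
}

#' @export
print.ViabilityLabel <- function(x, ...) {
  cat("<ViabilityLabel>", x$status)
  if (!is.null(x$violated)) cat(" | violated:", paste(x$violated, collapse = ","))
  if (!is.null(x$death_time)) cat(" | death_time:", fmt_num(x$death_time))
  cat("\n")
  invisible(x)
}

#' Classify a regular interior grid of states
#'
#' Applies [classify_state()] over an evenly spaced lattice of interior points
#' of the region's box hull. Lattice points are strictly interior: the grid
#' spacing places them away from the boundary (and any point within 1e-9 of a
#' facet is skipped) to avoid event-at-start ambiguity.
#'
#' @inheritParams classify_state
#' @param resolution Integer number of lattice points per axis (>= 2), or a
#'   per-axis vector.
#' @return A `LabelGrid`: list with `points` (matrix), `status` (character),
#'   `violated`, `death_time`, and `summary` (status counts).
#' @export
classify_grid <- function(field, region, resolution = 20, horizon = 50,
                          attractors = list(), conv_tol = 1e-2, ...) {
  hull <- box_hull(region)
  if (!all(is.finite(hull$lower)) || !all(is.finite(hull$upper))) {
    stop("classify_grid requires a region with finite box hull")
  }
  n <- region$dimension
  resolution <- rep(as.integer(resolution), length.out = n)
  stopifnot(all(resolution >= 2))
  axes <- lapply(seq_len(n), function(i) {
    d <- (hull$upper[i] - hull$lower[i]) / (resolution[i] + 1)
    seq(hull$lower[i] + d, hull$upper[i] - d, length.out = resolution[i])
  })
  pts <- as.matrix(expand.grid(axes))
  colnames(pts) <- NULL
  keep <- apply(pts, 1, function(x) {
    region_contains(region, x) && boundary_distance(region, x) > 1e-9
  })
  pts <- pts[keep, , drop = FALSE]
  labels <- apply(pts, 1, function(x) {
    classify_state(field, region, x, horizon = horizon,
                   attractors = attractors, conv_tol = conv_tol, ...)
  })
  status <- vapply(labels, `[[`, character(1), "status")
  violated <- vapply(labels, function(l) {
    if (is.null(l$violated)) NA_character_ else paste(l$violated, collapse = "|")
  }, character(1))
  death_time <- vapply(labels, function(l) l$death_time %||% NA_real_, numeric(1))
  structure(
    list(points = pts, status = status, violated = violated,
         death_time = death_time, summary = table(status)),
    class = "LabelGrid"
  )
}

#' @export
print.LabelGrid <- function(x, ...) {
  cat("<LabelGrid>", nrow(x$points), "points:\n")
  print(x$summary)
  invisible(x)
}

#' First constraint violation along a stored trajectory
#'
#' Scans a trajectory for the earliest constraint crossing and refines the
#' crossing time by root finding on linearly interpolated constraint values.
#' All constraints crossing within `tie_tol` of the earliest time are returned
#' together (joint fatality).
#'
#' @param traj A `Trajectory`.
#' @param region A [viability_region()] of matching dimension.
#' @param tie_tol Simultaneity window in time units.
#' @return `NULL` if the trajectory never exits, else list with `time` and
#'   `constraint_ids`.
#' @export
first_violation <- function(traj, region, tie_tol = 1e-9) {
  stopifnot(inherits(traj, "Trajectory"))
  tt <- traj$times
  vals <- apply(traj$states, 1, function(x) region_values(region, x))
  vals <- matrix(vals, ncol = length(tt)) # one row per constraint
  crossing <- rep(NA_real_, nrow(vals))
  for (k in seq_len(nrow(vals))) {
    v <- vals[k, ]
    if (v[1] > 0) { crossing[k] <- tt[1]; next }
    idx <- which(v > 0)[1]
    if (is.na(idx)) next
    if (idx == 1) { crossing[k] <- tt[1]; next }
    fv <- stats::approxfun(tt[c(idx - 1, idx)], v[c(idx - 1, idx)])
    crossing[k] <- stats::uniroot(fv, lower = tt[idx - 1], upper = tt[idx],
                                  tol = 1e-12)$root
  }
  if (all(is.na(crossing))) return(NULL)
  t0 <- min(crossing, na.rm = TRUE)
  ids <- region$ids[!is.na(crossing) & crossing <= t0 + tie_tol]
  list(time = t0, constraint_ids = ids)
}
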