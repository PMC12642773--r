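#' Integrate a vector field with boundary-event detection
#'
#' Integrates \eqn{\dot x = f(x)} forward or backward in time with an adaptive
#' solver with root finding (`deSolve::lsodar`). When a `ViabilityRegion` is
#' supplied as `events`, integration halts at the first constraint crossing;
#' the crossing state is refined by the solver's root finder. Backward
#' integration is implemented by negating the right-hand side, so times in the
#' returned trajectory are always nonnegative elapsed times in the stated
#' direction.
#'
#' @param field A [vector_field()].
#' @param x0 Initial state.
#' @param duration Positive integration time.
#' @param direction `"forward"` or `"backward"`.
#' @param events Optional `ViabilityRegion`; integration stops at the first
#'   constraint crossing.
#' @param attractors Optional list of states (or `Equilibrium` objects); an
#'   additional stopping event fires when the state comes within `conv_tol`
#'   of any of them.
#' @param conv_tol Convergence radius for `attractors`.
#' @param rtol,atol Relative/absolute solver tolerances. The tight defaults
#'   matter because manifold computations integrate backward in time, which
#'   amplifies drift.
#' @param n_out Number of requested output times (the event stop adds one).
#' @return A `Trajectory`: list with `times` (nondecreasing elapsed times),
#'   `states` (matrix, one row per time), `direction`, and `termination`
#'   (list with `type` = `"horizon_reached"`, `"event"`, or
#'   `"attractor_converged"`, plus `constraint_ids`/`time` for events).
#' @examples
#' f <- linear_field(-diag(2), center = c(0.5, 0.5))
#' tr <- integrate_field(f, c(0.9, 0.5), duration = 1)
#' tail(tr$states, 1) # approx c(0.5) + 0.4 * exp(-1) in x1
#' @export
integrate_field <- function(field, x0, duration, direction = c("forward", "backward"),
                            events = NULL, attractors = NULL, conv_tol = 1e-2,
                            rtol = 1e-8, atol = 1e-10, n_out = 201) {
  direction <- match.arg(direction)
  stopifnot(inherits(field, "VectorField"))
  x0 <- as.numeric(x0)
  if (length(x0) != field$dimension) {
    stop_viadeco("x0 length does not match field dimension", "dimension_mismatch")
  }
  if (!is.numeric(duration) || duration < 0) stop("duration must be >= 0")
  if (duration == 0) {
    return(new_trajectory(times = 0, states = matrix(x0, nrow = 1),
                          direction = direction,
                          termination = list(type = "horizon_reached")))
  }
  sgn <- if (direction == "forward") 1 else -1
  func <- function(t, y, parms) {
    dy <- sgn * field$rhs(y)
    if (!all(is.finite(dy))) {
      stop_viadeco(paste0("nonfinite derivative at state (",
                          paste(signif(y, 6), collapse = ", "), ")"),
                   "integration_failure", state = y)
    }
    list(dy)
  }

  att <- NULL
  if (!is.null(attractors) && length(attractors)) {
    att <- lapply(attractors, function(a) {
      if (inherits(a, "Equilibrium")) a$location else as.numeric(a)
    })
  }
  n_con <- if (!is.null(events)) length(events$constraints) else 0L
  n_att <- length(att %||% list())
  rootfunc <- NULL
  if (n_con + n_att > 0) {
    rootfunc <- function(t, y, parms) {
      r <- numeric(0)
      if (n_con > 0) r <- region_values(events, y)
      if (n_att > 0) {
        r <- c(r, vapply(att, function(a) sum((y - a)^2) - conv_tol^2, numeric(1)))
      }
      r
    }
  }

  times <- seq(0, duration, length.out = max(2, n_out))
  out <- deSolve::lsodar(y = x0, times = times, func = func, parms = NULL,
                         rtol = rtol, atol = atol, rootfunc = rootfunc,
                         maxsteps = 100000)
  tt <- out[, 1]
  ss <- matrix(out[, -1, drop = FALSE], ncol = field$dimension)

  termination <- list(type = "horizon_reached")
  iroot <- which(attr(out, "iroot") == 1L)
  troot <- attr(out, "troot")
  if (length(iroot) > 0 && length(troot) > 0) {
    con_hits <- iroot[iroot <= n_con]
    if (length(con_hits) > 0) {
      termination <- list(type = "event",
                          constraint_ids = events$ids[con_hits],
                          time = troot[1])
    } else {
      termination <- list(type = "attractor_converged",
                          attractor_index = iroot[iroot > n_con][1] - n_con,
                          time = troot[1])
    }
  }
  new_trajectory(times = tt, states = ss, direction = direction,
                 termination = termination)
}

new_trajectory <- function(times, states, direction, termination) {
  structure(
    list(times = times, states = states, direction = direction,
         termination = termination),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("<Trajectory>", x$direction, "|", length(x$times), "points | t in [",
      fmt_num(min(x$times)), ",", fmt_num(max(x$times)), "] |",
      x$termination$type,
      if (x$termination$type == "event")
        paste0("(", paste(x$termination$constraint_ids, collapse = ","), ")")
      else "", "\n")
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj A `Trajectory`.
#' @return The last state as a numeric vector.
#' @export
trajectory_end <- function(traj) {
  as.numeric(traj$states[nrow(traj$states), ])
}
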