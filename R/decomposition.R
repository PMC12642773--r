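#' Normal flow through a viability facet
#'
#' The component of the vector field along the outward unit normal of a
#' constraint's facet. Positive values mean the flow is immediately fatal at
#' that boundary state; negative values point into the interior; a zero is a
#' tangency.
#'
#' @param field A [vector_field()].
#' @param region A [viability_region()].
#' @param constraint_id Id of the facet's constraint.
#' @param x State on the facet (checked to `on_tol`).
#' @param on_tol Tolerance for "on the facet".
#' @return Signed scalar `f(x) . n_out`.
#' @export
normal_flow <- function(field, region, constraint_id, x, on_tol = 1e-8) {
  con <- get_constraint(region, constraint_id)
  x <- as.numeric(x)
  if (abs(constraint_value(con, x)) > on_tol) {
    stop_viadeco("state is not on the requested facet", "not_on_facet")
  }
  nrm <- constraint_normal(con, x, region$dimension)
  sum(eval_field(field, x) * nrm)
}

get_constraint <- function(region, constraint_id) {
  i <- match(constraint_id, region$ids)
  if (is.na(i)) stop("unknown constraint id: ", constraint_id)
  region$constraints[[i]]
}

# Parameterization of a 2-D box facet: the free coordinate ranges over the
# interval the remaining box constraints allow.
facet_segment <- function(region, con) {
  if (region$dimension != 2 || con$type != "box") {
    stop("exact facet scans are implemented for 2-D box constraints only")
  }
  hull <- box_hull(region)
  free <- if (con$index == 1L) 2L else 1L
  if (!is.finite(hull$lower[free]) || !is.finite(hull$upper[free])) {
    stop("facet is unbounded; bound the complementary variable to scan it")
  }
  point_at <- function(s) {
    x <- numeric(2)
    x[con$index] <- con$threshold
    x[free] <- s
    x
  }
  list(lo = hull$lower[free], hi = hull$upper[free], point_at = point_at,
       free = free)
}

#' Find tangency points of the flow on a viability facet
#'
#' Scans the normal flow along a 2-D box facet at `scan_resolution` points,
#' brackets its sign changes, and refines each root to high precision. Each
#' tangency is annotated with its crossing character (the sign change of the
#' normal flow along the facet) and its forward fate, classified from a state
#' nudged slightly into the interior (the tangency itself sits on the
#' boundary, where flow is tangent). A tangency whose forward fate is
#' asymptotically viable is a mortality point; other tangencies are retained
#' but marked non-organizing.
#'
#' @inheritParams normal_flow
#' @param scan_resolution Number of scan points along the facet (>= 2).
#' @param attractors,horizon,conv_tol Passed to [classify_state()] for the
#'   forward fate.
#' @param nudge Inward offset used for fate classification.
#' @return List of `TangencyPoint` objects: `location`, `constraint_id`,
#'   `normal_flow_residual`, `crossing_character`
#'   (`"inward_to_outward"`/`"outward_to_inward"` along increasing facet
#'   coordinate), `forward_fate` (a `ViabilityLabel`), and `organizing` flag.
#' @export
find_tangency_points <- function(field, region, constraint_id,
                                 scan_resolution = 200, attractors = list(),
                                 horizon = 50, conv_tol = 1e-2, nudge = 1e-7) {
  stopifnot(scan_resolution >= 2)
  con <- get_constraint(region, constraint_id)
  seg <- facet_segment(region, con)
  ss <- seq(seg$lo, seg$hi, length.out = scan_resolution)
  g <- function(s) normal_flow(field, region, constraint_id, seg$point_at(s))
  gv <- vapply(ss, g, numeric(1))
  out <- list()
  for (i in seq_len(length(ss) - 1)) {
    if (is.na(gv[i]) || is.na(gv[i + 1])) next
    if (gv[i] == 0 && i > 1) next # handled as a bracket endpoint below
    if (gv[i] * gv[i + 1] < 0 || (gv[i] == 0 && gv[i + 1] != 0)) {
      root <- if (gv[i] == 0) ss[i] else {
        stats::uniroot(g, lower = ss[i], upper = ss[i + 1], tol = 1e-13)$root
      }
      loc <- seg$point_at(root)
      nrm <- constraint_normal(con, loc, 2)
      fate <- classify_state(field, region, loc - nudge * nrm,
                             horizon = horizon, attractors = attractors,
                             conv_tol = conv_tol)
      character_ <- if (gv[i] < gv[i + 1]) "inward_to_outward" else "outward_to_inward"
      out <- c(out, list(structure(
        list(location = loc, constraint_id = constraint_id,
             normal_flow_residual = g(root),
             crossing_character = character_,
             forward_fate = fate,
             organizing = identical(fate$status, "asymptotically_viable")),
        class = "TangencyPoint"
      )))
    }
  }
  out
}

#' @export
print.TangencyPoint <- function(x, ...) {
  cat("<TangencyPoint> (", paste(signif(x$location, 6), collapse = ", "),
      ") on ", x$constraint_id, " | ", x$crossing_character,
      " | forward fate: ", x$forward_fate$status,
      if (x$organizing) " [mortality point]" else " [non-organizing]",
      "\n", sep = "")
  invisible(x)
}

# Backward trajectory from a boundary seed, halted at the first exit from the
# region (or the horizon). The seed is nudged `nudge` along `inward` before
# integrating because the event root function is zero on the boundary itself.
backward_polyline <- function(field, region, seed, inward, backward_horizon,
                              nudge = 1e-9, rtol = 1e-10, atol = 1e-12) {
  x_start <- seed + nudge * inward
  traj <- integrate_field(field, x_start, duration = backward_horizon,
                          direction = "backward", events = region,
                          rtol = rtol, atol = atol, n_out = 501)
  pts <- rbind(matrix(seed, nrow = 1), traj$states)
  times <- c(0, traj$times)
  converged <- FALSE
  if (traj$termination$type == "horizon_reached") {
    # backward flow may have run into an interior repeller (a backward sink)
    converged <- sqrt(sum(eval_field(field, trajectory_end(traj))^2)) < 1e-12
  }
  list(points = pts, times = times, termination = traj$termination,
       converged_to_equilibrium = converged)
}

new_manifold <- function(kind, seed, points, times, labels_either_side,
                         termination, degenerate = FALSE, flags = character(0)) {
  structure(
    list(kind = kind, seed = seed, points = points, times = times,
         labels_either_side = labels_either_side, termination = termination,
         degenerate = degenerate, flags = flags),
    class = "Manifold"
  )
}

#' @export
print.Manifold <- function(x, ...) {
  cat("<Manifold>", x$kind, "|", nrow(x$points), "points | seed (",
      paste(signif(x$seed, 6), collapse = ", "), ") | separates",
      paste(x$labels_either_side, collapse = " / "),
      if (x$degenerate) "[degenerate]" else "", "\n")
  invisible(x)
}

#' Mortality manifold seeded at a tangency point
#'
#' The backward-time trajectory of a mortality point (a boundary tangency
#' whose forward fate is asymptotically viable). It separates the
#' asymptotically viable set from the transiently viable set. Backward
#' integration halts at the first exit from the viability region or at
#' `backward_horizon`; if the backward flow converges to an interior
#' equilibrium the manifold is flagged.
#'
#' @inheritParams normal_flow
#' @param tp A `TangencyPoint` from [find_tangency_points()].
#' @param backward_horizon Maximum backward integration time.
#' @return A `Manifold` with `kind = "mortality"` and
#'   `labels_either_side = c("asymptotically_viable", "transiently_viable")`.
#' @export
mortality_manifold <- function(field, region, tp, backward_horizon = 100) {
  stopifnot(inherits(tp, "TangencyPoint"))
  if (!identical(tp$forward_fate$status, "asymptotically_viable")) {
    stop_viadeco(
      "tangency's forward fate is not asymptotically viable: it organizes nothing",
      "not_a_mortality_point")
  }
  con <- get_constraint(region, tp$constraint_id)
  inward <- -constraint_normal(con, tp$location, region$dimension)
  bp <- backward_polyline(field, region, tp$location, inward, backward_horizon)
  flags <- if (bp$converged_to_equilibrium) "converged_to_interior_equilibrium" else character(0)
  new_manifold("mortality", seed = tp$location, points = bp$points,
               times = bp$times,
               labels_either_side = c("asymptotically_viable", "transiently_viable"),
               termination = bp$termination,
               degenerate = nrow(bp$points) < 3, flags = flags)
}

#' Joint-fatal corners of a 2-D box region
#'
#' A corner where two box constraints on distinct variables intersect is
#' joint-fatal when the flow's outward normal component is strictly positive
#' for both constraints: a trajectory reaching the corner violates both
#' simultaneously. Corners where one component is zero (within `tol`) are
#' excluded from the fatal list and reported separately as marginal.
#'
#' @inheritParams normal_flow
#' @param tol Strictness tolerance on the normal components.
#' @return List with `corners` (each: `location`, `constraint_ids`,
#'   `normal_flows`) and `marginal` (same shape, at least one component within
#'   `tol` of zero).
#' @export
find_joint_fatal_corners <- function(field, region, tol = 1e-12) {
  if (region$dimension != 2) {
    stop("corner enumeration is implemented for 2-D regions (pairwise box intersections are points only there)")
  }
  box <- Filter(function(k) k$type == "box" && is.finite(k$threshold),
                region$constraints)
  if (length(box) < 2) stop("region needs at least two finite box constraints")
  corners <- list()
  marginal <- list()
  for (i in seq_along(box)) {
    for (j in seq_along(box)) {
      if (j <= i) next
      a <- box[[i]]; b <- box[[j]]
      if (a$index == b$index) next
      x <- numeric(2)
      x[a$index] <- a$threshold
      x[b$index] <- b$threshold
      if (!region_contains(region, x, tol = 1e-12)) next
      f <- eval_field(field, x)
      na_ <- constraint_normal(a, x, 2)
      nb_ <- constraint_normal(b, x, 2)
      flows <- c(sum(f * na_), sum(f * nb_))
      rec <- list(location = x, constraint_ids = c(a$id, b$id),
                  normal_flows = flows)
      if (all(flows > tol)) {
        corners <- c(corners, list(rec))
      } else if (all(flows > -tol)) {
        marginal <- c(marginal, list(rec))
      }
    }
  }
  list(corners = corners, marginal = marginal)
}

#' Ordering manifold seeded at a joint-fatal corner
#'
#' The backward-time trajectory of a joint-fatal corner. States exactly on it
#' reach the corner and violate both constraints simultaneously; on either
#' side, one or the other constraint is violated first, so the manifold
#' separates the region by death order.
#'
#' @inheritParams normal_flow
#' @param corner A corner record from [find_joint_fatal_corners()] (or a list
#'   with `location` and `constraint_ids`).
#' @param backward_horizon Maximum backward integration time.
#' @return A `Manifold` with `kind = "ordering"` and `labels_either_side` the
#'   two constraint ids. Flagged `degenerate` if the backward trajectory exits
#'   the region immediately.
#' @export
ordering_manifold <- function(field, region, corner, backward_horizon = 100) {
  loc <- as.numeric(corner$location)
  ids <- corner$constraint_ids
  if (length(ids) != 2) stop("corner must carry exactly two constraint ids")
  on_facets <- vapply(ids, function(id) {
    abs(constraint_value(get_constraint(region, id), loc)) <= 1e-8
  }, logical(1))
  if (!all(on_facets)) {
    stop_viadeco("corner state does not lie on both constraint facets",
                 "not_joint_fatal")
  }
  f <- eval_field(field, loc)
  flows <- vapply(ids, function(id) {
    con <- get_constraint(region, id)
    sum(f * constraint_normal(con, loc, region$dimension))
  }, numeric(1))
  if (!all(flows > 0)) {
    stop_viadeco("corner is not joint-fatal (outward flow not strictly positive for both constraints)",
                 "not_joint_fatal")
  }
  inward <- -Reduce(`+`, lapply(ids, function(id) {
    constraint_normal(get_constraint(region, id), loc, region$dimension)
  }))
  inward <- inward / sqrt(sum(inward^2))
  bp <- backward_polyline(field, region, loc, inward, backward_horizon)
  new_manifold("ordering", seed = loc, points = bp$points, times = bp$times,
               labels_either_side = ids, termination = bp$termination,
               degenerate = nrow(bp$points) < 3)
}

#' Verify that a manifold separates outcomes
#'
#' The definitional property of mortality, ordering, and collapse manifolds is
#' that outcomes differ on their two sides. This check samples points along
#' the polyline (arc-length weighted, seeded), places a probe pair at
#' `+/- band` along the local normal of each sampled segment, classifies both
#' probes with the supplied classifier, and counts a pair as consistent when
#' the two descriptors are distinct and together equal `labels_either_side`.
#' Probes outside the region or within `band` of its boundary are skipped.
#'
#' @param manifold A `Manifold`.
#' @param classifier Function from a state to an outcome descriptor
#'   (character); typically built on [classify_state()] or
#'   [simulate_hybrid()].
#' @param n_probes Number of probe pairs to attempt (>= 1).
#' @param band Probe offset along the local normal.
#' @param seed Integer seed for probe placement.
#' @param region Optional `ViabilityRegion` used to skip probes near the
#'   boundary.
#' @return A `SeparationReport`: `fraction` (consistent pairs / evaluated
#'   pairs), `n_evaluated`, `n_skipped`, and `counterexamples` (data frame of
#'   inconsistent probe pairs).
#' @export
verify_separation <- function(manifold, classifier, n_probes = 100,
                              band = 1e-2, seed = 1, region = NULL) {
  stopifnot(inherits(manifold, "Manifold"))
  if (n_probes < 1) stop("n_probes must be >= 1")
  if (band <= 0) stop("band must be positive")
  pts <- manifold$points
  if (nrow(pts) < 2) stop("manifold polyline has fewer than 2 points")
  if (ncol(pts) != 2) stop("probe placement is implemented for 2-D manifolds")
  # drop consecutive duplicate points (zero-length segments)
  dup <- c(FALSE, rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) == 0)
  pts <- pts[!dup, , drop = FALSE]
  if (nrow(pts) < 2) stop("manifold polyline has fewer than 2 distinct points")
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- cumsum(seglen)
  total <- cum[length(cum)]
  u <- with_seed(seed, stats::runif(n_probes, 0, total))
  labels <- manifold$labels_either_side
  n_eval <- 0L
  n_ok <- 0L
  cex <- list()
  for (ui in u) {
    i <- which(cum >= ui)[1]
    t0 <- if (i == 1) 0 else cum[i - 1]
    frac <- (ui - t0) / seglen[i]
    p <- pts[i, ] + frac * (pts[i + 1, ] - pts[i, ])
    tangent <- (pts[i + 1, ] - pts[i, ]) / seglen[i]
    nrm <- c(-tangent[2], tangent[1])
    pa <- p + band * nrm
    pb <- p - band * nrm
    if (!is.null(region)) {
      ok <- function(q) region_contains(region, q) && boundary_distance(region, q) >= band
      if (!ok(pa) || !ok(pb)) next
    }
    da <- classifier(pa)
    db <- classifier(pb)
    n_eval <- n_eval + 1L
    if (!identical(da, db) && setequal(c(da, db), labels)) {
      n_ok <- n_ok + 1L
    } else {
      cex <- c(cex, list(data.frame(
        x1_plus = pa[1], x2_plus = pa[2], label_plus = da,
        x1_minus = pb[1], x2_minus = pb[2], label_minus = db
      )))
    }
  }
  counterexamples <- if (length(cex)) do.call(rbind, cex) else
    data.frame(x1_plus = numeric(0), x2_plus = numeric(0),
               label_plus = character(0), x1_minus = numeric(0),
               x2_minus = numeric(0), label_minus = character(0))
  structure(
    list(fraction = if (n_eval > 0) n_ok / n_eval else NA_real_,
         n_evaluated = n_eval, n_skipped = n_probes - n_eval,
         counterexamples = counterexamples,
         band = band, seed = seed),
    class = "SeparationReport"
  )
}

#' @export
print.SeparationReport <- function(x, ...) {
  cat("<SeparationReport> fraction", fmt_num(x$fraction), "on", x$n_evaluated,
      "probe pairs (", x$n_skipped, "skipped );",
      nrow(x$counterexamples), "counterexamples\n")
  invisible(x)
}
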