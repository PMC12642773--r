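#' Multicellular hybrid dynamical systems
#'
#' A multicellular model is a hybrid dynamical system: continuous dynamics
#' within the intersection of every living cell's viability region, punctuated
#' by instantaneous death events that remove the dying cells' variables and
#' collapse the state space to the survivors' subspace.
#'
#' Dynamics are supplied per alive subset (a registry keyed by the subset of
#' cell names) because post-death dynamics need not be a restriction of the
#' full field. The default collapse rule is coordinate projection: dying
#' cells' variables are dropped and surviving coordinates are preserved
#' exactly. A custom `collapse_rule(x, alive, dying, system)` may instead
#' append debris/environment variables, as long as it preserves the surviving
#' coordinates.
#'
#' @param name Cell name (unique).
#' @param region A [viability_region()] over the cell's own variables.
#' @param n_vars Number of state variables the cell owns.
#' @return `cell_spec()` returns a `CellSpec`.
#' @export
cell_spec <- function(name, region, n_vars = region$dimension) {
  stopifnot(is.character(name), length(name) == 1,
            inherits(region, "ViabilityRegion"), region$dimension == n_vars)
  structure(list(name = name, n_vars = as.integer(n_vars), region = region),
            class = "CellSpec")
}

#' @rdname cell_spec
#' @param cells List of `CellSpec` objects; their order fixes the variable
#'   layout of the full state (cell 1's variables first, and so on).
#' @param dynamics Named list of [vector_field()]s, one per nonempty alive
#'   subset, keyed by [subset_key()] of the subset's cell names. Each field's
#'   dimension must equal the subset's total variable count.
#' @param collapse_rule Optional function `(x, alive, dying, system)`
#'   returning the reduced state; default is coordinate projection.
#' @return `multicell_system()` returns a `MultiCellSystem`.
#' @export
multicell_system <- function(cells, dynamics, collapse_rule = NULL) {
  stopifnot(length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "CellSpec")))
  names_ <- vapply(cells, `[[`, character(1), "name")
  if (anyDuplicated(names_)) stop("cell names must be unique")
  names(cells) <- names_
  sys <- structure(
    list(cells = cells, cell_names = names_, dynamics = dynamics,
         collapse_rule = collapse_rule),
    class = "MultiCellSystem"
  )
  for (s in all_subsets(names_, nonempty = TRUE)) {
    key <- subset_key(s)
    fld <- dynamics[[key]]
    if (is.null(fld)) stop("dynamics missing for alive subset '", key, "'")
    if (!inherits(fld, "VectorField")) stop("dynamics['", key, "'] is not a VectorField")
    if (fld$dimension != sum(vapply(cells[s], `[[`, integer(1), "n_vars"))) {
      stop("dynamics['", key, "'] has wrong dimension")
    }
  }
  sys
}

#' Canonical key for an alive subset
#'
#' Cell names joined by `+` in system order; the empty subset is `"{}"`.
#'
#' @param cell_names Character vector of cell names (any order).
#' @param system Optional `MultiCellSystem` used to impose its cell order.
#' @return A single string.
#' @export
subset_key <- function(cell_names, system = NULL) {
  if (length(cell_names) == 0) return("{}")
  if (!is.null(system)) {
    cell_names <- system$cell_names[system$cell_names %in% cell_names]
  }
  paste(cell_names, collapse = "+")
}

all_subsets <- function(names_, nonempty = FALSE) {
  k <- length(names_)
  out <- list()
  for (m in 0:(2^k - 1)) {
    s <- names_[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    out <- c(out, list(s))
  }
  if (nonempty) out <- Filter(length, out)
  out
}

# Variable indices (in the full state layout) owned by each cell.
cell_var_indices <- function(system) {
  nv <- vapply(system$cells, `[[`, integer(1), "n_vars")
  ends <- cumsum(nv)
  starts <- ends - nv + 1
  stats::setNames(lapply(seq_along(nv), function(i) starts[i]:ends[i]),
                  system$cell_names)
}

# Indices of the alive cells' variables within the *alive-subset* state, and
# the combined viability region over that state.
subset_layout <- function(system, alive) {
  alive <- system$cell_names[system$cell_names %in% alive]
  nv <- vapply(system$cells[alive], `[[`, integer(1), "n_vars")
  ends <- cumsum(nv)
  starts <- ends - nv + 1
  idx <- stats::setNames(lapply(seq_along(alive), function(i) starts[i]:ends[i]), alive)
  cons <- list()
  for (cn in alive) {
    off <- idx[[cn]][1] - 1L
    for (con in system$cells[[cn]]$region$constraints) {
      shifted <- if (con$type == "box") {
        s <- con; s$index <- con$index + off; s
      } else {
        shift_smooth_constraint(con, idx[[cn]], sum(nv))
      }
      shifted$id <- paste0(cn, ":", con$id)
      cons <- c(cons, list(shifted))
    }
  }
  list(alive = alive, indices = idx,
       region = viability_region(cons, dimension = sum(nv)))
}

# Lift a cell-local smooth constraint into the alive-subset state space.
# Separate function so each lifted constraint gets its own closure environment.
shift_smooth_constraint <- function(con, ii, total_dim) {
  g0 <- con$g
  grad0 <- con$gradient
  s <- con
  s$g <- function(x) g0(x[ii])
  if (!is.null(grad0)) {
    s$gradient <- function(x) {
      out <- rep(0, total_dim)
      out[ii] <- grad0(x[ii])
      out
    }
  }
  s
}

#' Reduced system for an alive subset
#'
#' @param system A [multicell_system()].
#' @param alive Nonempty character vector of alive cell names.
#' @return List with the registered `field` over the survivors' variables and
#'   the combined `region` (product of the survivors' regions, constraint ids
#'   prefixed `cell:`).
#' @export
reduced_system <- function(system, alive) {
  stopifnot(inherits(system, "MultiCellSystem"))
  if (length(alive) == 0) stop("alive subset must be nonempty")
  lay <- subset_layout(system, alive)
  key <- subset_key(lay$alive)
  list(field = system$dynamics[[key]], region = lay$region, alive = lay$alive)
}

#' Collapse a state across a death event
#'
#' @param x State over the `alive` subset's variables.
#' @param alive Character vector of currently alive cells (system order).
#' @param dying Nonempty subset of `alive` that dies.
#' @param system The `MultiCellSystem` (for the variable layout).
#' @param collapse_rule Optional override of the system's rule.
#' @return The reduced state; under the default projection the survivors'
#'   coordinates are bit-identical.
#' @export
collapse_state <- function(x, alive, dying, system, collapse_rule = NULL) {
  if (length(dying) == 0 || !all(dying %in% alive)) {
    stop_viadeco("dying cells must be a nonempty subset of the alive set",
                 "invalid_dying_subset")
  }
  rule <- collapse_rule %||% system$collapse_rule
  if (!is.null(rule)) return(rule(x, alive, dying, system))
  lay <- subset_layout(system, alive)
  keep <- unlist(lay$indices[setdiff(lay$alive, dying)], use.names = FALSE)
  x[keep]
}

#' Directed configuration graph of a multicellular system
#'
#' Nodes are alive-cell subsets (including the empty set); every pair
#' (source, nonempty dying subset of the source) contributes one edge to
#' `source minus dying`. For `k` cells there are `2^k` nodes and `3^k - 2^k`
#' edges. `realized` flags start `FALSE` and are set by simulation batches.
#'
#' @param system A [multicell_system()].
#' @return A `ConfigurationGraph`: list with `nodes` (character keys) and
#'   `edges` (data frame: `source`, `dying`, `target`, `realized`).
#' @export
configuration_graph <- function(system) {
  stopifnot(inherits(system, "MultiCellSystem"))
  names_ <- system$cell_names
  subsets <- all_subsets(names_)
  nodes <- vapply(subsets, subset_key, character(1))
  src <- character(0); dy <- character(0); tgt <- character(0)
  for (s in subsets) {
    if (length(s) == 0) next
    for (d in all_subsets(s, nonempty = TRUE)) {
      src <- c(src, subset_key(s))
      dy <- c(dy, subset_key(d))
      tgt <- c(tgt, subset_key(setdiff(s, d)))
    }
  }
  structure(
    list(nodes = nodes,
         edges = data.frame(source = src, dying = dy, target = tgt,
                            realized = FALSE, stringsAsFactors = FALSE)),
    class = "ConfigurationGraph"
  )
}

#' @export
print.ConfigurationGraph <- function(x, ...) {
  cat("<ConfigurationGraph>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$realized), "realized )\n")
  invisible(x)
}

#' Mark edges realized by simulations
#'
#' @param graph A `ConfigurationGraph`.
#' @param trajectories List of `HybridTrajectory` objects (or a single one).
#' @return The graph with `realized` flags updated.
#' @export
mark_realized <- function(graph, trajectories) {
  if (inherits(trajectories, "HybridTrajectory")) trajectories <- list(trajectories)
  for (ht in trajectories) {
    for (ev in ht$events) {
      hit <- graph$edges$source == ev$source_key & graph$edges$dying == ev$dying_key
      graph$edges$realized[hit] <- TRUE
    }
  }
  graph
}

#' Simulate a multicellular death cascade
#'
#' Integrates the current alive subset's field with stopping events on the
#' union of the alive cells' constraints; at each event every cell whose
#' constraint crosses within `tie_tol` of the first crossing dies
#' simultaneously, the collapse rule is applied, and integration continues in
#' the survivors' subspace until the empty subset or the horizon. Cells
#' already outside their region at t = 0 die in an immediate event (not an
#' error), so batch sweeps over initial conditions are total.
#'
#' @param system A [multicell_system()].
#' @param x0 Full-system initial state.
#' @param horizon Positive simulation horizon.
#' @param tie_tol Simultaneity window for joint deaths.
#' @param rtol,atol Solver tolerances.
#' @return A `HybridTrajectory`: `segments` (list of
#'   `list(alive, trajectory, t_offset)`), `events` (list of `DeathEvent`s:
#'   `time`, `dying`, `pre_state`, `post_state`, `source_key`, `dying_key`),
#'   `final_alive`, `final_state`.
#' @export
simulate_hybrid <- function(system, x0, horizon = 50, tie_tol = 1e-9,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "MultiCellSystem"))
  if (horizon <= 0) stop("horizon must be positive")
  alive <- system$cell_names
  x <- as.numeric(x0)
  t_now <- 0
  segments <- list()
  events <- list()

  repeat {
    if (length(alive) == 0 || t_now >= horizon) break
    lay <- subset_layout(system, alive)
    # immediate deaths: cells outside their region at the current state
    dead_now <- Filter(function(cn) {
      !region_contains(system$cells[[cn]]$region, x[lay$indices[[cn]]])
    }, alive)
    if (length(dead_now) > 0) {
      post <- collapse_state(x, alive, dead_now, system)
      events <- c(events, list(death_event(t_now, dead_now, x, post, alive)))
      alive <- setdiff(alive, dead_now)
      x <- post
      next
    }
    field <- system$dynamics[[subset_key(alive)]]
    traj <- integrate_field(field, x, duration = horizon - t_now,
                            direction = "forward", events = lay$region,
                            rtol = rtol, atol = atol)
    segments <- c(segments, list(list(alive = alive, trajectory = traj,
                                      t_offset = t_now)))
    if (traj$termination$type != "event") {
      x <- trajectory_end(traj)
      t_now <- horizon
      break
    }
    xe <- trajectory_end(traj)
    t_ev <- t_now + traj$termination$time
    ids <- union(traj$termination$constraint_ids,
                 tied_constraints(field, lay$region, xe, tie_tol))
    dying <- unique(vapply(strsplit(ids, ":", fixed = TRUE), `[[`,
                           character(1), 1))
    post <- collapse_state(xe, alive, dying, system)
    events <- c(events, list(death_event(t_ev, dying, xe, post, alive)))
    alive <- setdiff(alive, dying)
    x <- post
    t_now <- t_ev
  }

  structure(
    list(segments = segments, events = events,
         final_alive = alive, final_state = x, horizon = horizon),
    class = "HybridTrajectory"
  )
}

death_event <- function(time, dying, pre_state, post_state, alive) {
  structure(
    list(time = time, dying = dying, pre_state = pre_state,
         post_state = post_state, source_key = subset_key(alive),
         dying_key = subset_key(dying)),
    class = "DeathEvent"
  )
}

#' @export
print.HybridTrajectory <- function(x, ...) {
  cat("<HybridTrajectory>", length(x$segments), "segments,",
      length(x$events), "death events | final alive: {",
      subset_key(x$final_alive), "}\n")
  for (ev in x$events) {
    cat("  t =", fmt_num(ev$time), ": dies {", ev$dying_key, "}\n")
  }
  invisible(x)
}

#' Pre-images of reduced-system organizing structures on a death facet
#'
#' When `dying_cell` dies, the state collapses onto the survivors' subspace.
#' Under the default projection, the set of pre-death boundary states that
#' collapse onto a given target of the reduced system is the slice of the
#' dying cell's death facet with surviving coordinates equal to the target.
#' One point is returned per finite constraint of the dying cell. If the
#' target is an equilibrium of the reduced field its stability is checked: a
#' stable target is valid but non-organizing (`organizing = FALSE`); an
#' unstable/saddle equilibrium is an organizing structure.
#'
#' @param system A [multicell_system()].
#' @param source Alive subset in which the death occurs.
#' @param dying_cell Name of the cell that dies (single cell).
#' @param target State of the reduced system (survivors' coordinates).
#' @return List of collapse points: `location` (source-subset state),
#'   `constraint_id`, `organizing` flag.
#' @export
find_collapse_points <- function(system, source, dying_cell, target) {
  stopifnot(inherits(system, "MultiCellSystem"), dying_cell %in% source)
  survivors <- setdiff(system$cell_names[system$cell_names %in% source], dying_cell)
  if (length(survivors) == 0) stop("no survivors: nothing to organize")
  red <- reduced_system(system, survivors)
  target <- as.numeric(target)
  if (!region_contains(red$region, target)) {
    stop_viadeco("target lies outside the reduced system's viability region",
                 "target_outside_region")
  }
  organizing <- NA
  resid <- sqrt(sum(eval_field(red$field, target)^2))
  if (resid <= 1e-8) {
    eq <- stability(red$field, target)
    organizing <- eq$stability %in% c("unstable", "saddle")
  }
  lay <- subset_layout(system, source)
  out <- list()
  for (con in system$cells[[dying_cell]]$region$constraints) {
    if (con$type != "box" || !is.finite(con$threshold)) next
    x <- numeric(lay$region$dimension)
    keep <- unlist(lay$indices[survivors], use.names = FALSE)
    x[keep] <- target
    xi <- lay$indices[[dying_cell]]
    x[xi] <- NA_real_
    x[xi[con$index]] <- con$threshold
    if (anyNA(x)) next # multi-variable dying cell: facet is not a point slice
    out <- c(out, list(list(location = x,
                            constraint_id = paste0(dying_cell, ":", con$id),
                            organizing = organizing)))
  }
  out
}

#' Collapse manifold of a reduced-system organizing structure
#'
#' Backward-time trajectory of the source subset's field from a collapse
#' point (a death-facet state whose post-collapse image is an organizing
#' structure of the reduced system). It separates pre-death states by the
#' post-collapse fate of the survivors.
#'
#' @param system A [multicell_system()].
#' @param source Alive subset (must have a 2-D joint state space).
#' @param point A collapse point from [find_collapse_points()].
#' @param backward_horizon Maximum backward integration time.
#' @param labels_either_side Two outcome descriptors for the post-collapse
#'   fates; defaults to `"<survivor>_survives"` / `"<survivor>_dies"`.
#' @return A `Manifold` with `kind = "collapse"`.
#' @export
collapse_manifold <- function(system, source, point, backward_horizon = 100,
                              labels_either_side = NULL) {
  stopifnot(inherits(system, "MultiCellSystem"))
  lay <- subset_layout(system, source)
  if (lay$region$dimension != 2) {
    stop("collapse manifolds are computed in 2-D source subspaces only")
  }
  loc <- as.numeric(point$location)
  if (isFALSE(point$organizing)) {
    warning("collapse point targets a non-organizing (stable) structure; manifold flagged")
  }
  field <- system$dynamics[[subset_key(lay$alive)]]
  con <- get_constraint(lay$region, point$constraint_id)
  inward <- -constraint_normal(con, loc, 2)
  if (is.null(labels_either_side)) {
    dying_cell <- strsplit(point$constraint_id, ":", fixed = TRUE)[[1]][1]
    survivor <- setdiff(lay$alive, dying_cell)[1]
    labels_either_side <- paste0(survivor, c("_survives", "_dies"))
  }
  bp <- backward_polyline(field, lay$region, loc, inward, backward_horizon)
  flags <- if (isFALSE(point$organizing)) "non_organizing_target" else character(0)
  new_manifold("collapse", seed = loc, points = bp$points, times = bp$times,
               labels_either_side = labels_either_side,
               termination = bp$termination,
               degenerate = nrow(bp$points) < 3, flags = flags)
}
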