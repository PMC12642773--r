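#' Bounded Game-of-Life grids
#'
#' A `Grid` is a bounded binary lattice with an origin offset into an
#' unbounded quiescent (all-off) plane. Rows grow downward, columns grow
#' rightward; a live cell is addressed by its global `(row, col)`. The window
#' auto-grows (by 8 cells per side, capped at `max_size`) whenever live cells
#' approach its edge, so patterns never wrap or fall off.
#'
#' @param cells Two-column matrix of global `(row, col)` coordinates of live
#'   cells (may have zero rows).
#' @param margin Initial empty margin around the live cells.
#' @return A `Grid`.
#' @export
gol_grid <- function(cells = matrix(integer(0), ncol = 2), margin = 4) {
  cells <- normalize_cells(cells)
  if (nrow(cells) == 0) {
    mat <- matrix(0L, 2 * margin + 1, 2 * margin + 1)
    return(structure(list(mat = mat, origin = c(1L - margin, 1L - margin)),
                     class = "Grid"))
  }
  r0 <- min(cells[, 1]) - margin
  c0 <- min(cells[, 2]) - margin
  nr <- max(cells[, 1]) - r0 + 1 + margin
  nc <- max(cells[, 2]) - c0 + 1 + margin
  mat <- matrix(0L, nr, nc)
  mat[cbind(cells[, 1] - r0 + 1, cells[, 2] - c0 + 1)] <- 1L
  structure(list(mat = mat, origin = c(as.integer(r0), as.integer(c0))),
            class = "Grid")
}

normalize_cells <- function(cells) {
  if (is.null(cells) || length(cells) == 0) return(matrix(integer(0), ncol = 2))
  cells <- matrix(as.integer(cells), ncol = 2)
  unique(cells[order(cells[, 1], cells[, 2]), , drop = FALSE])
}

#' Live cells of a grid
#'
#' @param grid A `Grid`.
#' @return Two-column integer matrix of global `(row, col)` coordinates,
#'   sorted.
#' @export
live_cells <- function(grid) {
  idx <- which(grid$mat == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), ncol = 2))
  cells <- cbind(idx[, 1] + grid$origin[1] - 1L, idx[, 2] + grid$origin[2] - 1L)
  normalize_cells(cells)
}

#' @export
print.Grid <- function(x, ...) {
  lc <- live_cells(x)
  cat("<Grid>", nrow(x$mat), "x", ncol(x$mat), "window,", nrow(lc),
      "live cells\n")
  invisible(x)
}

grow_grid <- function(grid, pad = 8L, max_size = 512L) {
  nr <- nrow(grid$mat); nc <- ncol(grid$mat)
  if (nr + 2L * pad > max_size || nc + 2L * pad > max_size) {
    stop_viadeco("grid window exceeded the maximum size", "window_overflow")
  }
  mat <- matrix(0L, nr + 2L * pad, nc + 2L * pad)
  mat[(pad + 1L):(pad + nr), (pad + 1L):(pad + nc)] <- grid$mat
  structure(list(mat = mat, origin = grid$origin - pad), class = "Grid")
}

needs_growth <- function(grid) {
  m <- grid$mat
  nr <- nrow(m); nc <- ncol(m)
  any(m[1:2, ] == 1L) || any(m[(nr - 1):nr, ] == 1L) ||
    any(m[, 1:2] == 1L) || any(m[, (nc - 1):nc] == 1L)
}

#' One synchronous Game-of-Life step
#'
#' Standard rules: a dead cell with exactly 3 live Moore neighbours is born; a
#' live cell with 2 or 3 live neighbours survives; all other cells are off.
#'
#' @param grid A `Grid`.
#' @param auto_grow Grow the window when live cells approach its edge
#'   (default); with `auto_grow = FALSE` that situation is a
#'   `window_overflow` error.
#' @param max_size Maximum window side length.
#' @return The updated `Grid`.
#' @export
gol_step <- function(grid, auto_grow = TRUE, max_size = 512L) {
  stopifnot(inherits(grid, "Grid"))
  if (needs_growth(grid)) {
    if (!auto_grow) stop_viadeco("live cell at window edge", "window_overflow")
    grid <- grow_grid(grid, max_size = max_size)
  }
  m <- grid$mat
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  n <- p[1:nr, 1:nc]         + p[1:nr, 2:(nc + 1)]         + p[1:nr, 3:(nc + 2)] +
       p[2:(nr + 1), 1:nc]                                 + p[2:(nr + 1), 3:(nc + 2)] +
       p[3:(nr + 2), 1:nc]   + p[3:(nr + 2), 2:(nc + 1)]   + p[3:(nr + 2), 3:(nc + 2)]
  grid$mat <- matrix(as.integer(n == 3L | (m == 1L & n == 2L)), nr, nc)
  grid
}

#' Run several Game-of-Life steps
#'
#' @inheritParams gol_step
#' @param n Number of steps.
#' @return The updated `Grid`.
#' @export
gol_run <- function(grid, n, auto_grow = TRUE, max_size = 512L) {
  for (i in seq_len(n)) grid <- gol_step(grid, auto_grow, max_size)
  grid
}

expand_moore <- function(rc) {
  d <- expand.grid(dr = -1:1, dc = -1:1)
  cbind(rc[1] + d$dr, rc[2] + d$dc)
}

# The four phases of the standard glider (single chirality, heading
# down-right: one (1,1) translation per 4 steps). Offsets are (row, col)
# relative to the phase's bounding-box corner; `shift` is the corner
# translation produced by stepping that phase. Frozen from an independent
# reference simulation.
GLIDER_PHASES <- local({
  p <- list(
    rbind(c(0, 1), c(1, 2), c(2, 0), c(2, 1), c(2, 2)),
    rbind(c(0, 0), c(0, 2), c(1, 1), c(1, 2), c(2, 1)),
    rbind(c(0, 2), c(1, 0), c(1, 2), c(2, 1), c(2, 2)),
    rbind(c(0, 0), c(1, 1), c(1, 2), c(2, 0), c(2, 1))
  )
  shifts <- rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 0))
  lapply(1:4, function(k) {
    cells <- normalize_cells(p[[k]])
    # one-cell-thick off membrane: Moore neighbourhood closure minus on-cells
    nb <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      expand_moore(cells[i, ])
    }))
    nb <- normalize_cells(nb)
    membrane <- nb[!paste(nb[, 1], nb[, 2]) %in% paste(cells[, 1], cells[, 2]), ,
                   drop = FALSE]
    list(phase = k - 1L, cells = cells, membrane = membrane,
         shift = shifts[k, ])
  })
})

#' Canonical glider phases
#'
#' The four phase patterns of the standard glider in one chirality/heading
#' (down-right), each with its one-cell-thick off-cell membrane — the layer of
#' off cells around the pattern that functions as the individual's physical
#' boundary. Stepping phase `k` yields phase `(k+1) mod 4` at the recorded
#' corner shift; four steps translate the glider by `(1, 1)`.
#'
#' @return List of 4 phases: `phase` (0-3), `cells` (5x2 offsets), `membrane`
#'   (off-cell offsets), `shift` (corner translation of one step).
#' @export
glider_phases <- function() GLIDER_PHASES

#' Match a glider in a grid
#'
#' Exact mode: the grid's live set equals one phase pattern at some
#' translation. Windowed mode: some translation of a phase has all its
#' on-cells live and its whole membrane off; other live cells are permitted
#' outside the pattern and membrane (the glider is identified as an individual
#' within a larger scene).
#'
#' @param grid A `Grid`.
#' @param mode `"exact"` or `"windowed"`.
#' @return `NULL` when no phase matches, else list with `phase` (0-3) and
#'   `offset` (global `(row, col)` of the pattern's bounding-box corner).
#' @export
match_glider <- function(grid, mode = c("exact", "windowed")) {
  mode <- match.arg(mode)
  live <- live_cells(grid)
  if (nrow(live) == 0) return(NULL)
  live_key <- paste(live[, 1], live[, 2])
  for (ph in GLIDER_PHASES) {
    if (mode == "exact") {
      if (nrow(live) != nrow(ph$cells)) next
      off <- c(min(live[, 1]), min(live[, 2]))
      cand <- sweep(ph$cells, 2, off, "+")
      if (setequal(paste(cand[, 1], cand[, 2]), live_key)) {
        return(list(phase = ph$phase, offset = off))
      }
    } else {
      # anchor the phase's first cell on each live cell in turn
      anchors <- sweep(live, 2, ph$cells[1, ], "-")
      anchors <- unique(anchors)
      for (i in seq_len(nrow(anchors))) {
        off <- anchors[i, ]
        cand <- sweep(ph$cells, 2, off, "+")
        if (!all(paste(cand[, 1], cand[, 2]) %in% live_key)) next
        memb <- sweep(ph$membrane, 2, off, "+")
        if (any(paste(memb[, 1], memb[, 2]) %in% live_key)) next
        return(list(phase = ph$phase, offset = as.integer(off)))
      }
    }
  }
  NULL
}

#' Glider-environment configurations
#'
#' A `CAConfiguration` is a glider (phase + position) plus a set of extra
#' on-cells in its environment. Environment cells must be disjoint from the
#' glider's on-cells and from its off-cell membrane.
#'
#' @param phase Glider phase 0-3.
#' @param position Global `(row, col)` of the glider's bounding-box corner.
#' @param environment Two-column matrix of extra on-cells (global
#'   coordinates).
#' @param window Optional perturbation-window specification carried along for
#'   reporting.
#' @return A `CAConfiguration`.
#' @export
ca_configuration <- function(phase, position, environment = NULL, window = NULL) {
  stopifnot(phase %in% 0:3, length(position) == 2)
  ph <- GLIDER_PHASES[[phase + 1L]]
  environment <- normalize_cells(environment)
  g_on <- sweep(ph$cells, 2, position, "+")
  g_mem <- sweep(ph$membrane, 2, position, "+")
  forbidden <- paste(c(g_on[, 1], g_mem[, 1]), c(g_on[, 2], g_mem[, 2]))
  if (any(paste(environment[, 1], environment[, 2]) %in% forbidden)) {
    stop("environment cells overlap the glider or its membrane")
  }
  structure(
    list(phase = as.integer(phase), position = as.integer(position),
         environment = environment, window = window),
    class = "CAConfiguration"
  )
}

#' @export
print.CAConfiguration <- function(x, ...) {
  cat("<CAConfiguration> glider phase", x$phase, "at (",
      paste(x$position, collapse = ", "), ") +", nrow(x$environment),
      "environment cells\n")
  invisible(x)
}

config_to_grid <- function(config, margin = 6) {
  ph <- GLIDER_PHASES[[config$phase + 1L]]
  cells <- rbind(sweep(ph$cells, 2, config$position, "+"), config$environment)
  gol_grid(cells, margin = margin)
}

#' Enumerate environmental perturbations of a configuration
#'
#' All subsets of the window cells of size at most `max_flips` turned on, as
#' configurations; the count is `sum_{j=0..max_flips} choose(|window|, j)`.
#'
#' @param base A [ca_configuration()].
#' @param window Two-column matrix of candidate cells (global coordinates),
#'   disjoint from the glider's on-cells and membrane.
#' @param max_flips Maximum number of cells turned on (>= 0).
#' @return List of `CAConfiguration`s (the base configuration first).
#' @export
enumerate_perturbations <- function(base, window, max_flips = 1) {
  stopifnot(inherits(base, "CAConfiguration"), max_flips >= 0)
  window <- normalize_cells(window)
  ph <- GLIDER_PHASES[[base$phase + 1L]]
  g_on <- sweep(ph$cells, 2, base$position, "+")
  g_mem <- sweep(ph$membrane, 2, base$position, "+")
  forbidden <- paste(c(g_on[, 1], g_mem[, 1]), c(g_on[, 2], g_mem[, 2]))
  if (any(paste(window[, 1], window[, 2]) %in% forbidden)) {
    stop("window overlaps the glider or its membrane")
  }
  w <- nrow(window)
  out <- list()
  for (j in 0:min(max_flips, w)) {
    combos <- if (j == 0) list(integer(0)) else utils::combn(w, j, simplify = FALSE)
    for (cmb in combos) {
      env <- rbind(base$environment, window[cmb, , drop = FALSE])
      out <- c(out, list(ca_configuration(base$phase, base$position,
                                          environment = env,
                                          window = window)))
    }
  }
  out
}

#' Classify a glider-environment configuration
#'
#' Intrinsic viability of the glider: the configuration is a `nonmember` if no
#' glider is present at t = 0; otherwise the scene is simulated and the glider
#' identity is checked at every period-4 boundary up to `horizon`. If the
#' identity holds at every check the configuration is in the `interior` of the
#' glider's viability region. If the identity is lost and never regained by
#' the horizon the configuration is on the `boundary` (its transition is
#' terminal) and the first failing step is recorded. Identity lost but
#' regained by the final check counts as interior with `recovered = TRUE`
#' (only permanent loss is terminal).
#'
#' @param config A [ca_configuration()] or a `Grid`.
#' @param horizon Number of steps to simulate (>= 1); checks happen at
#'   multiples of 4.
#' @param mode Matching mode, `"windowed"` (default) or `"exact"`.
#' @param max_size Maximum window side for auto-growth.
#' @return List with `label` (`"interior"`, `"boundary"`, `"nonmember"`),
#'   `steps_to_disintegration` (first failing check, `NA` otherwise),
#'   `recovered`, and the final `match`.
#' @export
classify_configuration <- function(config, horizon = 64, mode = "windowed",
                                   max_size = 512L) {
  stopifnot(horizon >= 1)
  grid <- if (inherits(config, "Grid")) config else config_to_grid(config)
  if (is.null(match_glider(grid, mode))) {
    return(list(label = "nonmember", steps_to_disintegration = NA_integer_,
                recovered = FALSE, match = NULL))
  }
  checks <- seq(4, horizon, by = 4)
  missed <- integer(0)
  last_match <- NULL
  for (s in checks) {
    grid <- gol_run(grid, 4, max_size = max_size)
    m <- match_glider(grid, mode)
    if (is.null(m)) missed <- c(missed, s) else last_match <- m
  }
  if (length(missed) == 0) {
    return(list(label = "interior", steps_to_disintegration = NA_integer_,
                recovered = FALSE, match = last_match))
  }
  final_ok <- !is.null(match_glider(grid, mode))
  if (final_ok) {
    list(label = "interior", steps_to_disintegration = NA_integer_,
         recovered = TRUE, match = last_match)
  } else {
    list(label = "boundary", steps_to_disintegration = missed[1],
         recovered = FALSE, match = NULL)
  }
}

#' Partition configurations by intrinsic viability
#'
#' Maps [classify_configuration()] over a configuration list and tallies the
#' interior / boundary / nonmember counts. The counts always sum to the number
#' of configurations.
#'
#' @param configs Nonempty list of configurations.
#' @inheritParams classify_configuration
#' @return A `PartitionSummary`: `counts` (named integer vector) and `records`
#'   (data frame with one row per configuration: `config` index, `n_env`
#'   environment cells, `label`, `steps_to_disintegration`, `recovered`).
#' @export
viability_partition <- function(configs, horizon = 64, mode = "windowed") {
  stopifnot(length(configs) >= 1)
  recs <- lapply(seq_along(configs), function(i) {
    cl <- classify_configuration(configs[[i]], horizon = horizon, mode = mode)
    env <- if (inherits(configs[[i]], "CAConfiguration"))
      nrow(configs[[i]]$environment) else NA_integer_
    data.frame(config = i, n_env = env, label = cl$label,
               steps_to_disintegration = cl$steps_to_disintegration,
               recovered = cl$recovered, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  counts <- c(interior = sum(records$label == "interior"),
              boundary = sum(records$label == "boundary"),
              nonmember = sum(records$label == "nonmember"))
  structure(list(counts = counts, records = records, horizon = horizon,
                 mode = mode),
            class = "PartitionSummary")
}

#' @export
print.PartitionSummary <- function(x, ...) {
  cat("<PartitionSummary>", sum(x$counts), "configurations | interior:",
      x$counts["interior"], "boundary:", x$counts["boundary"],
      "nonmember:", x$counts["nonmember"], "\n")
  invisible(x)
}
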