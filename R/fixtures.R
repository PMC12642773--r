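#' Single-cell fixture systems
#'
#' Concrete, closed-form-verifiable realizations of the three qualitative
#' single-cell survival regimes, used throughout the test suite and runnable
#' from the CLI:
#'
#' * **A** — linear sink at `(0.5, 0.5)` inside the box `[0,1]^2`: all
#'   boundary flow points inward, the whole region is asymptotically viable.
#' * **B** — linear sink at `(1.5, 0.5)` with the same box: the attractor lies
#'   outside the region, every interior state exits through the `x1` upper
#'   facet in finite time (from `(0.5, 0.5)` at exactly `t = ln 2`).
#' * **C** — linear spiral (eigenvalues `lambda +/- i omega`,
#'   `lambda = -0.1`, `omega = 1`) at the origin in the box
#'   `[-1,1] x [-1, 0.5]`: mixed regime with one flow tangency on the upper
#'   facet at `x1 = -lambda * 0.5 / omega = 0.05`, whose backward trajectory
#'   is a mortality manifold.
#'
#' @param scenario `"A"`, `"B"`, or `"C"`.
#' @param overrides Named list of shallow parameter replacements
#'   (`center`, `lambda`, `omega`, `lower`, `upper`).
#' @return List with `field`, `region`, `attractors` (list with the viable
#'   attractor, where one exists inside the region), and `spec` (name,
#'   parameters, machine-checkable `expected_facts`).
#' @export
make_single_cell_fixture <- function(scenario = c("A", "B", "C"),
                                     overrides = list()) {
  scenario <- match.arg(scenario)
  par <- switch(scenario,
    A = list(center = c(0.5, 0.5), lower = c(0, 0), upper = c(1, 1)),
    B = list(center = c(1.5, 0.5), lower = c(0, 0), upper = c(1, 1)),
    C = list(center = c(0, 0), lambda = -0.1, omega = 1,
             lower = c(-1, -1), upper = c(1, 0.5))
  )
  par[names(overrides)] <- overrides
  if (scenario %in% c("A", "B")) {
    field <- linear_field(-diag(2), center = par$center)
  } else {
    A <- rbind(c(par$lambda, -par$omega), c(par$omega, par$lambda))
    field <- linear_field(A, center = par$center)
  }
  region <- box_region(par$lower, par$upper)
  att <- stability(field, par$center)
  attractors <- if (region_contains(region, par$center)) list(att) else list()
  expected_facts <- switch(scenario,
    A = list(all_boundary_flow_inward = TRUE, grid_status = "asymptotically_viable"),
    B = list(grid_status = "transiently_viable", exit_constraint = "x1_upper",
             death_time_from_center = log(2)),
    C = list(tangency = c(-par$lambda * par$upper[2] / par$omega, par$upper[2]),
             tangency_facet = "x2_upper", grid_status = "mixed")
  )
  list(field = field, region = region, attractors = attractors,
       spec = list(name = paste0("single_cell_", scenario), parameters = par,
                   expected_facts = expected_facts))
}

#' Two-cell fixture system
#'
#' Two coupled cells, blue (`b`) and purple (`p`), each with a single
#' essential variable bounded below (`b_min = 0.1`, `p_min = 0.05`). The joint
#' dynamics are a linear field `xdot = A (x - c)` with symmetric coupling
#' `gamma` and a stable node `c` below both thresholds, so every joint state
#' eventually kills at least one cell and which cell dies first depends on the
#' initial condition (an ordering manifold through the joint-fatal corner
#' `(b_min, p_min)` separates the two orders). The reduced single-cell
#' dynamics are bistable cubics `vdot = -v (v - a)(v - 1)` with unstable point
#' `a = 0.4`: a viable attractor at 1 and a terminal attractor at 0 below the
#' lower bound, so a survivor's fate is decided by which side of `a` it holds
#' at the moment its partner dies. The pre-image of blue's unstable point on
#' purple's death facet is the collapse point `(a, p_min)`.
#'
#' @param overrides Named list of shallow parameter replacements (`b_min`,
#'   `p_min`, `a`, `gamma`, `c_joint`, `decay`).
#' @return List with `system` (a [multicell_system()]) and `spec` (parameters
#'   and expected facts: corner and collapse-point locations).
#' @export
make_two_cell_fixture <- function(overrides = list()) {
  par <- list(b_min = 0.1, p_min = 0.05, a = 0.4, gamma = 0.2,
              c_joint = c(-0.1, -0.1), decay = 1)
  par[names(overrides)] <- overrides
  A <- rbind(c(-par$decay, -par$gamma), c(-par$gamma, -par$decay))
  joint <- linear_field(A, center = par$c_joint, names = c("b", "p"))
  bistable <- function(a) {
    force(a)
    vector_field(function(x) -x * (x - a) * (x - 1), dimension = 1,
                 jacobian = function(x) {
                   matrix(-((x - a) * (x - 1) + x * (x - 1) + x * (x - a)), 1, 1)
                 })
  }
  blue <- cell_spec("blue", viability_region(
    list(box_constraint(1, "lower", par$b_min, id = "b_lower")), dimension = 1))
  purple <- cell_spec("purple", viability_region(
    list(box_constraint(1, "lower", par$p_min, id = "p_lower")), dimension = 1))
  system <- multicell_system(
    cells = list(blue, purple),
    dynamics = list("blue+purple" = joint,
                    "blue" = bistable(par$a),
                    "purple" = bistable(par$a))
  )
  list(system = system,
       spec = list(name = "two_cell", parameters = par,
                   expected_facts = list(
                     joint_fatal_corner = c(par$b_min, par$p_min),
                     collapse_point = c(par$a, par$p_min),
                     blue_equilibria = c(0, par$a, 1),
                     blue_stabilities = c("stable_node", "unstable", "stable_node"))))
}

#' Game-of-Life fixtures
#'
#' @param name `"glider"` (phase 0 at `(10, 10)`), `"block"`, `"blinker"`
#'   (horizontal), or `"glider_vs_block"` (glider with a block placed on its
#'   diagonal path).
#' @return A `Grid` for `block`/`blinker`, a `CAConfiguration` for the glider
#'   fixtures.
#' @export
make_gol_fixture <- function(name = c("glider", "block", "blinker",
                                      "glider_vs_block")) {
  name <- match.arg(name)
  switch(name,
    glider = ca_configuration(0, c(10, 10)),
    block = gol_grid(rbind(c(10, 10), c(10, 11), c(11, 10), c(11, 11))),
    blinker = gol_grid(rbind(c(10, 9), c(10, 10), c(10, 11))),
    glider_vs_block = ca_configuration(
      0, c(10, 10),
      environment = rbind(c(18, 18), c(18, 19), c(19, 18), c(19, 19)))
  )
}

#' Check a fixture's expected facts with the package's own operations
#'
#' Self-consistency gate: every machine-checkable fact recorded in a fixture's
#' spec is re-derived with the package operations at default tolerances.
#'
#' @param fixture A fixture from [make_single_cell_fixture()] or
#'   [make_two_cell_fixture()].
#' @return Named logical vector, one entry per checked fact.
#' @export
check_fixture_facts <- function(fixture) {
  facts <- fixture$spec$expected_facts
  out <- logical(0)
  if (!is.null(fixture$field)) {
    field <- fixture$field; region <- fixture$region
    if (isTRUE(facts$all_boundary_flow_inward)) {
      hull <- box_hull(region)
      inward <- vapply(region$ids, function(id) {
        con <- get_constraint(region, id)
        free <- if (con$index == 1) 2 else 1
        ss <- seq(hull$lower[free], hull$upper[free], length.out = 100)
        all(vapply(ss, function(s) {
          x <- numeric(2); x[con$index] <- con$threshold; x[free] <- s
          normal_flow(field, region, id, x) < 0
        }, logical(1)))
      }, logical(1))
      out["all_boundary_flow_inward"] <- all(inward)
    }
    if (!is.null(facts$tangency)) {
      tps <- find_tangency_points(field, region, facts$tangency_facet,
                                  attractors = fixture$attractors)
      out["tangency"] <- length(tps) >= 1 &&
        sqrt(sum((tps[[1]]$location - facts$tangency)^2)) < 1e-6
    }
    if (!is.null(facts$death_time_from_center)) {
      lab <- classify_state(field, region, c(0.5, 0.5),
                            attractors = fixture$attractors)
      out["death_time_from_center"] <-
        identical(lab$status, "transiently_viable") &&
        abs(lab$death_time - facts$death_time_from_center) < 1e-4 &&
        identical(lab$violated, facts$exit_constraint %||% lab$violated)
    }
  }
  if (!is.null(fixture$system)) {
    sys <- fixture$system
    if (!is.null(facts$joint_fatal_corner)) {
      full <- reduced_system(sys, sys$cell_names)
      cj <- find_joint_fatal_corners(full$field, full$region)
      out["joint_fatal_corner"] <- length(cj$corners) == 1 &&
        isTRUE(all.equal(cj$corners[[1]]$location, facts$joint_fatal_corner))
    }
    if (!is.null(facts$blue_equilibria)) {
      red <- reduced_system(sys, "blue")
      eqs <- find_equilibria(red$field,
                             list(lower = -0.5, upper = 1.5),
                             n_starts = 24, seed = 7)
      locs <- sort(vapply(eqs, function(e) e$location, numeric(1)))
      labs <- vapply(eqs, `[[`, character(1), "stability")
      labs <- labs[order(vapply(eqs, function(e) e$location, numeric(1)))]
      out["blue_equilibria"] <- length(locs) == 3 &&
        max(abs(locs - facts$blue_equilibria)) < 1e-6 &&
        identical(labs, facts$blue_stabilities)
    }
    if (!is.null(facts$collapse_point)) {
      cps <- find_collapse_points(sys, sys$cell_names, "purple",
                                  target = facts$collapse_point[1])
      out["collapse_point"] <- length(cps) == 1 &&
        isTRUE(all.equal(cps[[1]]$location, facts$collapse_point))
    }
  }
  out
}
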