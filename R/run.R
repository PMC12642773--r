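#' Load a dynamical system from a plain-text configuration file
#'
#' Systems are described in YAML. A linear system gives its coefficient
#' matrix and center:
#'
#' ```yaml
#' field:
#'   type: linear
#'   A: [[-1, 0], [0, -1]]
#'   center: [0.5, 0.5]
#' region:
#'   lower: [0, 0]
#'   upper: [1, 1]
#' ```
#'
#' A polynomial system lists monomial terms per equation; each term is
#' `coef` times the product of `vars` (1-based variable indices, repeated for
#' powers):
#'
#' ```yaml
#' field:
#'   type: polynomial
#'   dimension: 1
#'   equations:
#'     - terms: [{coef: -1, vars: [1, 1, 1]}, {coef: 1.4, vars: [1, 1]}]
#' ```
#'
#' @param path YAML file path.
#' @return List with `field` and (when the file defines one) `region`.
#' @export
load_system_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$field$type)) stop("config error: field.type is required")
  field <- switch(cfg$field$type,
    linear = {
      A <- do.call(rbind, lapply(cfg$field$A, as.numeric))
      centre <- as.numeric(cfg$field$center %||% rep(0, nrow(A)))
      linear_field(A, center = centre)
    },
    polynomial = {
      n <- cfg$field$dimension
      eqs <- cfg$field$equations
      if (length(eqs) != n) stop("config error: equations must match dimension")
      terms <- lapply(eqs, `[[`, "terms")
      vector_field(function(x) {
        vapply(terms, function(tt) {
          sum(vapply(tt, function(term) {
            term$coef * prod(x[as.integer(unlist(term$vars %||% integer(0)))])
          }, numeric(1)))
        }, numeric(1))
      }, dimension = n)
    },
    stop("config error: unknown field.type '", cfg$field$type, "'")
  )
  region <- NULL
  if (!is.null(cfg$region)) {
    region <- box_region(as.numeric(cfg$region$lower),
                         as.numeric(cfg$region$upper),
                         names = cfg$region$names)
  }
  list(field = field, region = region)
}

#' Serialize a fixture's system to the CLI configuration format
#'
#' @param fixture A single-cell fixture from [make_single_cell_fixture()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_system_config <- function(fixture, path) {
  A <- field_jacobian(fixture$field, rep(0, fixture$field$dimension))
  centre <- fixture$spec$parameters$center
  hull <- box_hull(fixture$region)
  cfg <- list(
    field = list(type = "linear",
                 A = lapply(seq_len(nrow(A)), function(i) as.numeric(A[i, ])),
                 center = as.numeric(centre)),
    region = list(lower = as.numeric(hull$lower),
                  upper = as.numeric(hull$upper))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

resolve_system <- function(system) {
  if (system %in% c("A", "B", "C")) {
    make_single_cell_fixture(system)
  } else if (file.exists(system)) {
    fx <- load_system_config(system)
    if (is.null(fx$region)) stop("config error: region is required")
    eqs <- find_equilibria(fx$field, box_hull(fx$region), n_starts = 32, seed = 1)
    fx$attractors <- Filter(function(e) {
      startsWith(e$stability, "stable") && region_contains(fx$region, e$location)
    }, eqs)
    fx$spec <- list(name = system, parameters = list())
    fx
  } else {
    stop("config error: unknown system '", system,
         "' (expected fixture A/B/C or a config file path)")
  }
}

#' Run a named analysis and write its artifacts
#'
#' The programmatic core of the command-line interface. `config` is a list
#' with:
#'
#' * `operation` — `"classify"`, `"decompose"`, `"hybrid"`, or `"gol"`.
#' * `system` — fixture name (`"A"`, `"B"`, `"C"` for classify/decompose;
#'   hybrid always uses the two-cell fixture; gol uses the glider fixture) or
#'   a YAML config path.
#' * `out` — output directory (created if missing).
#' * `seed` — integer; all probe sampling randomness flows from it.
#' * optional numeric settings: `resolution`, `horizon`, `n_probes`, `band`,
#'   `backward_horizon`, `x0`, `window`, `flips`.
#'
#' Every run writes a `manifest.json` listing the produced files with the
#' parameters that produced them; seeds and tolerances are echoed there.
#'
#' @param config Named list as above.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_viadeco <- function(config) {
  op <- config$operation %||% stop("config error: operation is required")
  out_dir <- config$out %||% stop("config error: out is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  files <- character(0)

  if (op == "classify") {
    fx <- resolve_system(config$system %||% "A")
    grid <- classify_grid(fx$field, fx$region,
                          resolution = config$resolution %||% 20,
                          horizon = config$horizon %||% 50,
                          attractors = fx$attractors)
    f1 <- file.path(out_dir, "labels.csv")
    export_labels_csv(grid, f1)
    f2 <- file.path(out_dir, "summary.json")
    jsonlite::write_json(as.list(grid$summary), f2, auto_unbox = TRUE)
    files <- c(f1, f2)
  } else if (op == "decompose") {
    fx <- resolve_system(config$system %||% "C")
    tps <- list()
    for (id in fx$region$ids) {
      tps <- c(tps, find_tangency_points(fx$field, fx$region, id,
                                         attractors = fx$attractors))
    }
    f1 <- file.path(out_dir, "tangencies.json")
    jsonlite::write_json(lapply(tps, function(tp) list(
      location = tp$location, constraint = tp$constraint_id,
      crossing_character = tp$crossing_character,
      forward_fate = tp$forward_fate$status, organizing = tp$organizing
    )), f1, auto_unbox = TRUE, digits = 12, pretty = TRUE)
    files <- f1
    k <- 0
    for (tp in tps) {
      if (!tp$organizing) next
      k <- k + 1
      mf <- mortality_manifold(fx$field, fx$region, tp,
                               backward_horizon = config$backward_horizon %||% 100)
      fm <- file.path(out_dir, sprintf("mortality_manifold_%d.csv", k))
      export_manifold_csv(mf, fm)
      classifier <- function(x) classify_state(
        fx$field, fx$region, x, horizon = config$horizon %||% 200,
        attractors = fx$attractors)$status
      rep_ <- verify_separation(mf, classifier,
                                n_probes = config$n_probes %||% 100,
                                band = config$band %||% 1e-2,
                                seed = seed, region = fx$region)
      fs <- file.path(out_dir, sprintf("separation_%d.json", k))
      export_separation_json(rep_, fs)
      files <- c(files, fm, fs)
    }
  } else if (op == "hybrid") {
    fx <- make_two_cell_fixture()
    sys <- fx$system
    x0 <- as.numeric(config$x0 %||% c(0.9, 0.2))
    ht <- simulate_hybrid(sys, x0, horizon = config$horizon %||% 50)
    files <- export_hybrid(ht, file.path(out_dir, "hybrid"))
    graph <- mark_realized(configuration_graph(sys), ht)
    fg <- file.path(out_dir, "configuration_graph.dot")
    export_graph_dot(graph, fg)
    files <- c(files, fg)
  } else if (op == "gol") {
    base <- make_gol_fixture("glider")
    # default: 3x3 window ahead of the glider's heading, flush with its membrane
    wspec <- config$window %||% list(rows = 3, cols = 3, offset = c(1, 4))
    wr <- wspec$offset[1] + base$position[1] + seq_len(wspec$rows) - 1L
    wc <- wspec$offset[2] + base$position[2] + seq_len(wspec$cols) - 1L
    window <- as.matrix(expand.grid(wr, wc))
    configs <- enumerate_perturbations(base, window,
                                       max_flips = config$flips %||% 1)
    part <- viability_partition(configs, horizon = config$horizon %||% 64)
    f1 <- file.path(out_dir, "partition.csv")
    export_partition_csv(part, f1)
    f2 <- file.path(out_dir, "partition_summary.json")
    jsonlite::write_json(c(as.list(part$counts),
                           list(window = dim(window)[1],
                                horizon = part$horizon)),
                         f2, auto_unbox = TRUE)
    files <- c(f1, f2)
  } else {
    stop("config error: unknown operation '", op, "'")
  }

  manifest <- list(operation = op, seed = seed,
                   parameters = config[setdiff(names(config), c("operation", "out"))],
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 12)
  invisible(manifest)
}
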