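# Exporters. All floating-point output goes through fmt_num() (12 significant
# digits) so two runs with the same configuration produce byte-identical
# artifacts.

#' Export a trajectory as CSV
#'
#' Columns: `t`, `x1..xn`, `termination` (repeated on every row).
#'
#' @param traj A `Trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  n <- ncol(traj$states)
  df <- data.frame(t = fmt_num(traj$times))
  for (j in seq_len(n)) df[[paste0("x", j)]] <- fmt_num(traj$states[, j])
  df$termination <- traj$termination$type
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a label grid as CSV
#'
#' Columns: `x1..xn`, `status`, `violated`, `death_time`.
#'
#' @param grid A `LabelGrid` from [classify_grid()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_labels_csv <- function(grid, path) {
  stopifnot(inherits(grid, "LabelGrid"))
  n <- ncol(grid$points)
  df <- data.frame(row.names = seq_len(nrow(grid$points)))
  for (j in seq_len(n)) df[[paste0("x", j)]] <- fmt_num(grid$points[, j])
  df$status <- grid$status
  df$violated <- ifelse(is.na(grid$violated), "", grid$violated)
  df$death_time <- ifelse(is.na(grid$death_time), "",
                          fmt_num(grid$death_time))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a manifold polyline as CSV
#'
#' Columns: `kind`, `t` (backward time from the seed), `x1..xn`.
#'
#' @param manifold A `Manifold`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_manifold_csv <- function(manifold, path) {
  stopifnot(inherits(manifold, "Manifold"))
  n <- ncol(manifold$points)
  df <- data.frame(kind = rep(manifold$kind, nrow(manifold$points)),
                   t = fmt_num(manifold$times))
  for (j in seq_len(n)) df[[paste0("x", j)]] <- fmt_num(manifold$points[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a separation report as JSON
#'
#' @param report A `SeparationReport` from [verify_separation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_separation_json <- function(report, path) {
  stopifnot(inherits(report, "SeparationReport"))
  obj <- list(fraction = report$fraction, n_evaluated = report$n_evaluated,
              n_skipped = report$n_skipped, band = report$band,
              seed = report$seed,
              counterexamples = report$counterexamples)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(path)
}

#' Export a configuration graph as DOT
#'
#' One node per alive subset (the empty subset rendered `{}`), one edge per
#' possible death event, labelled with the dying subset; realized edges are
#' drawn solid/bold, unrealized edges dashed.
#'
#' @param graph A `ConfigurationGraph`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_graph_dot <- function(graph, path) {
  stopifnot(inherits(graph, "ConfigurationGraph"))
  q <- function(s) paste0("\"", s, "\"")
  lines <- c("digraph configuration {")
  lines <- c(lines, paste0("  ", q(graph$nodes), ";"))
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    style <- if (e$realized) "style=bold" else "style=dashed"
    lines <- c(lines, sprintf("  %s -> %s [label=%s, %s];",
                              q(e$source), q(e$target), q(e$dying), style))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Parse a DOT file written by [export_graph_dot()]
#'
#' Minimal reader for round-trip checks: returns node names and an edge table.
#'
#' @param path DOT file path.
#' @return List with `nodes` (character) and `edges` (data frame: `source`,
#'   `target`, `dying`, `realized`).
#' @export
read_graph_dot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  node_lines <- grep("^\\s*\"[^\"]*\"\\s*;\\s*$", lines, value = TRUE)
  nodes <- sub("^\\s*\"([^\"]*)\"\\s*;\\s*$", "\\1", node_lines)
  edge_lines <- grep("->", lines, value = TRUE)
  m <- regmatches(edge_lines,
                  regexec("\"([^\"]*)\"\\s*->\\s*\"([^\"]*)\"\\s*\\[label=\"([^\"]*)\",\\s*style=(\\w+)\\]",
                          edge_lines))
  edges <- do.call(rbind, lapply(m, function(g) {
    data.frame(source = g[2], target = g[3], dying = g[4],
               realized = g[5] == "bold", stringsAsFactors = FALSE)
  }))
  list(nodes = nodes, edges = edges %||%
         data.frame(source = character(0), target = character(0),
                    dying = character(0), realized = logical(0)))
}

#' Export a hybrid trajectory
#'
#' Writes a JSON-lines event log (`<stem>_events.jsonl`, one death event per
#' line) and one CSV per continuous segment
#' (`<stem>_segment<k>.csv`).
#'
#' @param ht A `HybridTrajectory`.
#' @param stem Output path stem.
#' @return Character vector of written paths, invisibly.
#' @export
export_hybrid <- function(ht, stem) {
  stopifnot(inherits(ht, "HybridTrajectory"))
  paths <- character(0)
  ev_path <- paste0(stem, "_events.jsonl")
  con <- file(ev_path, "w")
  for (ev in ht$events) {
    writeLines(jsonlite::toJSON(list(
      time = ev$time, dying = ev$dying, source = ev$source_key,
      pre_state = ev$pre_state, post_state = ev$post_state
    ), auto_unbox = TRUE, digits = 12), con)
  }
  close(con)
  paths <- c(paths, ev_path)
  for (k in seq_along(ht$segments)) {
    sg <- ht$segments[[k]]
    p <- paste0(stem, "_segment", k, ".csv")
    tr <- sg$trajectory
    tr$times <- tr$times + sg$t_offset
    export_trajectory_csv(tr, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a viability partition as CSV
#'
#' @param partition A `PartitionSummary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_partition_csv <- function(partition, path) {
  stopifnot(inherits(partition, "PartitionSummary"))
  utils::write.csv(partition$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
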