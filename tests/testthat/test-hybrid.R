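test_that("configuration graphs have 2^k nodes and 3^k - 2^k edges", {
  fx <- make_two_cell_fixture()
  one <- multicell_system(cells = fx$system$cells["blue"],
                          dynamics = fx$system$dynamics["blue"])
  g1 <- configuration_graph(one)
  expect_length(g1$nodes, 2)
  expect_equal(nrow(g1$edges), 1)

  g2 <- configuration_graph(fx$system)
  expect_length(g2$nodes, 4)
  expect_equal(nrow(g2$edges), 5)

  cells3 <- list(fx$system$cells$blue, fx$system$cells$purple,
                 cell_spec("green", viability_region(
                   list(box_constraint(1, "lower", 0.2, id = "g_lower")),
                   dimension = 1)))
  dyn3 <- list()
  for (s in viadeco:::all_subsets(c("blue", "purple", "green"), nonempty = TRUE)) {
    n <- length(s)
    dyn3[[subset_key(s)]] <- linear_field(-diag(n), center = rep(0.5, n))
  }
  g3 <- configuration_graph(multicell_system(cells3, dyn3))
  expect_length(g3$nodes, 8)
  expect_equal(nrow(g3$edges), 19)

  # every edge removes a nonempty dying subset from its source
  for (i in seq_len(nrow(g2$edges))) {
    e <- g2$edges[i, ]
    src <- strsplit(e$source, "+", fixed = TRUE)[[1]]
    dy <- strsplit(e$dying, "+", fixed = TRUE)[[1]]
    tgt <- if (e$target == "{}") character(0) else
      strsplit(e$target, "+", fixed = TRUE)[[1]]
    expect_true(all(dy %in% src))
    expect_setequal(tgt, setdiff(src, dy))
  }
})

test_that("a viable joint attractor yields a single event-free segment", {
  fx <- make_two_cell_fixture(overrides = list(c_joint = c(0.7, 0.6)))
  ht <- simulate_hybrid(fx$system, c(0.9, 0.3), horizon = 20)
  expect_length(ht$events, 0)
  expect_length(ht$segments, 1)
  expect_setequal(ht$final_alive, c("blue", "purple"))
  expect_equal(ht$final_state, c(0.7, 0.6), tolerance = 1e-4)
})

test_that("death cascades collapse the state space cell by cell", {
  fx <- make_two_cell_fixture()
  # blue holds b >> a when purple dies: purple first, then blue recovers to 1
  ht <- simulate_hybrid(fx$system, c(0.9, 0.2), horizon = 100)
  expect_length(ht$events, 1)
  expect_identical(ht$events[[1]]$dying, "purple")
  expect_identical(ht$final_alive, "blue")
  expect_equal(ht$final_state, 1, tolerance = 1e-3)

  # blue near its floor dies first; purple's reduced fate follows its own cubic
  ht2 <- simulate_hybrid(fx$system, c(0.12, 0.9), horizon = 100)
  expect_identical(ht2$events[[1]]$dying, "blue")

  # a cell already outside its region dies in an immediate t = 0 event
  ht3 <- simulate_hybrid(fx$system, c(0.9, 0.01), horizon = 100)
  expect_equal(ht3$events[[1]]$time, 0)
  expect_identical(ht3$events[[1]]$dying, "purple")
})

test_that("dimension bookkeeping holds across every death event", {
  fx <- make_two_cell_fixture()
  nv <- vapply(fx$system$cells, `[[`, integer(1), "n_vars")
  x0s <- viadeco:::with_seed(21, matrix(stats::runif(100, 0.06, 1.5), ncol = 2))
  for (i in seq_len(nrow(x0s))) {
    ht <- simulate_hybrid(fx$system, x0s[i, ], horizon = 30)
    for (ev in ht$events) {
      expect_equal(length(ev$post_state),
                   length(ev$pre_state) - sum(nv[ev$dying]))
    }
  }
})

test_that("realized edges form a subgraph of the configuration graph", {
  fx <- make_two_cell_fixture()
  graph <- configuration_graph(fx$system)
  x0s <- list(c(0.9, 0.2), c(0.12, 0.9), c(0.9, 0.01), c(0.3, 0.3))
  hts <- lapply(x0s, function(x0) simulate_hybrid(fx$system, x0, horizon = 50))
  marked <- mark_realized(graph, hts)
  expect_true(sum(marked$edges$realized) >= 2)
  # realized flags only ever sit on existing edges (same table, by construction)
  expect_identical(marked$edges[, c("source", "dying", "target")],
                   graph$edges[, c("source", "dying", "target")])
})

test_that("reduced systems restrict to survivors", {
  fx <- make_two_cell_fixture()
  full <- reduced_system(fx$system, c("blue", "purple"))
  expect_equal(full$field$dimension, 2)
  expect_setequal(full$region$ids, c("blue:b_lower", "purple:p_lower"))

  blue <- reduced_system(fx$system, "blue")
  expect_equal(blue$field$dimension, 1)
  # bistable: pulled to 1 from above the unstable point
  expect_gt(eval_field(blue$field, 0.7), 0)
  expect_lt(eval_field(blue$field, 0.2), 0)

  expect_error(reduced_system(fx$system, character(0)), "nonempty")
})

test_that("collapse_state projects out dying coordinates exactly", {
  fx <- make_two_cell_fixture()
  x <- c(0.7, 0.05)
  expect_identical(collapse_state(x, c("blue", "purple"), "purple", fx$system),
                   0.7)
  expect_length(collapse_state(x, c("blue", "purple"), c("blue", "purple"),
                               fx$system), 0)
  expect_error(collapse_state(0.7, "blue", "purple", fx$system),
               class = "invalid_dying_subset")

  # a custom debris rule may append variables but must keep survivors intact
  debris <- function(x, alive, dying, system) c(x[1], 99)
  out <- collapse_state(x, c("blue", "purple"), "purple", fx$system,
                        collapse_rule = debris)
  expect_identical(out, c(0.7, 99))
})

test_that("collapse points are facet pre-images of reduced-system structures", {
  fx <- make_two_cell_fixture()
  cps <- find_collapse_points(fx$system, c("blue", "purple"), "purple",
                              target = 0.4)
  expect_length(cps, 1)
  expect_identical(cps[[1]]$location, c(0.4, 0.05))
  expect_true(cps[[1]]$organizing)

  # the viable attractor is a valid but non-organizing target
  cps2 <- find_collapse_points(fx$system, c("blue", "purple"), "purple",
                               target = 1)
  expect_false(cps2[[1]]$organizing)

  expect_error(find_collapse_points(fx$system, c("blue", "purple"), "purple",
                                    target = 0.02),
               class = "target_outside_region")
})

test_that("collapse manifolds separate post-collapse fates", {
  fx <- make_two_cell_fixture()
  cp <- find_collapse_points(fx$system, c("blue", "purple"), "purple",
                             target = 0.4)[[1]]
  cm <- collapse_manifold(fx$system, c("blue", "purple"), cp,
                          backward_horizon = 6)
  expect_identical(cm$kind, "collapse")
  expect_equal(cm$points[1, ], cp$location, tolerance = 1e-10)

  blue_fate <- function(x) {
    ht <- simulate_hybrid(fx$system, x, horizon = 150)
    if ("blue" %in% ht$final_alive) "blue_survives" else "blue_dies"
  }
  full <- reduced_system(fx$system, c("blue", "purple"))
  rep_ <- verify_separation(cm, blue_fate, n_probes = 40, band = 1e-2,
                            seed = 7, region = full$region)
  expect_equal(rep_$fraction, 1.0)
})

test_that("hybrid first deaths agree with the ordering-manifold side", {
  fx <- make_two_cell_fixture()
  full <- reduced_system(fx$system, c("blue", "purple"))
  corner <- find_joint_fatal_corners(full$field, full$region)$corners[[1]]
  om <- ordering_manifold(full$field, full$region, corner, backward_horizon = 6)
  cls <- function(x) {
    ht <- simulate_hybrid(fx$system, x, horizon = 100)
    d <- ht$events[[1]]$dying
    if (length(d) > 1) "joint" else if (d == "blue") "blue:b_lower" else "purple:p_lower"
  }
  rep_ <- verify_separation(om, cls, n_probes = 40, band = 1e-2, seed = 5,
                            region = full$region)
  expect_equal(rep_$fraction, 1.0)
})
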