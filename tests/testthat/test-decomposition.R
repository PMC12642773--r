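test_that("normal flow is the outward component of the field on a facet", {
  fa <- make_single_cell_fixture("A")
  expect_equal(normal_flow(fa$field, fa$region, "x1_upper", c(1, 0.5)), -0.5)

  rot <- linear_field(rbind(c(0, -1), c(1, 0)))
  rbox <- box_region(c(-1, -1), c(1, 1))
  expect_equal(normal_flow(rot, rbox, "x1_upper", c(1, 0)), 0)

  fb <- make_single_cell_fixture("B")
  expect_equal(normal_flow(fb$field, fb$region, "x1_upper", c(1, 0.5)), 0.5)

  expect_error(normal_flow(fa$field, fa$region, "x1_upper", c(0.5, 0.5)),
               class = "not_on_facet")
})

test_that("tangency scan finds all sign changes of the normal flow", {
  # all-inward boundary: no tangency on any facet
  fa <- make_single_cell_fixture("A")
  for (id in fa$region$ids) {
    expect_length(find_tangency_points(fa$field, fa$region, id,
                                       attractors = fa$attractors), 0)
  }

  # rotation field: tangency where the facet's flow component vanishes
  rot <- linear_field(rbind(c(0, -1), c(1, 0)))
  rbox <- box_region(c(-1, -1), c(1, 1))
  tps <- find_tangency_points(rot, rbox, "x1_upper")
  expect_length(tps, 1)
  expect_equal(tps[[1]]$location, c(1, 0), tolerance = 1e-9)

  # scenario-C spiral: closed-form root omega*x1 + lambda*x2 = 0 on x2 = 0.5
  fc <- make_single_cell_fixture("C")
  tps <- find_tangency_points(fc$field, fc$region, "x2_upper",
                              attractors = fc$attractors)
  expect_length(tps, 1)
  tp <- tps[[1]]
  expect_equal(tp$location, c(0.05, 0.5), tolerance = 1e-6)
  expect_lt(abs(tp$normal_flow_residual), 1e-9)
  expect_identical(tp$forward_fate$status, "asymptotically_viable")
  expect_true(tp$organizing)
  expect_identical(tp$crossing_character, "inward_to_outward")

  # exhaustiveness: doubling the scan resolution discovers nothing new
  tps2 <- find_tangency_points(fc$field, fc$region, "x2_upper",
                               scan_resolution = 400,
                               attractors = fc$attractors)
  expect_length(tps2, length(tps))
  expect_equal(tps2[[1]]$location, tp$location, tolerance = 1e-9)
})

test_that("mortality manifolds start at their seed and stay inside the region", {
  fc <- make_single_cell_fixture("C")
  tp <- find_tangency_points(fc$field, fc$region, "x2_upper",
                             attractors = fc$attractors)[[1]]
  mf <- mortality_manifold(fc$field, fc$region, tp)
  expect_identical(mf$kind, "mortality")
  expect_equal(mf$points[1, ], tp$location, tolerance = 1e-10)
  inside <- apply(mf$points, 1, function(x) region_contains(fc$region, x, tol = 1e-6))
  expect_true(all(inside))
  expect_identical(mf$labels_either_side,
                   c("asymptotically_viable", "transiently_viable"))

  # a tangency whose forward fate is not asymptotic organizes nothing
  fake <- tp
  fake$forward_fate$status <- "transiently_viable"
  expect_error(mortality_manifold(fc$field, fc$region, fake),
               class = "not_a_mortality_point")
})

test_that("the scenario-C mortality manifold separates the two viable sets", {
  fc <- make_single_cell_fixture("C")
  tp <- find_tangency_points(fc$field, fc$region, "x2_upper",
                             attractors = fc$attractors)[[1]]
  mf <- mortality_manifold(fc$field, fc$region, tp)
  classifier <- function(x) classify_state(fc$field, fc$region, x, horizon = 200,
                                           attractors = fc$attractors)$status
  rep_ <- verify_separation(mf, classifier, n_probes = 40, band = 1e-2,
                            seed = 1234, region = fc$region)
  expect_equal(rep_$fraction, 1.0)
  expect_gt(rep_$n_evaluated, 20)

  # a straight chord of the region is not a separatrix: counterexamples appear
  chord <- viadeco:::new_manifold(
    "mortality", seed = c(-0.9, 0.5),
    points = rbind(c(-0.9, 0.45), c(0.9, 0.45)),
    times = c(0, 1),
    labels_either_side = c("asymptotically_viable", "transiently_viable"),
    termination = list(type = "horizon_reached"))
  rep_bad <- verify_separation(chord, classifier, n_probes = 40, band = 1e-2,
                               seed = 1234, region = fc$region)
  expect_lt(rep_bad$fraction, 1.0)
  expect_gt(nrow(rep_bad$counterexamples), 0)

  expect_error(verify_separation(mf, classifier, n_probes = 0), "n_probes")
})

test_that("forward flow from a mortality-manifold point re-reaches the seed facet", {
  fc <- make_single_cell_fixture("C")
  tp <- find_tangency_points(fc$field, fc$region, "x2_upper",
                             attractors = fc$attractors)[[1]]
  mf <- mortality_manifold(fc$field, fc$region, tp)
  # pick interior polyline points a little way back along the manifold and
  # integrate forward: each returns to within event tolerance of the seed
  idx <- which(mf$times > 0.5 & mf$times < 3)[1:3]
  for (i in idx) {
    x <- mf$points[i, ]
    tr <- integrate_field(fc$field, x, duration = mf$times[i] + 0.2,
                          n_out = 4001)
    d <- sqrt(rowSums(sweep(tr$states, 2, tp$location)^2))
    # closest sampled approach is bounded by the output spacing times the speed
    expect_lt(min(d), 1e-3)
  }
})

test_that("joint-fatal corners require strictly outward flow in both constraints", {
  fx <- make_two_cell_fixture()
  full <- reduced_system(fx$system, c("blue", "purple"))
  found <- find_joint_fatal_corners(full$field, full$region)
  expect_length(found$corners, 1)
  expect_equal(found$corners[[1]]$location, c(0.1, 0.05))
  expect_setequal(found$corners[[1]]$constraint_ids,
                  c("blue:b_lower", "purple:p_lower"))
  expect_true(all(found$corners[[1]]$normal_flows > 0))

  # all-inward region: no fatal corner
  fa <- make_single_cell_fixture("A")
  expect_length(find_joint_fatal_corners(fa$field, fa$region)$corners, 0)

  # one zero component: excluded from fatal, reported marginal
  slide <- vector_field(function(x) c(0, -1), dimension = 2)
  region <- box_region(c(0, 0), c(1, 1))
  res <- find_joint_fatal_corners(slide, region)
  expect_length(res$corners, 0)
  expect_gt(length(res$marginal), 0)
})

test_that("ordering manifolds separate which constraint is violated first", {
  fx <- make_two_cell_fixture()
  full <- reduced_system(fx$system, c("blue", "purple"))
  corner <- find_joint_fatal_corners(full$field, full$region)$corners[[1]]
  om <- ordering_manifold(full$field, full$region, corner, backward_horizon = 6)
  expect_identical(om$kind, "ordering")
  expect_equal(om$points[1, ], corner$location, tolerance = 1e-10)
  expect_false(om$degenerate)

  first_violated <- function(x) {
    lab <- classify_state(full$field, full$region, x, horizon = 100)
    lab$violated[1]
  }
  rep_ <- verify_separation(om, first_violated, n_probes = 40, band = 1e-2,
                            seed = 99, region = full$region)
  expect_equal(rep_$fraction, 1.0)

  # an interior point is not a joint-fatal corner
  expect_error(
    ordering_manifold(full$field, full$region,
                      list(location = c(0.5, 0.5),
                           constraint_ids = corner$constraint_ids)),
    class = "not_joint_fatal")
})
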