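test_that("the step rule preserves quiescence and still lifes", {
  empty <- gol_grid()
  expect_equal(nrow(live_cells(gol_step(empty))), 0)

  block <- make_gol_fixture("block")
  expect_identical(live_cells(gol_step(block)), live_cells(block))

  blinker <- make_gol_fixture("blinker")
  s1 <- gol_step(blinker)
  s2 <- gol_step(s1)
  expect_false(identical(live_cells(s1), live_cells(blinker))) # vertical
  expect_identical(live_cells(s2), live_cells(blinker))        # period 2
})

test_that("the engine agrees cell-for-cell with a naive double-loop oracle", {
  n_grids <- 50
  for (g in seq_len(n_grids)) {
    cells <- viadeco:::with_seed(1000 + g, {
      m <- matrix(stats::rbinom(32 * 32, 1, 0.3), 32, 32)
      which(m == 1L, arr.ind = TRUE)
    })
    grid <- gol_grid(cells)
    nm <- naive_matrix(cells, pad = 24)
    mat <- nm$mat
    for (s in 1:20) {
      grid <- gol_step(grid)
      mat <- naive_step(mat)
    }
    expect_identical(live_cells(grid),
                     viadeco:::normalize_cells(naive_live(mat, nm$origin)))
  }
})

test_that("glider phases are 5-cell patterns cycling with a (1,1) shift per period", {
  ph <- glider_phases()
  expect_length(ph, 4)
  total_shift <- c(0, 0)
  for (k in 1:4) {
    expect_equal(nrow(ph[[k]]$cells), 5)
    # membrane is off by construction: disjoint from the on-cells
    on_key <- paste(ph[[k]]$cells[, 1], ph[[k]]$cells[, 2])
    mem_key <- paste(ph[[k]]$membrane[, 1], ph[[k]]$membrane[, 2])
    expect_length(intersect(on_key, mem_key), 0)
    # stepping phase k yields phase (k+1) mod 4 at the recorded shift
    g <- gol_grid(sweep(ph[[k]]$cells, 2, c(20, 20), "+"))
    m <- match_glider(gol_step(g), "exact")
    expect_equal(m$phase, k %% 4)
    expect_equal(m$offset, c(20, 20) + ph[[k]]$shift)
    total_shift <- total_shift + ph[[k]]$shift
  }
  expect_equal(total_shift, c(1, 1))
})

test_that("the unperturbed glider translates by (k,k) every 4k steps", {
  grid <- viadeco:::config_to_grid(make_gol_fixture("glider"), margin = 10)
  for (k in 1:10) {
    grid <- gol_run(grid, 4)
    m <- match_glider(grid, "exact")
    expect_equal(m$phase, 0)
    expect_equal(m$offset, c(10, 10) + k)
  }
})

test_that("glider matching distinguishes exact and windowed modes", {
  ph <- glider_phases()
  g <- gol_grid(sweep(ph[[1]]$cells, 2, c(3, 7), "+"))
  m <- match_glider(g, "exact")
  expect_equal(m$phase, 0)
  expect_equal(m$offset, c(3, 7))

  expect_null(match_glider(make_gol_fixture("block"), "exact"))
  expect_null(match_glider(make_gol_fixture("block"), "windowed"))

  scene <- gol_grid(rbind(sweep(ph[[1]]$cells, 2, c(3, 7), "+"),
                          c(20, 20), c(20, 21), c(21, 20), c(21, 21)))
  expect_null(match_glider(scene, "exact"))
  mw <- match_glider(scene, "windowed")
  expect_equal(mw$offset, c(3, 7))

  # a live cell on the membrane destroys the windowed identity
  bad <- gol_grid(rbind(sweep(ph[[1]]$cells, 2, c(3, 7), "+"),
                        sweep(ph[[1]]$membrane[1, , drop = FALSE], 2, c(3, 7), "+")))
  expect_null(match_glider(bad, "windowed"))
})

test_that("perturbation enumeration has binomial counts", {
  base <- make_gol_fixture("glider")
  w <- as.matrix(expand.grid(11:13, 14:16))  # flush with the membrane, ahead
  expect_length(enumerate_perturbations(base, w, max_flips = 0), 1)
  expect_length(enumerate_perturbations(base, w, max_flips = 1), 10)
  expect_length(enumerate_perturbations(base, w, max_flips = 2),
                1 + 9 + choose(9, 2))
  expect_length(enumerate_perturbations(base, matrix(integer(0), ncol = 2),
                                        max_flips = 2), 1)
  # windows may not touch the membrane itself
  expect_error(enumerate_perturbations(base, rbind(c(13, 13)), max_flips = 1),
               "membrane")
})

test_that("configuration classification follows the glider's self-maintenance", {
  glider <- make_gol_fixture("glider")
  cl <- classify_configuration(glider, horizon = 100)
  expect_identical(cl$label, "interior")
  expect_false(cl$recovered)
  # after 100 steps the glider sits 25 cells down the diagonal
  grid <- gol_run(viadeco:::config_to_grid(glider, margin = 10), 100)
  m <- match_glider(grid, "exact")
  expect_equal(m$offset, c(35, 35))

  expect_identical(classify_configuration(gol_grid(), horizon = 64)$label,
                   "nonmember")
  # 4 live cells contain no glider: nonmember at t = 0
  ph <- glider_phases()
  broken <- gol_grid(sweep(ph[[1]]$cells[-1, , drop = FALSE], 2, c(10, 10), "+"))
  expect_identical(classify_configuration(broken, horizon = 64)$label,
                   "nonmember")

  # a block on the glider's path destroys it: boundary, with the step recorded
  vs <- classify_configuration(make_gol_fixture("glider_vs_block"), horizon = 64)
  expect_identical(vs$label, "boundary")
  expect_true(is.finite(vs$steps_to_disintegration))
})

test_that("single-flip partitions match the independent exhaustive oracle", {
  base <- make_gol_fixture("glider")
  w <- as.matrix(expand.grid(11:13, 14:16))
  configs <- enumerate_perturbations(base, w, max_flips = 1)
  part <- viability_partition(configs, horizon = 64)
  expect_equal(sum(part$counts), length(configs))

  oracle <- vapply(configs, function(cfg) {
    ph <- glider_phases()[[cfg$phase + 1]]
    cells <- rbind(sweep(ph$cells, 2, cfg$position, "+"), cfg$environment)
    naive_classify(cells, horizon = 64)
  }, character(1))
  expect_identical(part$records$label, unname(oracle))
  # the window beside the membrane produces both outcomes
  expect_setequal(unique(part$records$label), c("interior", "boundary"))
})

test_that("partitions conserve counts and the unperturbed base is interior", {
  base <- make_gol_fixture("glider")
  part <- viability_partition(enumerate_perturbations(
    base, as.matrix(expand.grid(11:13, 14:16)), max_flips = 0), horizon = 64)
  expect_equal(unname(part$counts["interior"]), 1L)
  expect_equal(sum(part$counts), 1L)
})

test_that("window overflow grows the grid or errors when growth is disabled", {
  ph <- glider_phases()
  tight <- gol_grid(sweep(ph[[1]]$cells, 2, c(1, 1), "+"), margin = 1)
  expect_error(gol_step(tight, auto_grow = FALSE), class = "window_overflow")
  grown <- gol_step(tight)                 # auto-grow succeeds
  expect_equal(nrow(live_cells(grown)), 5)
  expect_error(gol_step(tight, max_size = 4L), class = "window_overflow")
})

test_that("RLE and .cells files round-trip patterns", {
  grid <- viadeco:::config_to_grid(make_gol_fixture("glider"))
  p1 <- withr::local_tempfile(fileext = ".rle")
  write_rle(grid, p1, comment = "glider, phase 0")
  expect_identical(live_cells(read_rle(p1, origin = c(10, 10))),
                   live_cells(grid))

  p2 <- withr::local_tempfile(fileext = ".cells")
  write_cells(grid, p2)
  expect_identical(live_cells(read_cells(p2, origin = c(10, 10))),
                   live_cells(grid))

  # hand-written RLE of the textbook glider
  p3 <- withr::local_tempfile(fileext = ".rle")
  writeLines(c("#C glider", "x = 3, y = 3, rule = B3/S23", "bob$2bo$3o!"), p3)
  g <- read_rle(p3, origin = c(0, 0))
  m <- match_glider(g, "exact")
  expect_equal(m$phase, 0)
})
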