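test_that("sink filling leaves monotone surfaces alone and is idempotent", {
  ramp <- eco_grid(outer(rep(1, 6), 6:1) * 10, 30)
  f <- fill_sinks(ramp)
  expect_equal(f$values, ramp$values, tolerance = 1e-9)

  z <- matrix(10, 5, 5); z[3, 3] <- 2
  pit <- eco_grid(z, 30)
  f2 <- fill_sinks(pit)
  expect_equal(f2$values[3, 3], 10, tolerance = 1e-4)  # lowest pour point
  f3 <- fill_sinks(f2)
  expect_identical(f3$values, f2$values)
})

test_that("D8 on an east-tilted plane drains east with linear accumulation", {
  z <- outer(rep(1, 6), 6:1) * 5.0   # decreasing eastwards
  ff <- d8_flow(eco_grid(z, 30))
  dir <- ff$flow_direction$values
  expect_true(all(dir[, 1:5] == 1))     # E
  expect_true(all(dir[, 6] == 0))       # outlets on the east edge
  acc <- ff$flow_accumulation$values
  expect_equal(acc[3, ], 0:5)
})

test_that("flow is conserved: outlet drainage accounts for every cell", {
  set.seed(17)
  for (i in 1:4) {
    z <- matrix(stats::runif(100, 0, 50), 10, 10)
    ff <- d8_flow(fill_sinks(eco_grid(z, 30)))
    acc <- ff$flow_accumulation$values
    outlets <- ff$flow_direction$values == 0
    expect_equal(sum(acc[outlets] + 1), 100)
    # accumulation of any cell at least matches its immediate upstreams
    expect_true(all(acc >= 0))
  }
})

test_that("hand-traced 4x4 fixture accumulates as expected", {
  z <- matrix(c(4, 3, 2, 1,
                5, 4, 3, 2,
                6, 5, 4, 3,
                7, 6, 5, 4), 4, 4, byrow = TRUE)
  ff <- d8_flow(eco_grid(z, 30))
  # steepest descent is diagonal NE (priority E first when tied):
  # gradients: E drop 1/1, NE drop (z - z_ne)/sqrt2 = 2/1.414 > 1 except row 1
  dir <- ff$flow_direction$values
  expect_true(all(dir[1, 1:3] == 1))   # top row flows E
  expect_true(all(dir[2:4, 1:3] == 8)) # others flow NE
  acc <- ff$flow_accumulation$values
  # manual trace: the outlet at (1,4) drains all 15 other cells
  expect_equal(acc[1, 4], 15)
  expect_equal(acc[1, 3], 5)
  expect_equal(acc[2, 4], 5)
  expect_equal(acc[4, ], rep(0, 4))
})

test_that("ridges are the valleys of the negated surface", {
  set.seed(23)
  z <- matrix(stats::runif(144, 0, 10), 12, 12)
  g <- eco_grid(z, 30)
  vr <- valleys_and_ridges(g, quantile = 0.9)
  neg <- g; neg$values <- -neg$values
  vr_neg <- valleys_and_ridges(neg, quantile = 0.9)
  expect_identical(vr$ridges, vr_neg$valleys)
  # raising the quantile never adds valley cells
  vr95 <- valleys_and_ridges(g, quantile = 0.97)
  expect_true(all(vr95$valleys <= vr$valleys))
})

test_that("a trough line concentrates the valley cells", {
  z <- outer(rep(1, 9), rep(1, 9))
  for (r in 1:9) for (c in 1:9) z[r, c] <- abs(r - 5) * 10 + c * 0.1
  vr <- valleys_and_ridges(eco_grid(z, 30), quantile = 0.9)
  hit <- which(vr$valleys, arr.ind = TRUE)
  expect_true(all(hit[, 1] == 5))   # all on the trough row
})

test_that("node classification finds constructed crossings and merges them", {
  dims <- c(21, 21)
  # one corridor along row 11, a ridge along column 11
  corridor_cells <- (seq_len(21) - 1) * 21 + 11
  ridge <- matrix(FALSE, 21, 21); ridge[, 11] <- TRUE
  valley <- matrix(FALSE, 21, 21); valley[3, ] <- TRUE
  pathset <- structure(list(
    paths = list(list(src = 1L, dst = 2L, cells = corridor_cells,
                      length_km = 20, cum_cost = 20)),
    table = tibble::tibble(src = 1L, dst = 2L, length_km = 20, cum_cost = 20,
                           kept = TRUE, drop_reason = NA_character_),
    dim = dims, cell_size = 1000, origin = c(0, 0)),
    class = "cost_path_set")
  corridors <- classify_corridors(
    tibble::tibble(src = 1L, dst = 2L, length_km = 20, cum_cost = 20,
                   gravity = 50))
  # strategic: one crossing cluster at (11, 11)
  ns <- suppressWarnings(classify_nodes(ridge, valley, corridors, pathset,
                                        masks = list()))
  strat <- ns[ns$node_type == "strategic", ]
  expect_equal(nrow(strat), 1)
  expect_equal(round(strat$row), 11)
  expect_equal(round(strat$col), 11)

  # natural: two persistent corridors crossing once
  cross_cells <- seq_len(21) + (11 - 1) * 21   # column 11... row-wise line
  ns2 <- suppressWarnings(classify_nodes(
    ridge, valley, corridors, pathset,
    persistent_cells = list(corridor_cells, cross_cells), masks = list()))
  nat <- ns2[ns2$node_type == "natural", ]
  expect_equal(nrow(nat), 1)

  # artificial: valley row crosses a road column; absent masks yield none
  road <- matrix(FALSE, 21, 21); road[, 7] <- TRUE
  ns3 <- suppressWarnings(classify_nodes(ridge, valley, corridors, pathset,
                                         masks = list(roads = road)))
  art <- ns3[ns3$node_type == "artificial", ]
  expect_equal(nrow(art), 1)
  expect_equal(round(art$row), 3)
  expect_equal(round(art$col), 7)
  w <- testthat::capture_warnings(
    classify_nodes(ridge, valley, corridors, pathset, masks = list()))
  expect_true(any(grepl("artificial", w)))
})
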