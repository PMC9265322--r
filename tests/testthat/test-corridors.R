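surf <- function(m, cs = 1000) {
  g <- eco_grid(m, cs)
  class(g) <- c("resistance_surface", class(g))
  g
}

test_that("cost distance on a uniform surface is the chamfer metric", {
  cf <- cost_distance(surf(matrix(1, 5, 5)), list(13L))  # centre cell
  v <- cf$cumulative_cost$values
  expect_equal(v[3, 3], 0)
  expect_equal(v[3, 4], 1)
  expect_equal(v[2, 4], sqrt(2), tolerance = 1e-12)
  expect_equal(v[1, 1], 2 * sqrt(2), tolerance = 1e-12)
  expect_error(cost_distance(surf(matrix(c(1, 1, 0, 1), 2, 2)), list(1L)),
               class = "econetr_validation_error")
})

test_that("cost distance matches brute-force value iteration on small grids", {
  # high-cost wall forcing a detour
  m <- matrix(1, 5, 5)
  m[1:4, 3] <- 100
  cf <- cost_distance(surf(m), list(1L))
  expect_equal(cf$cumulative_cost$values, oracle_cost_distance(m, 1L),
               tolerance = 1e-9)

  set.seed(31)
  for (i in 1:6) {
    r <- matrix(stats::runif(36, 0.5, 10), 6, 6)
    src <- sample(36, 1)
    cf2 <- cost_distance(surf(r), list(src))
    expect_equal(cf2$cumulative_cost$values, oracle_cost_distance(r, src),
                 tolerance = 1e-9, info = paste("grid", i))
  }
})

test_that("multi-source field is the pointwise minimum of single-source fields", {
  set.seed(5)
  r <- matrix(stats::runif(49, 1, 5), 7, 7)
  f1 <- cost_distance(surf(r), list(3L))$cumulative_cost$values
  f2 <- cost_distance(surf(r), list(45L))$cumulative_cost$values
  f12 <- cost_distance(surf(r), list(3L, 45L))$cumulative_cost$values
  expect_equal(f12, pmin(f1, f2), tolerance = 1e-9)
})

test_that("cost field satisfies the Bellman condition and backlinks descend", {
  set.seed(6)
  r <- matrix(stats::runif(64, 1, 8), 8, 8)
  cf <- cost_distance(surf(r), list(1L))
  cost <- cf$cumulative_cost$values
  back <- cf$backlink$values
  off <- list(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
              dc = c(1, 1, 0, -1, -1, -1, 0, 1),
              len = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))
  for (cell in seq_len(64)) {
    rr <- ((cell - 1) %% 8) + 1; cc <- ((cell - 1) %/% 8) + 1
    if (back[cell] == 0) { expect_equal(cost[cell], 0); next }
    d <- back[cell]
    r2 <- rr + off$dr[d]; c2 <- cc + off$dc[d]
    move <- (r[rr, cc] + r[r2, c2]) / 2 * off$len[d]
    expect_equal(cost[rr, cc], cost[r2, c2] + move, tolerance = 1e-9)
  }
})

test_that("pairwise least-cost paths run straight on uniform ground and filter by length", {
  m <- matrix(1, 5, 21)
  ps <- make_patch_set(list(3L, 3L + 20L * 5L), dims = c(5, 21),
                       cell_size = 1000)  # (3,1) and (3,21): 20 km apart
  lp <- least_cost_paths(surf(m), ps, min_length_km = 10)
  expect_equal(nrow(lp$table), 1)
  expect_true(lp$table$kept)
  expect_equal(lp$table$length_km, 20, tolerance = 1e-9)
  expect_equal(lp$table$cum_cost, 20, tolerance = 1e-9)  # theta = 1
  # raising the floor drops it
  lp2 <- least_cost_paths(surf(m), ps, min_length_km = 30)
  expect_false(lp2$table$kept)
  expect_equal(lp2$table$drop_reason, "below_min_length")
})

test_that("duplicated paths collapse onto the cheaper corridor", {
  # three collinear 1-cell patches: the long pair's path contains the others
  m <- matrix(1, 3, 30)
  cells <- list(2L + 3L * 1L, 2L + 3L * 14L, 2L + 3L * 28L)  # row 2
  ps <- make_patch_set(cells, dims = c(3, 30), cell_size = 1000)
  lp <- least_cost_paths(surf(m), ps, min_length_km = 5, overlap_dedup = 0.9)
  expect_equal(nrow(lp$table), 3)
  expect_equal(sum(lp$table$kept), 2)
  dropped <- lp$table[!lp$table$kept, ]
  expect_equal(dropped$drop_reason, "duplicate")
  expect_equal(c(dropped$src, dropped$dst), c(1L, 3L))  # longest, costliest
})

test_that("gravity follows the closed form and its scale-free tiering", {
  pathset <- structure(list(
    table = tibble::tibble(src = c(1L, 1L), dst = c(2L, 3L),
                           length_km = c(10, 20), cum_cost = c(50, 100),
                           kept = TRUE, drop_reason = NA_character_),
    paths = list(), dim = c(1, 3), cell_size = 1000, origin = c(0, 0)),
    class = "cost_path_set")
  patches <- tibble::tibble(id = 1:3, area_km2 = c(exp(1), exp(1), exp(1)) / 100)
  g <- gravity_ranking(pathset, patches, area_unit = "ha")  # areas = e ha
  # pair with L = Lmax and ln a = 1 on both ends -> G = 1
  expect_equal(g$gravity[g$dst == 3], 1, tolerance = 1e-12)
  # halving L quadruples G
  expect_equal(g$gravity[g$dst == 2], 4, tolerance = 1e-12)

  # areas below 1 unit are rejected with unit guidance
  patches_small <- tibble::tibble(id = 1:3, area_km2 = rep(0.005, 3))
  expect_error(gravity_ranking(pathset, patches_small, area_unit = "km2"),
               class = "econetr_validation_error")

  # scaling every resistance leaves gravity invariant
  pathset2 <- pathset
  pathset2$table$cum_cost <- pathset$table$cum_cost * 7.3
  g2 <- gravity_ranking(pathset2, patches)
  expect_equal(g2$gravity, g$gravity, tolerance = 1e-12)
})

test_that("hand-set three-patch gravity matrix matches direct arithmetic", {
  pathset <- structure(list(
    table = tibble::tibble(src = c(1L, 1L, 2L), dst = c(2L, 3L, 3L),
                           length_km = c(12, 25, 14),
                           cum_cost = c(40, 90, 60),
                           kept = TRUE, drop_reason = NA_character_),
    paths = list(), dim = c(1, 3), cell_size = 1000, origin = c(0, 0)),
    class = "cost_path_set")
  patches <- tibble::tibble(id = 1:3, area_km2 = c(12, 30, 7))
  g <- gravity_ranking(pathset, patches, area_unit = "ha")
  a <- patches$area_km2 * 100
  lmax <- 90
  want <- lmax^2 * log(a[g$src]) * log(a[g$dst]) / g$cum_cost^2
  expect_equal(g$gravity, want, tolerance = 1e-12)
})

test_that("gravity tier bounds follow the published rule, boundaries inclusive downward", {
  tbl <- tibble::tibble(src = 1:4, dst = 2:5, length_km = 1, cum_cost = 1,
                        gravity = c(265.43, 61.18, 5.99, 0.87))
  cs <- classify_corridors(tbl)
  expect_equal(cs$level[match(c(265.43, 61.18, 5.99, 0.87), cs$gravity)],
               c(1L, 2L, 3L, NA))
  cs2 <- classify_corridors(dplyr::mutate(tbl, gravity = c(100, 10, 1, 150)))
  expect_equal(cs2$level[match(c(100, 10, 1, 150), cs2$gravity)],
               c(2L, 3L, NA, 1L))
  empty <- classify_corridors(tbl[0, ])
  expect_equal(nrow(empty), 0)
})
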