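lc2 <- function(v, legend = c(a = 1L, b = 2L)) {
  land_cover(eco_grid(v, 1000), legend)
}

test_that("transitions cross-tabulate exactly", {
  set.seed(1)
  m <- matrix(sample(c(1, 2), 100, replace = TRUE), 10, 10)
  a <- lc2(m)
  tm <- estimate_transitions(a, a)
  expect_equal(tm$probabilities, diag(2), ignore_attr = TRUE)
  expect_equal(sum(tm$counts), 100)

  # exactly 7 cells move a -> b
  v2 <- m; v2[which(m == 1)[1:7]] <- 2
  tm2 <- estimate_transitions(a, lc2(v2))
  expect_equal(tm2$counts["a", "b"], 7)
  expect_equal(tm2$counts["b", "a"], 0)
  expect_equal(tm2$areas_km2["a", "b"], 7 * 1)  # 1 km2 cells

  expect_error(estimate_transitions(a, lc2(m, c(x = 1L, y = 2L))),
               class = "econetr_validation_error")
})

test_that("demand projection is the exact matrix power with conservation", {
  base <- lc2(matrix(1, 10, 10))
  v2 <- matrix(1, 10, 10); v2[1:10] <- 2
  tm <- estimate_transitions(base, lc2(v2))   # P = [[0.9, 0.1], [0, 1]]
  expect_equal(tm$probabilities["a", ], c(a = 0.9, b = 0.1))

  d1 <- project_demand(tm, c(a = 100, b = 0), steps = 1)
  expect_equal(d1$demand, c(90, 10))
  d2 <- project_demand(tm, c(a = 100, b = 0), steps = 2)
  expect_equal(d2$demand, c(81, 19))
  expect_equal(sum(d2$demand), 100)

  # identity projection returns the current counts
  tmI <- estimate_transitions(base, base)
  expect_equal(project_demand(tmI, c(a = 63, b = 37), 5)$demand, c(63, 37))

  # largest-remainder rounding conserves awkward totals
  d3 <- project_demand(tm, c(a = 33, b = 0), steps = 1)  # 29.7 / 3.3
  expect_equal(sum(d3$demand), 33)
})

test_that("transition estimation recovers the generating matrix of a synthetic series", {
  P <- diag(8)
  P[2, 2] <- 0.85; P[2, 7] <- 0.15
  P[1, 1] <- 0.9; P[1, 7] <- 0.1
  spec <- synth_spec(shape = c(100L, 100L), n_dates = 2L,
                     transition_matrix = P, seed = 9)
  ser <- make_series(spec)
  tm <- estimate_transitions(ser[[1]], ser[[2]])
  for (cls in c(1, 2)) {
    n <- sum(ser[[1]]$values == cls)
    se <- sqrt(P[cls, 7] * (1 - P[cls, 7]) / n)
    expect_lt(abs(tm$probabilities[cls, 7] - P[cls, 7]), 3 * se + 1 / n)
  }
})

test_that("suitability surfaces are per-cell probabilities honouring separable signal", {
  spec <- small_demo_spec()
  dem <- make_dem(spec)
  # constant predictor: suitability collapses to the class prior
  lc <- make_landcover(spec, dem)
  flatg <- eco_grid(matrix(1, 60, 60), 600)
  suppressWarnings(s0 <- default_suitability(list(flat = flatg), lc,
                                             sample_frac = 0.5, seed = 2))
  tot <- Reduce(`+`, lapply(s0, function(g) g$values))
  expect_equal(max(abs(tot - 1)), 0, tolerance = 1e-6)
  prior <- class_counts(lc)$fraction
  got <- vapply(s0, function(g) g$values[1, 1], numeric(1))
  expect_equal(unname(got), prior, tolerance = 0.05)

  # water perfectly separated by a synthetic indicator predictor
  ind <- eco_grid((lc$values == 5) * 1.0, 600)
  s1 <- default_suitability(list(ind = ind), lc, sample_frac = 0.2, seed = 2)
  expect_gt(mean(s1$water_area$values[lc$values == 5]), 0.95)
  expect_lt(mean(s1$water_area$values[lc$values != 5]), 0.05)
})

test_that("CA allocation meets demand, freezes restricted cells, and contracts", {
  spec <- small_demo_spec()
  dem <- make_dem(spec)
  lc <- make_landcover(spec, dem)
  cnt <- class_counts(lc)
  legend <- default_legend()
  uniform_suit <- lapply(stats::setNames(nm = names(legend)), function(k) {
    eco_grid(matrix(1 / 8, 60, 60), 600)
  })

  # demand equal to current counts: nothing to do
  dem0 <- tibble::tibble(class = cnt$class, demand = as.numeric(cnt$cells))
  r0 <- ca_allocate(lc, uniform_suit, dem0, seed = 4)
  expect_equal(r0$iterations, 0L)
  expect_identical(r0$landcover$values, lc$values)

  # move 120 cells of dry land into construction
  demand <- dem0
  demand$demand[demand$class == "dry_land"] <-
    demand$demand[demand$class == "dry_land"] - 120
  demand$demand[demand$class == "construction_land"] <-
    demand$demand[demand$class == "construction_land"] + 120
  riv <- lc$values == 5
  r1 <- ca_allocate(lc, uniform_suit, demand, restricted = riv, seed = 4)
  got <- vapply(unname(legend), function(code) {
    sum(r1$landcover$values == code)
  }, numeric(1))
  expect_true(all(abs(got - demand$demand) <=
                    pmax(0.005 * pmax(demand$demand, 1), 0.5)))
  # river cells untouched
  expect_identical(r1$landcover$values[riv], lc$values[riv])
  # total absolute deficit never grows between iterations
  expect_true(all(diff(r1$deficit_trace) <= 0))

  # infeasible demand is rejected before iteration
  bad <- demand; bad$demand[1] <- bad$demand[1] + 5
  expect_error(ca_allocate(lc, uniform_suit, bad, seed = 4),
               class = "econetr_validation_error")
})

test_that("directed suitability confines conversions to the permitted strip", {
  legend <- default_legend()
  v <- matrix(2, 20, 20)        # all dry land
  lc <- land_cover(eco_grid(v, 1000))
  strip <- matrix(0, 20, 20); strip[, 1:3] <- 1
  suit <- lapply(stats::setNames(nm = names(legend)), function(k) {
    m <- if (k == "construction_land") strip else
      matrix(1e-9, 20, 20)
    eco_grid(m, 1000)
  })
  demand <- tibble::tibble(class = names(legend),
                           demand = c(0, 350, 0, 0, 0, 0, 50, 0))
  r <- ca_allocate(lc, suit, demand, seed = 8)
  conv <- which(r$landcover$values == 7)
  expect_equal(length(conv), 50)
  cols <- ((conv - 1) %/% 20) + 1
  expect_true(all(cols <= 3))
})

test_that("agreement reproduces the closed-form kappa arithmetic", {
  m <- matrix(rep(c(1, 2), each = 50), 10, 10)
  a <- lc2(m)
  expect_equal(agreement(a, a)$kappa, 1)
  expect_equal(agreement(a, a)$overall_accuracy, 1)

  # confusion {a->a 40, a->b 10, b->a 10, b->b 40}: OA 0.8, kappa 0.6
  v2 <- m
  v2[which(m == 1)[1:10]] <- 2
  v2[which(m == 2)[1:10]] <- 1
  ag <- agreement(a, lc2(v2))
  expect_equal(ag$overall_accuracy, 0.8)
  expect_equal(ag$kappa, 0.6)

  # label permutation gives chance-level kappa
  set.seed(12)
  vp <- matrix(sample(as.vector(m)), 10, 10)
  expect_lt(abs(agreement(a, lc2(vp))$kappa), 0.2)
})
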