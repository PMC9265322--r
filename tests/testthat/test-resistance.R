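test_that("AHP recovers weights from a perfectly consistent matrix", {
  w <- c(4, 2, 1, 1) / 8
  m <- outer(w, w, "/")
  res <- ahp_weights(m)
  expect_equal(res$weights, c(0.5, 0.25, 0.125, 0.125), tolerance = 1e-6)
  expect_equal(res$consistency_ratio, 0, tolerance = 1e-6)

  m2 <- matrix(c(1, 3, 1 / 3, 1), 2, 2, byrow = TRUE)
  expect_equal(ahp_weights(m2)$consistency_ratio, 0)

  expect_error(ahp_weights(matrix(c(1, 2, 3, 1), 2, 2)),
               class = "econetr_validation_error")
})

test_that("AHP consistency ratio matches a direct eigendecomposition", {
  m <- matrix(c(1, 2, 5,
                1 / 2, 1, 3,
                1 / 5, 1 / 3, 1), 3, 3, byrow = TRUE)
  res <- ahp_weights(m)
  ev <- eigen(m)
  lambda <- Re(ev$values[1])
  expect_equal(res$lambda_max, lambda, tolerance = 1e-6)
  expect_equal(res$consistency_ratio, ((lambda - 3) / 2) / 0.58,
               tolerance = 1e-6)
  w_direct <- Re(ev$vectors[, 1]); w_direct <- w_direct / sum(w_direct)
  expect_equal(res$weights, w_direct, tolerance = 1e-6)
})

test_that("fixed-break grading reproduces the printed coefficient ladder", {
  cfg <- resistance_config()
  slope <- eco_grid(matrix(c(3, 12, 7, 46), 2, 2), 30)
  graded <- grade_layer(slope, breaks = cfg$slope_breaks,
                        values = cfg$slope_values)
  expect_equal(graded$values, matrix(c(10, 40, 20, 80), 2, 2))

  elev <- eco_grid(matrix(c(100, 150, 650, 1200), 2, 2), 30)
  ge <- grade_layer(elev, breaks = cfg$elevation_breaks,
                    values = cfg$elevation_values)
  expect_equal(ge$values, matrix(c(10, 20, 70, 90), 2, 2))

  lc <- land_cover(eco_grid(matrix(c(7, 3, 1, 2), 2, 2), 30))
  gl <- grade_layer(lc, table = cfg$landcover)
  expect_equal(gl$values, matrix(c(100, 10, 40, 50), 2, 2))
})

test_that("natural-breaks grading degrades gracefully on constant data", {
  g <- eco_grid(matrix(5, 4, 4), 30)
  graded <- grade_layer(g, values = c(10, 20, 40, 60, 80),
                        mode = "natural_breaks")
  expect_true(all(graded$values == 10))
})

test_that("jenks breaks land on the gaps between separated clusters", {
  set.seed(1)
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1), rnorm(50, 20, 0.1))
  br <- jenks_breaks(x, 3)   # class upper bounds
  expect_length(br, 2)
  expect_true(br[1] > -1 && br[1] < 1)
  expect_true(br[2] > 9 && br[2] < 11)
  # classing by the breaks recovers the clusters exactly
  cls <- findInterval(x, br, left.open = TRUE) + 1
  expect_equal(cls, rep(1:3, each = 50))
})

test_that("composition is the exact weighted overlay, clamped and monotone", {
  cfg <- resistance_config()
  mk <- function(x) eco_grid(matrix(x, 2, 2), 30)
  layers <- list(mspa = mk(10), landcover = mk(10), elevation = mk(10),
                 slope = mk(10))
  out <- compose_resistance(layers, cfg$weights)
  expect_equal(unique(as.vector(out$values)), 10)

  layers2 <- list(mspa = mk(80), landcover = mk(100), elevation = mk(10),
                  slope = mk(10))
  out2 <- compose_resistance(layers2, cfg$weights)
  expect_equal(out2$values[1, 1],
               0.5638 * 80 + 0.2634 * 100 + 0.1178 * 10 + 0.055 * 10,
               tolerance = 1e-12)   # 73.172

  # permuting layer order with matching names is a no-op
  out3 <- compose_resistance(rev(layers2), cfg$weights)
  expect_equal(out3$values, out2$values)

  # raising one layer's coefficient never lowers the composite
  layers3 <- layers2; layers3$slope <- mk(80)
  expect_true(all(compose_resistance(layers3, cfg$weights)$values >=
                    out2$values))
  expect_true(all(out2$values >= 1 & out2$values <= 100))
})

test_that("the four-layer build grades and weights end to end", {
  spec <- small_demo_spec()
  dem <- make_dem(spec)
  lc <- make_landcover(spec, dem)
  m <- mspa_classify(binarize(lc, c(1, 3, 4, 5, 6)), 1)
  r <- build_resistance(m, lc, dem, slope_from_dem(dem))
  expect_s3_class(r, "resistance_surface")
  expect_true(all(r$values >= 1 & r$values <= 100, na.rm = TRUE))
  # construction land inside the background should be high-resistance
  con <- lc$values == 7 & m$values == 0
  expect_gt(mean(r$values[con]), mean(r$values[m$values == 1]))
})

test_that("invalid configurations are rejected", {
  expect_error(resistance_config(weights = c(mspa = 0.5, landcover = 0.2,
                                             elevation = 0.2, slope = 0.2)),
               class = "econetr_validation_error")
  expect_error(resistance_config(mspa = c(core = 0.5)),
               class = "econetr_validation_error")
  lc <- land_cover(eco_grid(matrix(1, 2, 2), 30))
  lc$values[1] <- 9   # legal grid, unknown to the coefficient table
  expect_error(grade_layer(lc, table = resistance_config()$landcover),
               class = "econetr_validation_error")
})
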