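#' AHP weights from a pairwise comparison matrix
#'
#' Normalised principal eigenvector by power iteration, with Saaty's
#' consistency ratio `CR = ((lambda_max - n)/(n - 1)) / RI`. A warning is
#' issued when CR exceeds 0.1.
#'
#' @param pairwise Positive reciprocal square matrix (`m[j,i] == 1/m[i,j]`,
#'   unit diagonal).
#' @param tol Power-iteration convergence tolerance.
#' @return List with `weights` (sums to 1), `lambda_max` and
#'   `consistency_ratio` (0 for n <= 2).
#' @export
ahp_weights <- function(pairwise, tol = 1e-10) {
  m <- as.matrix(pairwise)
  n <- nrow(m)
  if (ncol(m) != n || any(m <= 0)) {
    abort_validation("`pairwise` must be a positive square matrix")
  }
  if (any(abs(m * t(m) - 1) > 1e-6) || any(abs(diag(m) - 1) > 1e-9)) {
    abort_validation("`pairwise` must be reciprocal with a unit diagonal")
  }
  w <- rep(1 / n, n)
  for (i in seq_len(10000)) {
    w2 <- as.vector(m %*% w)
    w2 <- w2 / sum(w2)
    if (max(abs(w2 - w)) < tol) { w <- w2; break }
    w <- w2
  }
  lambda_max <- mean((m %*% w) / w)
  # Saaty random consistency indices, n = 1..10
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  cr <- if (n <= 2) 0 else {
    ci <- (lambda_max - n) / (n - 1)
    ci / ri[min(n, length(ri))]
  }
  if (cr > 0.1) {
    warning(sprintf("AHP consistency ratio %.3f exceeds 0.1", cr))
  }
  list(weights = w, lambda_max = lambda_max, consistency_ratio = cr)
}

#' Resistance grading tables and layer weights
#'
#' Defaults reproduce the published grading scheme: basic resistance
#' coefficients between 1 and 100 for each factor level of the four layers
#' (MSPA class, land-cover type, elevation, slope), with AHP layer weights
#' 0.5638 / 0.2634 / 0.1178 / 0.055 (sum 1).
#'
#' @param mspa Named coefficients per MSPA class.
#' @param landcover Named coefficients per land-cover class.
#' @param elevation_breaks,elevation_values Fixed elevation class bounds (m,
#'   right-open) and the five-coefficient ladder.
#' @param slope_breaks,slope_values Same for slope, degrees.
#' @param weights Layer weights in the order mspa, landcover, elevation,
#'   slope; must be positive and sum to 1 (tolerance 1e-6).
#' @param terrain_mode `"fixed_breaks"` uses the printed bounds;
#'   `"natural_breaks"` computes 5-class Jenks breaks from the data and
#'   assigns the same coefficient ladder.
#' @return A `resistance_config` list.
#' @export
resistance_config <- function(
    mspa = c(core = 10, islet = 10, edge = 20, bridge = 20, branch = 30,
             loop = 30, perforation = 40, background = 80),
    landcover = c(paddy_field = 40, dry_land = 50, woodland = 10,
                  grassland = 20, water_area = 30, bottomland = 30,
                  construction_land = 100, unutilized_land = 60),
    elevation_breaks = c(150, 300, 600, 1000),
    elevation_values = c(10, 20, 40, 70, 90),
    slope_breaks = c(5, 10, 30, 45),
    slope_values = c(10, 20, 40, 60, 80),
    weights = c(mspa = 0.5638, landcover = 0.2634, elevation = 0.1178,
                slope = 0.055),
    terrain_mode = c("fixed_breaks", "natural_breaks")) {
  terrain_mode <- match.arg(terrain_mode)
  coefs <- c(mspa, landcover, elevation_values, slope_values)
  if (any(coefs < 1 | coefs > 100)) {
    abort_validation("resistance coefficients must lie in [1, 100]")
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-6) {
    abort_validation("layer weights must be positive and sum to 1")
  }
  structure(list(mspa = mspa, landcover = landcover,
                 elevation_breaks = elevation_breaks,
                 elevation_values = elevation_values,
                 slope_breaks = slope_breaks, slope_values = slope_values,
                 weights = weights, terrain_mode = terrain_mode),
            class = "resistance_config")
}

#' Jenks natural breaks (Fisher's exact algorithm)
#'
#' @param x Numeric vector.
#' @param k Number of classes.
#' @return `k - 1` interior break values (class upper bounds, right-closed
#'   on the left classes).
#' @export
jenks_breaks <- function(x, k = 5L) {
  x <- sort(x[is.finite(x)])
  u <- unique(x)
  if (length(u) <= k) {
    # degenerate: fewer distinct values than classes
    br <- u[-length(u)]
    return(c(br, rep(u[length(u)], k - 1 - length(br)))[seq_len(k - 1)])
  }
  if (length(x) > 2000) {     # subsample for tractability on big rasters
    x <- stats::quantile(x, probs = seq(0, 1, length.out = 2000),
                         names = FALSE, type = 1)
  }
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) {     # within-class sum of squared deviations
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- ssd(1, j)
  for (c_i in 2:k) {
    for (j in c_i:n) {
      for (i in c_i:j) {
        v <- cost[c_i - 1, i - 1] + ssd(i, j)
        if (v < cost[c_i, j]) { cost[c_i, j] <- v; back[c_i, j] <- i }
      }
    }
  }
  breaks <- numeric(k - 1)
  j <- n
  for (c_i in k:2) {
    i <- back[c_i, j]
    breaks[c_i - 1] <- x[i - 1]   # upper bound of the class below
    j <- i - 1
  }
  breaks
}

#' Grade a layer into resistance coefficients
#'
#' Categorical layers (MSPA raster, land cover) use exact code lookup;
#' continuous layers (elevation, slope) are classed by fixed bounds or
#' 5-class Jenks natural breaks and then mapped to the coefficient ladder.
#'
#' @param grid An `eco_grid` (or `mspa_raster` / `land_cover`).
#' @param table Named coefficient vector for categorical layers, where
#'   names follow [mspa_codes()] / [default_legend()] class names.
#' @param breaks,values For continuous layers: interior class bounds
#'   (right-open: `x < breaks[1]` is class 1) and the per-class
#'   coefficients (`length(values) == length(breaks) + 1`).
#' @param mode `"fixed_breaks"` or `"natural_breaks"` (continuous only).
#' @return An `eco_grid` of resistance coefficients.
#' @export
grade_layer <- function(grid, table = NULL, breaks = NULL, values = NULL,
                        mode = "fixed_breaks") {
  stopifnot(inherits(grid, "eco_grid"))
  v <- grid$values
  if (!is.null(table)) {
    code_of <- if (inherits(grid, "mspa_raster")) {
      mspa_codes()
    } else if (inherits(grid, "land_cover")) {
      grid$legend
    } else {
      abort_validation("categorical grading needs an mspa_raster or land_cover")
    }
    missing_nm <- setdiff(names(code_of), names(table))
    if (length(missing_nm)) {
      abort_validation(sprintf("coefficient table is missing classes: %s",
                               paste(missing_nm, collapse = ", ")))
    }
    lut <- rep(NA_real_, max(code_of) + 1L)
    lut[code_of + 1L] <- table[names(code_of)]
    codes_present <- unique(v[!is.na(v)])
    unknown <- setdiff(codes_present, code_of)
    if (length(unknown)) {
      abort_validation(sprintf("unknown category code(s): %s",
                               paste(unknown, collapse = ", ")))
    }
    out <- matrix(lut[v + 1L], nrow(v), ncol(v))
  } else {
    if (is.null(values)) abort_validation("continuous grading needs `values`")
    if (identical(mode, "natural_breaks")) {
      breaks <- jenks_breaks(as.vector(v), k = length(values))
      # degenerate data collapse to a single (lowest-coefficient) class
      cls <- findInterval(v, unique(breaks), left.open = TRUE) + 1L
      cls <- pmin(cls, length(values))
    } else {
      if (length(values) != length(breaks) + 1) {
        abort_validation("`values` must have one more entry than `breaks`")
      }
      cls <- findInterval(v, breaks) + 1L   # x < breaks[1] -> class 1
    }
    out <- matrix(values[cls], nrow(v), ncol(v))
    out[is.na(v)] <- NA
  }
  eco_grid(out, cell_size = grid$cell_size, origin = grid$origin,
           crs_tag = grid$crs_tag)
}

#' Compose the comprehensive resistance surface
#'
#' Weighted-sum overlay of the four graded layers, clamped to [1, 100].
#'
#' @param layers Named list of graded `eco_grid`s (names matching
#'   `weights`).
#' @param weights Named positive weights summing to 1.
#' @return A `resistance_surface` (an `eco_grid` with a provenance field).
#' @export
compose_resistance <- function(layers, weights) {
  if (is.null(names(layers)) || !setequal(names(layers), names(weights))) {
    abort_validation("`layers` and `weights` must share names")
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-6) {
    abort_validation("weights must be positive and sum to 1")
  }
  layers <- align_stack(layers)
  acc <- 0
  for (nm in names(weights)) acc <- acc + weights[[nm]] * layers[[nm]]$values
  acc <- pmin(pmax(acc, 1), 100)
  ref <- layers[[1]]
  g <- eco_grid(acc, cell_size = ref$cell_size, origin = ref$origin,
                crs_tag = ref$crs_tag)
  g$provenance <- list(layers = names(weights), weights = weights)
  class(g) <- c("resistance_surface", class(g))
  g
}

#' Build the resistance surface from the standard four layers
#'
#' Grades the MSPA raster, land cover, elevation and slope with a
#' [resistance_config()] and composes them.
#'
#' @param mspa An `mspa_raster`.
#' @param landcover A `land_cover`.
#' @param dem,slope Continuous `eco_grid`s (m, degrees).
#' @param config A [resistance_config()].
#' @return A `resistance_surface`.
#' @export
build_resistance <- function(mspa, landcover, dem, slope,
                             config = resistance_config()) {
  stopifnot(inherits(config, "resistance_config"))
  graded <- list(
    mspa = grade_layer(mspa, table = config$mspa),
    landcover = grade_layer(landcover, table = config$landcover),
    elevation = grade_layer(dem, breaks = config$elevation_breaks,
                            values = config$elevation_values,
                            mode = config$terrain_mode),
    slope = grade_layer(slope, breaks = config$slope_breaks,
                        values = config$slope_values,
                        mode = config$terrain_mode))
  compose_resistance(graded, config$weights)
}
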