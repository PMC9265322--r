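#' Specification of a synthetic landscape
#'
#' Describes the seeded demonstration landscape used throughout the package:
#' a west-high / east-low terrain with fractal relief, autocorrelated
#' multi-class land cover conditioned on that terrain, a long narrow river
#' corridor flanked by bottomland, a central construction-land block, and an
#' optional multi-date sequence generated by known class-transition
#' probabilities. Every generator is a pure function of the spec (including
#' its seed).
#'
#' @param shape `(rows, cols)` of the grid; at least 8 x 8.
#' @param cell_size Cell side in metres.
#' @param class_proportions Named fractions (legend class names) summing
#'   to 1.
#' @param autocorrelation_range Gaussian smoothing sigma, in cells, of the
#'   random field that drives land-cover patchiness.
#' @param dem_roughness Persistence of the midpoint-displacement relief, in
#'   (0, 1); 0 is the pure linear west-east trend.
#' @param dem_relief Amplitude (m) of the fractal relief.
#' @param trend_height Elevation drop (m) from the west to the east edge.
#' @param base_elevation Elevation (m) of the east edge.
#' @param river `NULL`, or a list with `row_start`, `row_end` (fractions of
#'   the grid height where the river crosses the west and east edges) and
#'   `width_cells`; the river is overwritten as water with one cell of
#'   flanking bottomland.
#' @param urban_core `NULL`, or a list with `centre` (row/col fractions) and
#'   `radius_cells`; overwritten as construction land.
#' @param n_dates Number of land-cover dates to generate.
#' @param transition_matrix Row-stochastic class-by-class matrix (legend
#'   order) applied per step of the sequence.
#' @param contiguity_lambda Weight in [0, 1] of neighbourhood affinity when
#'   choosing *which* cells of a class realise each sampled transition;
#'   0 gives salt-and-pepper change, 1 maximally patchy change. The sampled
#'   transition frequencies themselves always follow `transition_matrix`.
#' @param seed Integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(shape = c(150L, 150L),
                       cell_size = 600,
                       class_proportions = c(paddy_field = 0.12, dry_land = 0.35,
                                             woodland = 0.10, grassland = 0.08,
                                             water_area = 0.04, bottomland = 0.03,
                                             construction_land = 0.22,
                                             unutilized_land = 0.06),
                       autocorrelation_range = 1.5,
                       dem_roughness = 0.6,
                       dem_relief = 120,
                       trend_height = 900,
                       base_elevation = 80,
                       river = list(row_start = 0.40, row_end = 0.55,
                                    width_cells = 2L),
                       urban_core = list(centre = c(0.60, 0.55),
                                         radius_cells = 18L),
                       n_dates = 1L,
                       transition_matrix = NULL,
                       contiguity_lambda = 0.5,
                       seed = 42L) {
  if (length(shape) != 2 || any(shape < 8)) {
    abort_validation("`shape` must be (rows, cols), each >= 8")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort_validation("`class_proportions` must sum to 1")
  }
  if (dem_roughness < 0 || dem_roughness >= 1) {
    abort_validation("`dem_roughness` must lie in [0, 1)")
  }
  if (!is.null(transition_matrix)) validate_stochastic(transition_matrix)
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 class_proportions = class_proportions,
                 autocorrelation_range = autocorrelation_range,
                 dem_roughness = dem_roughness, dem_relief = dem_relief,
                 trend_height = trend_height, base_elevation = base_elevation,
                 river = river, urban_core = urban_core,
                 n_dates = as.integer(n_dates),
                 transition_matrix = transition_matrix,
                 contiguity_lambda = contiguity_lambda,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

validate_stochastic <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9)) {
    abort_validation("`transition_matrix` must be a square row-stochastic matrix")
  }
  invisible(P)
}

#' Generate a synthetic elevation model
#'
#' Midpoint displacement (diamond--square) relief superimposed on a
#' deterministic west-high / east-low linear trend. At `dem_roughness = 0`
#' the surface is exactly the trend.
#'
#' @param spec A [synth_spec()].
#' @return A continuous `eco_grid` of elevations in metres.
#' @export
make_dem <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  withr_seed(spec$seed + 101L, {
    n <- 2^ceiling(log2(max(nr, nc) - 1)) + 1
    z <- matrix(0, n, n)
    step <- n - 1
    scale <- spec$dem_relief * spec$dem_roughness
    while (step > 1) {
      half <- step / 2
      # diamond step
      for (r in seq(half + 1, n - half, by = step)) {
        for (cc in seq(half + 1, n - half, by = step)) {
          z[r, cc] <- mean(c(z[r - half, cc - half], z[r - half, cc + half],
                             z[r + half, cc - half], z[r + half, cc + half])) +
            stats::runif(1, -scale, scale)
        }
      }
      # square step
      for (r in seq(1, n, by = half)) {
        off <- if (((r - 1) / half) %% 2 == 0) half + 1 else 1
        for (cc in seq(off, n, by = step)) {
          nb <- c(if (r - half >= 1) z[r - half, cc],
                  if (r + half <= n) z[r + half, cc],
                  if (cc - half >= 1) z[r, cc - half],
                  if (cc + half <= n) z[r, cc + half])
          z[r, cc] <- mean(nb) + stats::runif(1, -scale, scale)
        }
      }
      step <- half
      scale <- scale * spec$dem_roughness
    }
    z <- z[seq_len(nr), seq_len(nc), drop = FALSE]
    trend <- matrix(rep(spec$base_elevation +
                          spec$trend_height * (nc - seq_len(nc)) / (nc - 1),
                        each = nr), nr, nc)
    eco_grid(trend + z, cell_size = spec$cell_size)
  })
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Slope (degrees) from an elevation grid
#'
#' Central-difference gradient magnitude converted to degrees; edges use
#' one-sided differences.
#'
#' @param dem A continuous `eco_grid` of elevations (m).
#' @return An `eco_grid` of slopes in degrees.
#' @export
slope_from_dem <- function(dem) {
  z <- dem$values
  h <- dem$cell_size
  dzdx <- (shift_mat(z, 0, 1, NA) - shift_mat(z, 0, -1, NA)) / (2 * h)
  dzdy <- (shift_mat(z, 1, 0, NA) - shift_mat(z, -1, 0, NA)) / (2 * h)
  # one-sided at borders
  fix <- function(g, fwd, bwd) { g[is.na(g)] <- ((fwd - bwd) / h)[is.na(g)]; g }
  dzdx <- fix(dzdx, shift_mat(z, 0, 1, z[, ncol(z)]), shift_mat(z, 0, -1, z[, 1]))
  dzdy <- fix(dzdy, shift_mat(z, 1, 0, z[nrow(z), ]), shift_mat(z, -1, 0, z[1, ]))
  eco_grid(atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi, cell_size = dem$cell_size,
           origin = dem$origin, crs_tag = dem$crs_tag)
}

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {
    xp <- c(rep(x[1], hw), x, rep(x[length(x)], hw))
    stats::convolve(xp, rev(k), type = "filter")
  }
  m2 <- t(apply(m, 1, pad_conv))
  apply(m2, 2, pad_conv)
}

#' Generate synthetic land cover conditioned on terrain
#'
#' Classes are assigned by thresholding a composite of a smoothed Gaussian
#' random field and the terrain rank, so woodland and grassland concentrate
#' on high ground and paddy fields on low flat ground, then the river
#' corridor (water + flanking bottomland) and urban core (construction) are
#' overwritten. Realised class fractions track `class_proportions` up to the
#' overwritten area.
#'
#' @param spec A [synth_spec()].
#' @param dem The matching elevation grid from [make_dem()].
#' @return A `land_cover` raster.
#' @export
make_landcover <- function(spec, dem) {
  stopifnot(inherits(spec, "synth_spec"), inherits(dem, "eco_grid"))
  if (!all(dim(dem$values) == spec$shape)) {
    abort_validation("`dem` shape does not match spec")
  }
  legend <- default_legend()
  props <- spec$class_proportions
  unknown <- setdiff(names(props), names(legend))
  if (length(unknown)) {
    abort_validation(sprintf("class_proportions has unknown classes: %s",
                             paste(unknown, collapse = ", ")))
  }
  nr <- spec$shape[1]; nc <- spec$shape[2]
  ncell <- nr * nc
  withr_seed(spec$seed + 202L, {
    grf <- gaussian_smooth(matrix(stats::rnorm(ncell), nr, nc),
                           spec$autocorrelation_range)
    # composite rank: high = high ground + high field
    comp <- 0.5 * rank(grf, ties.method = "first") / ncell +
      0.5 * rank(dem$values, ties.method = "first") / ncell
    # low -> high composite; terrain-loving classes at the top
    order_names <- c("paddy_field", "water_area", "bottomland", "dry_land",
                     "construction_land", "unutilized_land", "grassland",
                     "woodland")
    order_names <- order_names[order_names %in% names(props)]
    cum <- cumsum(props[order_names])
    qs <- stats::quantile(comp, probs = pmin(cum, 1), names = FALSE,
                          type = 1)
    cls <- matrix(legend[[order_names[length(order_names)]]], nr, nc)
    for (i in rev(seq_along(order_names))) {
      cls[comp <= qs[i]] <- legend[[order_names[i]]]
    }
    # river corridor: water with one flanking cell of bottomland
    if (!is.null(spec$river)) {
      rows <- round(spec$river$row_start * nr +
                      (spec$river$row_end - spec$river$row_start) * nr *
                      (seq_len(nc) - 1) / (nc - 1))
      rows <- pmin(pmax(rows, 1), nr)
      riv <- matrix(FALSE, nr, nc)
      w <- spec$river$width_cells
      for (j in seq_len(nc)) {
        rr <- (rows[j] - (w - 1)):(rows[j] + (w - 1))
        riv[rr[rr >= 1 & rr <= nr], j] <- TRUE
      }
      bank <- dilate_mask(riv, 1L) & !riv
      cls[bank] <- legend[["bottomland"]]
      cls[riv] <- legend[["water_area"]]
    }
    if (!is.null(spec$urban_core) && spec$urban_core$radius_cells > 0) {
      ctr <- spec$urban_core$centre * c(nr, nc)
      rr <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      disc <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <=
        spec$urban_core$radius_cells^2
      cls[disc] <- legend[["construction_land"]]
    }
    land_cover(eco_grid(cls, cell_size = spec$cell_size), legend)
  })
}

# chebyshev dilation of a logical mask by `k` cells
dilate_mask <- function(mask, k) {
  out <- mask
  off <- d8_offsets()
  for (i in seq_len(k)) {
    acc <- out
    for (d in seq_len(8)) {
      acc <- acc | shift_mat(out, off$dr[d], off$dc[d], FALSE)
    }
    out <- acc
  }
  out
}

#' Generate a multi-date land-cover series with known transitions
#'
#' Date 1 comes from [make_landcover()]; each later date applies the
#' row-stochastic `transition_matrix` per cell. The number of cells sampled
#' for each class-to-class move follows the matrix exactly (multinomial), so
#' estimated transition frequencies converge to the matrix; the
#' `contiguity_lambda` weight only chooses *which* cells move, preferring
#' cells whose 8-neighbourhood already holds the target class, which keeps
#' change patchy rather than salt-and-pepper.
#'
#' @param spec A [synth_spec()] with `n_dates >= 2` and a `transition_matrix`.
#' @return List of `land_cover` rasters, one per date.
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_dates < 2) abort_validation("`n_dates` must be >= 2 for a series")
  if (is.null(spec$transition_matrix)) {
    abort_validation("`transition_matrix` is required for a series")
  }
  P <- validate_stochastic(spec$transition_matrix)
  legend <- default_legend()
  if (nrow(P) != length(legend)) {
    abort_validation("`transition_matrix` must be 8 x 8 (legend order)")
  }
  dem <- make_dem(spec)
  lc <- make_landcover(spec, dem)
  out <- vector("list", spec$n_dates)
  out[[1]] <- lc
  withr_seed(spec$seed + 303L, {
    for (t in seq_len(spec$n_dates - 1L)) {
      out[[t + 1]] <- transition_step(out[[t]], P, spec$contiguity_lambda)
    }
  })
  out
}

transition_step <- function(lc, P, lambda) {
  v <- lc$values
  K <- nrow(P)
  off <- d8_offsets()
  # neighbourhood fraction of each class, from the current date
  neigh <- lapply(seq_len(K), function(k) {
    acc <- matrix(0, nrow(v), ncol(v))
    cnt <- matrix(0, nrow(v), ncol(v))
    for (d in seq_len(8)) {
      s <- shift_mat(v, off$dr[d], off$dc[d], NA)
      acc <- acc + (!is.na(s) & s == k)
      cnt <- cnt + !is.na(s)
    }
    acc / pmax(cnt, 1)
  })
  new <- v
  for (c_from in seq_len(K)) {
    idx <- which(!is.na(v) & v == c_from)
    n <- length(idx)
    if (n == 0) next
    counts <- as.vector(stats::rmultinom(1, n, P[c_from, ]))
    if (counts[c_from] == n) next
    # preference for each target class: contiguity + noise
    score <- vapply(seq_len(K), function(k) {
      lambda * neigh[[k]][idx] + (1 - lambda) * stats::runif(n)
    }, numeric(n))
    score <- matrix(score, nrow = n)
    assigned <- rep(NA_integer_, n)
    # allocate rarer target classes first so their preferred cells are free
    for (k in order(counts)) {
      if (counts[k] == 0) next
      free <- which(is.na(assigned))
      pick <- free[order(score[free, k], decreasing = TRUE)[seq_len(counts[k])]]
      assigned[pick] <- k
    }
    new[idx] <- assigned
  }
  res <- lc
  res$values <- new
  res
}

#' Bundle of synthetic demonstration layers
#'
#' Convenience wrapper generating the DEM, slope and land-cover date(s) of a
#' spec in one call.
#'
#' @param spec A [synth_spec()].
#' @return List with elements `spec`, `dem`, `slope` and `landcover` (a list
#'   of dates).
#' @export
make_demo_landscape <- function(spec = synth_spec()) {
  dem <- make_dem(spec)
  lcs <- if (spec$n_dates >= 2 && !is.null(spec$transition_matrix)) {
    make_series(spec)
  } else {
    list(make_landcover(spec, dem))
  }
  list(spec = spec, dem = dem, slope = slope_from_dem(dem), landcover = lcs)
}
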