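#' Default land-cover legend
#'
#' The eight-class legend used throughout the pipeline: paddy field, dry
#' land, woodland, grassland, water area, bottomland, construction land and
#' unutilized land, coded 1--8.
#'
#' @return Named integer vector mapping class name to code.
#' @export
default_legend <- function() {
  c(paddy_field = 1L, dry_land = 2L, woodland = 3L, grassland = 4L,
    water_area = 5L, bottomland = 6L, construction_land = 7L,
    unutilized_land = 8L)
}

#' Create a categorical land-cover raster
#'
#' @param grid An `eco_grid` whose non-`NA` cells are integer class codes.
#' @param legend Named integer vector (name -> code); defaults to the
#'   eight-class legend of [default_legend()]. User-extensible.
#' @return A `land_cover` object (an `eco_grid` with a legend).
#' @export
land_cover <- function(grid, legend = default_legend()) {
  stopifnot(inherits(grid, "eco_grid"))
  v <- grid$values
  if (any(abs(v - round(v)) > 1e-9, na.rm = TRUE)) {
    abort_validation("land-cover grid contains fractional values")
  }
  codes <- sort(unique(as.vector(v[!is.na(v)])))
  unknown <- setdiff(codes, legend)
  if (length(unknown)) {
    abort_validation(sprintf("land-cover codes not in legend: %s",
                             paste(unknown, collapse = ", ")))
  }
  grid$legend <- legend
  class(grid) <- c("land_cover", class(grid))
  grid
}

#' @export
print.land_cover <- function(x, ...) {
  NextMethod()
  tab <- class_counts(x)
  cat("  classes: ", paste(sprintf("%s=%d", tab$class, tab$cells),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-class cell counts of a land-cover raster
#'
#' @param lc A `land_cover`.
#' @return Tibble with `class`, `code`, `cells` and `fraction` columns, one
#'   row per legend class (zero-count classes included).
#' @export
class_counts <- function(lc) {
  stopifnot(inherits(lc, "land_cover"))
  v <- lc$values[!is.na(lc$values)]
  n <- vapply(lc$legend, function(code) sum(v == code), integer(1))
  tibble::tibble(class = names(lc$legend), code = unname(lc$legend),
                 cells = unname(n),
                 fraction = if (length(v)) unname(n) / length(v) else 0)
}
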