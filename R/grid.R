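#' Create a regular raster grid
#'
#' `eco_grid` is the substrate every pipeline stage operates on: a plain
#' numeric matrix plus the minimal georeferencing needed to keep layers
#' aligned and to export cell coordinates. Row 1 is the northmost row and the
#' origin is the *outer* corner of the top-left cell, so the centre of cell
#' (r, c) lies at `origin + cell_size * (c - 0.5, -(r - 0.5))`.
#'
#' Nodata cells are held as `NA` internally; the `nodata` sentinel is only
#' used when reading and writing files, so missing cells can never leak into
#' arithmetic.
#'
#' @param values Numeric matrix (row 1 = north). `NA` marks nodata.
#' @param cell_size Cell side length in metres (> 0).
#' @param origin Length-2 numeric `(x, y)` of the outer corner of the
#'   top-left cell.
#' @param nodata Sentinel written to file for `NA` cells.
#' @param crs_tag Free-text coordinate-system label, kept as metadata only.
#' @return An object of class `eco_grid`.
#' @export
eco_grid <- function(values, cell_size, origin = c(0, 0), nodata = -9999,
                     crs_tag = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort_validation("`cell_size` must be a single positive number")
  }
  if (length(origin) != 2 || !is.numeric(origin)) {
    abort_validation("`origin` must be a numeric (x, y) pair")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata),
         crs_tag = as.character(crs_tag)),
    class = "eco_grid"
  )
}

abort_validation <- function(msg) rlang::abort(msg, class = "econetr_validation_error")
abort_format    <- function(msg) rlang::abort(msg, class = "econetr_format_error")
abort_alignment <- function(msg) rlang::abort(msg, class = "econetr_alignment_error")

#' @export
dim.eco_grid <- function(x) dim(x$values)

#' @export
print.eco_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<eco_grid> %d x %d cells, cell size %g m, origin (%g, %g)%s\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2],
              if (nzchar(x$crs_tag)) paste0(" [", x$crs_tag, "]") else ""))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: min %g, max %g, nodata cells %d\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' Coordinates of cell centres
#'
#' @param grid An `eco_grid`.
#' @param rows,cols Integer vectors of 1-based row/column indices.
#' @return Two-column matrix of x/y centre coordinates.
#' @export
cell_xy <- function(grid, rows, cols) {
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
        y = grid$origin[2] - (rows - 0.5) * grid$cell_size)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.eco_grid <- function(x, ...) {
  d <- dim(x$values)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  xy <- cell_xy(x, rows, cols)
  vals <- as.vector(x$values)
  tibble::tibble(row = rows, col = cols, x = unname(xy[, 1]),
                 y = unname(xy[, 2]), value = vals)
}

same_geometry <- function(a, b, tol = 0.5) {
  all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    all(abs(a$origin - b$origin) <= tol * a$cell_size)
}

#' Align a stack of raster layers
#'
#' Verifies that every layer shares the shape and cell size of the first and
#' that origins agree to within half a cell; small origin offsets (from
#' export rounding) are snapped to the first layer's origin. Larger
#' disagreements are an error naming the offending layer -- the pipeline
#' never resamples silently.
#'
#' @param layers A (optionally named) list of `eco_grid` objects.
#' @return The list with all origins snapped to the first layer's.
#' @export
align_stack <- function(layers) {
  if (!is.list(layers) || length(layers) < 1) {
    abort_validation("`layers` must be a non-empty list of eco_grid objects")
  }
  nm <- names(layers)
  if (is.null(nm)) nm <- paste0("layer_", seq_along(layers))
  nm[!nzchar(nm)] <- paste0("layer_", which(!nzchar(nm)))
  ref <- layers[[1]]
  out <- lapply(seq_along(layers), function(i) {
    g <- layers[[i]]
    if (!inherits(g, "eco_grid")) {
      abort_alignment(sprintf("layer '%s' is not an eco_grid", nm[i]))
    }
    if (!all(dim(g$values) == dim(ref$values))) {
      abort_alignment(sprintf(
        "layer '%s' has shape %dx%d, expected %dx%d", nm[i],
        nrow(g$values), ncol(g$values), nrow(ref$values), ncol(ref$values)))
    }
    if (!isTRUE(all.equal(g$cell_size, ref$cell_size))) {
      abort_alignment(sprintf("layer '%s' has cell size %g, expected %g",
                              nm[i], g$cell_size, ref$cell_size))
    }
    if (any(abs(g$origin - ref$origin) > 0.5 * ref$cell_size)) {
      abort_alignment(sprintf(
        "layer '%s' origin (%g, %g) is more than half a cell from (%g, %g)",
        nm[i], g$origin[1], g$origin[2], ref$origin[1], ref$origin[2]))
    }
    g$origin <- ref$origin
    g
  })
  names(out) <- nm
  out
}

#' Read an Esri ASCII grid
#'
#' @param path Path to an `.asc` file. GeoTIFF input is not supported by this
#'   build; convert to ASCII grid first.
#' @param expected_kind `"continuous"` or `"categorical"`; categorical reads
#'   reject fractional cell values.
#' @return An `eco_grid`.
#' @export
read_raster <- function(path, expected_kind = c("continuous", "categorical")) {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path)) abort_format(sprintf("file '%s' does not exist", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    abort_format("GeoTIFF input is not supported; supply an Esri ASCII grid (.asc)")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort_format(sprintf("'%s' is not an Esri ASCII grid (missing %s header)",
                         path, paste(setdiff(need, names(hdr)), collapse = ", ")))
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  # corner vs centre registration
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner; yll <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - hdr$cellsize / 2
    yll <- hdr$yllcenter - hdr$cellsize / 2
  } else {
    xll <- 0; yll <- 0
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrows * ncols) {
    abort_format(sprintf("'%s': expected %d values, found %d",
                         path, nrows * ncols, length(vals)))
  }
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (expected_kind == "categorical" &&
      any(abs(m - round(m)) > 1e-9, na.rm = TRUE)) {
    abort_validation(sprintf("'%s' read as categorical but contains fractional values", path))
  }
  eco_grid(m, cell_size = hdr$cellsize,
           origin = c(xll, yll + nrows * hdr$cellsize), nodata = nodata)
}

#' Write an Esri ASCII grid
#'
#' @param grid An `eco_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "eco_grid"))
  d <- dim(grid$values)
  yll <- grid$origin[2] - d[1] * grid$cell_size
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# shifted[i, j] = m[i + dr, j + dc]; out-of-range cells get `fill`.
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  ok_r <- ri >= 1 & ri <= nr
  ok_c <- ci >= 1 & ci <= nc
  out[which(ok_r), which(ok_c)] <- m[ri[ok_r], ci[ok_c], drop = FALSE]
  out
}

# The 8 D8 neighbour offsets in fixed priority order E, SE, S, SW, W, NW, N, NE
d8_offsets <- function() {
  list(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
       dc = c(1, 1, 0, -1, -1, -1, 0, 1),
       len = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))
}
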