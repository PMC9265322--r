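#' MSPA class codes
#'
#' Codes used in the classified raster: 0 background, 1 core, 2 islet,
#' 3 edge, 4 bridge, 5 branch, 6 loop, 7 perforation.
#'
#' @return Named integer vector.
#' @export
mspa_codes <- function() {
  c(background = 0L, core = 1L, islet = 2L, edge = 3L, bridge = 4L,
    branch = 5L, loop = 6L, perforation = 7L)
}

#' Binarise a land-cover raster into foreground/background
#'
#' @param lc A `land_cover`.
#' @param foreground_classes Codes counted as habitat foreground.
#' @return An `eco_grid` of 0/1 (NA preserved).
#' @export
binarize <- function(lc, foreground_classes) {
  stopifnot(inherits(lc, "land_cover"))
  if (length(foreground_classes) == 0) {
    abort_validation("`foreground_classes` must not be empty")
  }
  v <- lc$values
  b <- ifelse(is.na(v), NA_real_, as.numeric(v %in% foreground_classes))
  out <- eco_grid(matrix(b, nrow(v), ncol(v)), cell_size = lc$cell_size,
                  origin = lc$origin, crs_tag = lc$crs_tag)
  out
}

#' Morphological spatial pattern analysis
#'
#' Segments a binary landscape into the seven morphological foreground
#' classes -- core, islet, edge, perforation, bridge, loop, branch -- using
#' the chamfer (8-neighbourhood) distance for erosion. The decision
#' sequence:
#'
#' 1. *Core*: foreground cells farther than `edge_width_cells` (Chebyshev)
#'    from any background cell; the area beyond the map edge counts as
#'    background.
#' 2. Foreground components (at `connectivity`) containing no core cell are
#'    *islet* in their entirety.
#' 3. Non-core cells of core-bearing components within `edge_width_cells` of
#'    core form the boundary zone: *edge* where the nearest-zone background
#'    is connected to the outside, *perforation* where it is an enclosed
#'    hole (edge takes priority when both are in reach).
#' 4. The remaining connector components are *bridge* when they contact two
#'    or more distinct core components, *loop* when they contact the same
#'    core component at two or more disjoint contact zones, *branch* when
#'    they contact exactly one core once, and *islet* when they contact
#'    none. A connector contacts a core of its own foreground component
#'    when it comes within `edge_width_cells + 1` (Chebyshev) of it.
#'
#' @param landscape A binary `eco_grid` (0/1/NA), e.g. from [binarize()].
#' @param edge_width_cells Positive integer structuring-element radius.
#' @param connectivity Foreground connectivity, 4 or 8 (default 8).
#' @return An `mspa_raster`: an `eco_grid` of class codes (see
#'   [mspa_codes()]) with attributes `edge_width_cells` and `connectivity`.
#' @export
mspa_classify <- function(landscape, edge_width_cells = 1L,
                          connectivity = 8L) {
  stopifnot(inherits(landscape, "eco_grid"))
  if (edge_width_cells < 1) abort_validation("`edge_width_cells` must be >= 1")
  if (!connectivity %in% c(4L, 8L)) abort_validation("`connectivity` must be 4 or 8")
  v <- landscape$values
  if (!all(v %in% c(0, 1) | is.na(v))) {
    abort_validation("binary landscape may only contain 0, 1 and NA")
  }
  fg <- !is.na(v) & v == 1
  bg <- !is.na(v) & v == 0   # NA cells treated as background for morphology
  bg_or_na <- !fg
  w <- as.integer(edge_width_cells)
  codes <- mspa_codes()
  out <- matrix(codes[["background"]], nrow(v), ncol(v))

  if (any(fg)) {
    d_bg <- chebyshev_dist(bg_or_na, outside = TRUE, max_dist = w + 1)
    core <- fg & d_bg > w
    comp <- label_components(fg, connectivity)
    core_comps <- unique(comp[core])
    in_core_comp <- comp > 0 & comp %in% core_comps
    out[fg & !in_core_comp] <- codes[["islet"]]
    out[core] <- codes[["core"]]

    rest <- fg & in_core_comp & !core
    if (any(rest)) {
      d_core <- chebyshev_dist(core, max_dist = w + 1)
      zone <- rest & d_core <= w
      if (any(zone)) {
        # split background into outside-connected vs enclosed holes, using
        # the complementary connectivity
        bg_conn <- if (connectivity == 8L) 4L else 8L
        bg_lab <- label_components(bg_or_na, bg_conn)
        border <- matrix(FALSE, nrow(v), ncol(v))
        border[1, ] <- TRUE; border[nrow(v), ] <- TRUE
        border[, 1] <- TRUE; border[, ncol(v)] <- TRUE
        outside_ids <- unique(bg_lab[border & bg_or_na])
        outside_bg <- bg_lab > 0 & bg_lab %in% outside_ids
        hole_bg <- bg_or_na & !outside_bg
        d_out <- chebyshev_dist(outside_bg, outside = TRUE, max_dist = w + 1)
        out[zone] <- ifelse(d_out[zone] <= w, codes[["edge"]],
                            codes[["perforation"]])
      }
      conn_mask <- rest & !zone
      if (any(conn_mask)) {
        core_lab <- label_components(core, 8L)
        conn_lab <- label_components(conn_mask, connectivity)
        n_core <- max(core_lab)
        # distance field from each core component (small counts in practice)
        d_core_k <- lapply(seq_len(n_core), function(k) {
          chebyshev_dist(core_lab == k, max_dist = w + 2)
        })
        for (cid in seq_len(max(conn_lab))) {
          cells <- conn_lab == cid
          own_comp <- comp[which(cells)[1]]
          touched <- integer(0)
          zones_of <- list()
          for (k in seq_len(n_core)) {
            if (comp[which(core_lab == k)[1]] != own_comp) next
            contact <- cells & d_core_k[[k]] <= w + 1
            if (any(contact)) {
              touched <- c(touched, k)
              zones_of[[length(zones_of) + 1]] <- contact
            }
          }
          cls <- if (length(touched) >= 2) {
            codes[["bridge"]]
          } else if (length(touched) == 1) {
            nz <- max(label_components(zones_of[[1]], 8L))
            if (nz >= 2) codes[["loop"]] else codes[["branch"]]
          } else {
            codes[["islet"]]
          }
          out[cells] <- cls
        }
      }
    }
  }
  out[is.na(v)] <- NA
  g <- eco_grid(out, cell_size = landscape$cell_size,
                origin = landscape$origin, crs_tag = landscape$crs_tag)
  g$edge_width_cells <- w
  g$connectivity <- as.integer(connectivity)
  class(g) <- c("mspa_raster", class(g))
  g
}

#' Class-area summary of an MSPA raster
#'
#' @param mspa An `mspa_raster`.
#' @return Tibble of `class`, `code`, `cells`, `area_km2`, `fraction_fg`
#'   (fraction of the foreground), one row per MSPA class.
#' @export
mspa_summary <- function(mspa) {
  stopifnot(inherits(mspa, "mspa_raster"))
  codes <- mspa_codes()
  v <- mspa$values
  n <- vapply(codes, function(k) sum(v == k, na.rm = TRUE), numeric(1))
  fg <- sum(n[names(codes) != "background"])
  tibble::tibble(class = names(codes), code = unname(codes),
                 cells = as.integer(unname(n)),
                 area_km2 = unname(n) * (mspa$cell_size / 1000)^2,
                 fraction_fg = ifelse(names(codes) == "background", NA,
                                      if (fg > 0) unname(n) / fg else 0))
}

#' Extract core patches as candidate ecological sources
#'
#' Labels core cells into 8-connected components and drops components
#' smaller than `min_area_cells`.
#'
#' @param mspa An `mspa_raster`.
#' @param min_area_cells Minimum component size retained, in cells.
#' @return A `patch_set`: a list with a `patches` tibble (`id`,
#'   `area_cells`, `area_km2`, `centroid_x`, `centroid_y`), a parallel list
#'   `cells` of linear cell indices, and the grid geometry.
#' @export
extract_cores <- function(mspa, min_area_cells = 1L) {
  stopifnot(inherits(mspa, "mspa_raster"))
  core <- !is.na(mspa$values) & mspa$values == mspa_codes()[["core"]]
  lab <- label_components(core, 8L)
  patch_set_from_labels(lab, mspa, min_area_cells)
}

patch_set_from_labels <- function(lab, grid, min_area_cells = 1L) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  cells <- lapply(ids, function(k) which(lab == k))
  keep <- vapply(cells, length, integer(1)) >= min_area_cells
  cells <- cells[keep]
  nr <- nrow(lab)
  cell_area_km2 <- (grid$cell_size / 1000)^2
  rows <- lapply(cells, function(ix) ((ix - 1) %% nr) + 1)
  cols <- lapply(cells, function(ix) ((ix - 1) %/% nr) + 1)
  cent <- t(vapply(seq_along(cells), function(i) {
    colMeans(cell_xy(grid, rows[[i]], cols[[i]]))
  }, numeric(2)))
  patches <- tibble::tibble(
    id = seq_along(cells),
    area_cells = vapply(cells, length, integer(1)),
    area_km2 = vapply(cells, length, integer(1)) * cell_area_km2,
    centroid_x = if (length(cells)) cent[, 1] else numeric(0),
    centroid_y = if (length(cells)) cent[, 2] else numeric(0))
  structure(list(patches = patches, cells = cells,
                 dim = dim(lab), cell_size = grid$cell_size,
                 origin = grid$origin),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, %.4g km2 total\n",
              nrow(x$patches), sum(x$patches$area_km2)))
  print(x$patches)
  invisible(x)
}
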