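#' Fill sinks of a surface (priority-flood style)
#'
#' Minimally raises cells so that every interior cell has a strictly
#' descending 8-neighbour path to the map boundary. A tiny epsilon gradient
#' is imposed on filled flats so that D8 directions are defined everywhere;
#' the operation is exactly idempotent.
#'
#' @param surface A finite `eco_grid`.
#' @param eps Minimal drop imposed per step across filled areas.
#' @return The filled `eco_grid`.
#' @export
fill_sinks <- function(surface, eps = 1e-6) {
  z <- surface$values
  if (any(!is.finite(z))) abort_validation("surface must be finite everywhere")
  nr <- nrow(z); nc <- ncol(z)
  fill <- matrix(Inf, nr, nc)
  border <- matrix(FALSE, nr, nc)
  border[1, ] <- TRUE; border[nr, ] <- TRUE; border[, 1] <- TRUE; border[, nc] <- TRUE
  fill[border] <- z[border]
  off <- d8_offsets()
  repeat {
    lowest <- matrix(Inf, nr, nc)
    for (d in seq_len(8)) {
      nb <- shift_mat(fill, off$dr[d], off$dc[d], Inf)
      lowest <- pmin(lowest, nb + eps)
    }
    cand <- pmax(z, lowest)
    cand[border] <- z[border]
    newfill <- pmin(fill, cand)
    if (identical(newfill, fill)) break
    fill <- newfill
  }
  out <- surface
  out$values <- fill
  out
}

#' D8 flow direction and accumulation
#'
#' Direction is the steepest descent among the 8 neighbours (drop divided
#' by step length, sqrt(2) on diagonals), with ties broken by the fixed
#' priority E, SE, S, SW, W, NW, N, NE. Cells with no lower neighbour are
#' outlets (direction 0). Accumulation counts the cells draining through
#' each cell, routed in decreasing-elevation order.
#'
#' @param surface A filled `eco_grid` (see [fill_sinks()]).
#' @return A `flow_field`: list of `flow_direction` (codes 0--8) and
#'   `flow_accumulation` `eco_grid`s plus the `filled_surface`.
#' @export
d8_flow <- function(surface) {
  z <- surface$values
  nr <- nrow(z); nc <- ncol(z)
  off <- d8_offsets()
  best <- matrix(0, nr, nc)           # best positive gradient so far
  dir <- matrix(0L, nr, nc)
  for (d in seq_len(8)) {
    nb <- shift_mat(z, off$dr[d], off$dc[d], NA)
    grad <- (z - nb) / off$len[d]
    better <- !is.na(grad) & grad > best
    best[better] <- grad[better]
    dir[better] <- d
  }
  acc <- matrix(0, nr, nc)
  ord <- order(z, decreasing = TRUE)
  rows <- ((ord - 1) %% nr) + 1
  cols <- ((ord - 1) %/% nr) + 1
  for (i in seq_along(ord)) {
    d <- dir[ord[i]]
    if (d == 0L) next
    r2 <- rows[i] + off$dr[d]; c2 <- cols[i] + off$dc[d]
    tgt <- (c2 - 1) * nr + r2
    acc[tgt] <- acc[tgt] + acc[ord[i]] + 1
  }
  mkg <- function(m) eco_grid(m, cell_size = surface$cell_size,
                              origin = surface$origin, crs_tag = surface$crs_tag)
  structure(list(flow_direction = mkg(dir), flow_accumulation = mkg(acc),
                 filled_surface = surface),
            class = "flow_field")
}

#' Valley and ridge cells of a surface
#'
#' Valleys are cells whose D8 flow accumulation on the (sink-filled)
#' surface reaches the `quantile` level; ridges are the same rule applied
#' to the negated surface.
#'
#' @param surface An `eco_grid`, typically a resistance surface.
#' @param quantile Accumulation quantile defining a line cell.
#' @return List of logical matrices `valleys` and `ridges` plus the two
#'   `flow_field`s.
#' @export
valleys_and_ridges <- function(surface, quantile = 0.95) {
  if (quantile <= 0 || quantile >= 1) {
    abort_validation("`quantile` must lie in (0, 1)")
  }
  fv <- d8_flow(fill_sinks(surface))
  neg <- surface
  neg$values <- -neg$values
  fr <- d8_flow(fill_sinks(neg))
  vacc <- fv$flow_accumulation$values
  racc <- fr$flow_accumulation$values
  list(valleys = vacc >= stats::quantile(vacc, quantile),
       ridges = racc >= stats::quantile(racc, quantile),
       valley_flow = fv, ridge_flow = fr)
}

# rasterize a list of cell-index vectors onto a logical matrix
cells_to_mask <- function(cells, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[unlist(cells)] <- TRUE
  m
}

# merge candidate cells into nodes: cluster cells within chebyshev
# `radius` of each other (union-find via graph components, order
# independent) and take each cluster's centroid
merge_node_cells <- function(cells_idx, dims, radius) {
  if (!length(cells_idx)) {
    return(tibble::tibble(row = numeric(0), col = numeric(0),
                          n_cells = integer(0)))
  }
  nr <- dims[1]
  rows <- ((cells_idx - 1) %% nr) + 1
  cols <- ((cells_idx - 1) %/% nr) + 1
  n <- length(cells_idx)
  dch <- pmax(abs(outer(rows, rows, "-")), abs(outer(cols, cols, "-")))
  adj <- dch <= radius
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  tibble::tibble(row = as.vector(tapply(rows, memb, mean)),
                 col = as.vector(tapply(cols, memb, mean)),
                 n_cells = as.integer(table(memb)))
}

#' Classify ecological nodes
#'
#' Three node families are extracted from intersections, each mask being
#' dilated by one cell before testing and the resulting cells merged into
#' single points within `merge_radius` cells:
#' * *strategic*: ridge cells crossing the maximum-cost corridor (or all
#'   corridors with `strategic_scope = "all"`);
#' * *natural*: cells where at least two corridors flagged as persistent
#'   across dates cross each other;
#' * *artificial*: valley cells crossing roads, rivers or paddy fields.
#'
#' Missing inputs (no persistent corridors, no road/river/paddy masks)
#' skip that family with a warning.
#'
#' @param ridges,valleys Logical matrices from [valleys_and_ridges()].
#' @param corridors A `corridor_set` from [classify_corridors()].
#' @param pathset The `cost_path_set` the corridors came from.
#' @param persistent_cells List of cell-index vectors, one per corridor
#'   persisting across all dates; defaults to every kept corridor.
#' @param masks Named list of logical matrices `roads`, `rivers`, `paddy`
#'   (any subset).
#' @param merge_radius Chebyshev merge radius in cells.
#' @param strategic_scope `"max_cost"` or `"all"`.
#' @return A `node_set` tibble: `node_id`, `node_type`, `row`, `col`, `x`,
#'   `y`, `n_cells`, `provenance`.
#' @export
classify_nodes <- function(ridges, valleys, corridors, pathset,
                           persistent_cells = NULL, masks = list(),
                           merge_radius = 3L,
                           strategic_scope = c("max_cost", "all")) {
  strategic_scope <- match.arg(strategic_scope)
  dims <- pathset$dim
  kept <- corridors[!is.na(corridors$level), ]
  path_cells <- function(src, dst) {
    for (p in pathset$paths) if (p$src == src && p$dst == dst) return(p$cells)
    integer(0)
  }
  corridor_cells <- lapply(seq_len(nrow(kept)), function(i) {
    path_cells(kept$src[i], kept$dst[i])
  })
  if (is.null(persistent_cells)) persistent_cells <- corridor_cells
  out <- list()

  # strategic: ridge x (max cost corridor)
  if (nrow(kept)) {
    scope <- if (strategic_scope == "max_cost") {
      corridor_cells[which.max(kept$cum_cost)]
    } else {
      corridor_cells
    }
    mask <- dilate_mask(cells_to_mask(scope, dims), 1L) &
      dilate_mask(ridges, 1L)
    out$strategic <- merge_node_cells(which(mask), dims, merge_radius) |>
      dplyr::mutate(node_type = "strategic",
                    provenance = "ridge x max-cost corridor")
  }

  # natural: crossings among persistent corridors
  if (length(persistent_cells) >= 2) {
    cover <- matrix(0L, dims[1], dims[2])
    for (cl in persistent_cells) {
      cover <- cover + dilate_mask(cells_to_mask(list(cl), dims), 1L)
    }
    mask <- cover >= 2
    out$natural <- merge_node_cells(which(mask), dims, merge_radius) |>
      dplyr::mutate(node_type = "natural",
                    provenance = "persistent corridor crossing")
  } else {
    warning("fewer than two persistent corridors; natural nodes skipped")
  }

  # artificial: valley x (roads | rivers | paddy)
  feat <- masks[names(masks) %in% c("roads", "rivers", "paddy")]
  if (length(feat)) {
    u <- Reduce(`|`, feat)
    mask <- dilate_mask(valleys, 1L) & dilate_mask(u, 1L)
    out$artificial <- merge_node_cells(which(mask), dims, merge_radius) |>
      dplyr::mutate(node_type = "artificial",
                    provenance = "valley x roads/rivers/paddy")
  } else {
    warning("no road/river/paddy masks supplied; artificial nodes skipped")
  }

  nodes <- dplyr::bind_rows(out)
  if (nrow(nodes) == 0) {
    nodes <- tibble::tibble(row = numeric(0), col = numeric(0),
                            n_cells = integer(0), node_type = character(0),
                            provenance = character(0))
  }
  xy <- cbind(pathset$origin[1] + (nodes$col - 0.5) * pathset$cell_size,
              pathset$origin[2] - (nodes$row - 0.5) * pathset$cell_size)
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  nodes <- dplyr::mutate(nodes, node_id = dplyr::row_number()) |>
    dplyr::relocate("node_id", "node_type", "row", "col", "x", "y")
  class(nodes) <- c("node_set", class(nodes))
  nodes
}
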