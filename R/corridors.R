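# 8-connected lattice graph over a resistance surface. Move cost between
# adjacent cells = mean of endpoint resistances x step length (1 or sqrt(2)
# cell units); geometric length is carried separately on each edge.
lattice_igraph <- function(surface) {
  v <- surface$values
  if (any(v <= 0, na.rm = TRUE)) {
    abort_validation("resistances must be strictly positive")
  }
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  vid <- integer(length(v))
  vid[ok] <- seq_len(sum(ok))
  off <- d8_offsets()
  from <- integer(0); to <- integer(0); wt <- numeric(0); len <- numeric(0)
  idx <- which(ok)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  for (d in 1:4) {        # E, SE, S, SW cover all undirected pairs
    r2 <- rows + off$dr[d]; c2 <- cols + off$dc[d]
    keep <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[keep] - 1) * nr + r2[keep]
    keep2 <- ok[nb]
    a <- idx[keep][keep2]; b <- nb[keep2]
    from <- c(from, vid[a]); to <- c(to, vid[b])
    wt <- c(wt, (v[a] + v[b]) / 2 * off$len[d])
    len <- c(len, rep(off$len[d], length(a)))
  }
  g <- igraph::make_empty_graph(n = sum(ok), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  igraph::E(g)$steplen <- len
  list(graph = g, vid = vid, cell_of = idx, nr = nr, nc = nc)
}

#' Cost distance from source cells over a resistance surface
#'
#' Exact (Dijkstra) accumulated cost over the 8-connected cell graph, with
#' move cost between adjacent cells equal to the mean of their resistances
#' times the step length (1 or sqrt(2) cell units). With several sources the
#' field is the pointwise minimum over them.
#'
#' @param surface A `resistance_surface` (or any positive `eco_grid`).
#' @param sources List of integer vectors of linear cell indices (or a
#'   `patch_set`, whose patches are pooled).
#' @return A `cost_field`: list of `cumulative_cost` and `backlink`
#'   `eco_grid`s. Backlink codes are 0 on source cells and otherwise the
#'   D8 direction (1 = E, 2 = SE, ..., 8 = NE) of the upstream neighbour
#'   satisfying the Bellman condition.
#' @export
cost_distance <- function(surface, sources) {
  if (inherits(sources, "patch_set")) sources <- sources$cells
  src <- unique(unlist(sources))
  if (!length(src)) abort_validation("at least one source cell is required")
  lat <- lattice_igraph(surface)
  g <- igraph::add_vertices(lat$graph, 1)
  virt <- igraph::vcount(g)
  g <- igraph::add_edges(g, rbind(rep(virt, length(src)), lat$vid[src]),
                         weight = 0, steplen = 0)
  dist <- as.vector(igraph::distances(g, v = virt,
                                      weights = igraph::E(g)$weight))
  cost <- matrix(NA_real_, lat$nr, lat$nc)
  cost[lat$cell_of] <- dist[seq_len(length(lat$cell_of))]
  # backlink: upstream neighbour minimising cost(n) + movecost(n, c)
  v <- surface$values
  off <- d8_offsets()
  best <- matrix(Inf, lat$nr, lat$nc)
  back <- matrix(0L, lat$nr, lat$nc)
  for (d in seq_len(8)) {
    nb_cost <- shift_mat(cost, off$dr[d], off$dc[d], NA)
    nb_res <- shift_mat(v, off$dr[d], off$dc[d], NA)
    cand <- nb_cost + (nb_res + v) / 2 * off$len[d]
    better <- !is.na(cand) & cand < best
    best[better] <- cand[better]
    back[better] <- d
  }
  back[src] <- 0L
  back[is.na(cost)] <- NA
  costg <- eco_grid(cost, cell_size = surface$cell_size,
                    origin = surface$origin, crs_tag = surface$crs_tag)
  backg <- eco_grid(back, cell_size = surface$cell_size,
                    origin = surface$origin, crs_tag = surface$crs_tag)
  structure(list(cumulative_cost = costg, backlink = backg),
            class = "cost_field")
}

#' Least-cost paths between all patch pairs
#'
#' For each unordered patch pair, the minimum-cumulative-resistance path
#' between the patches (entering and leaving anywhere on the patch). Paths
#' shorter than `min_length_km` are dropped, and near-duplicate paths (cell
#' overlap at or above `overlap_dedup` of the shorter path) are removed
#' keeping the lower-cost one. Unreachable pairs are skipped with a warning.
#'
#' @param surface A `resistance_surface`.
#' @param ps A `patch_set` with at least 2 patches.
#' @param min_length_km Minimum geometric path length retained.
#' @param overlap_dedup Fractional overlap treated as duplication.
#' @return A `cost_path_set`: `table` tibble (`src`, `dst`, `length_km`,
#'   `cum_cost`, `kept`, `drop_reason`) plus the cell sequence of every
#'   pair's path.
#' @export
least_cost_paths <- function(surface, ps, min_length_km = 10,
                             overlap_dedup = 0.9) {
  stopifnot(inherits(ps, "patch_set"))
  n <- nrow(ps$patches)
  if (n < 2) abort_validation("need at least 2 patches")
  lat <- lattice_igraph(surface)
  g <- lat$graph
  base <- igraph::vcount(g)
  g <- igraph::add_vertices(g, n)
  for (i in seq_len(n)) {
    cl <- ps$cells[[i]]
    g <- igraph::add_edges(g, rbind(rep(base + i, length(cl)), lat$vid[cl]),
                           weight = 0, steplen = 0)
  }
  wts <- igraph::E(g)$weight
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  paths <- list()
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- unname(pairs[p, 1]); j <- unname(pairs[p, 2])
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = base + i, to = base + j,
                             weights = wts, output = "both"))
    vp <- sp$vpath[[1]]
    if (length(vp) == 0) {
      warning(sprintf("patches %d and %d are not reachable; pair skipped", i, j))
      next
    }
    vseq <- as.integer(vp)
    cum_cost <- sum(wts[as.integer(sp$epath[[1]])])
    vseq <- vseq[vseq <= base]            # strip virtual patch vertices
    cells <- lat$cell_of[vseq]
    steps <- igraph::E(g)$steplen[as.integer(sp$epath[[1]])]
    length_km <- sum(steps) * surface$cell_size / 1000
    paths[[length(paths) + 1]] <- list(src = i, dst = j, cells = cells,
                                       length_km = length_km,
                                       cum_cost = cum_cost)
  }
  tab <- dplyr::bind_rows(lapply(paths, function(p) {
    tibble::tibble(src = p$src, dst = p$dst, length_km = p$length_km,
                   cum_cost = p$cum_cost)
  }))
  if (nrow(tab) == 0) {
    return(structure(list(table = tab, paths = paths,
                          cell_size = surface$cell_size, dim = dim(surface$values),
                          origin = surface$origin),
                     class = "cost_path_set"))
  }
  tab$kept <- TRUE
  tab$drop_reason <- NA_character_
  short <- tab$length_km < min_length_km
  tab$kept[short] <- FALSE
  tab$drop_reason[short] <- "below_min_length"
  # dedup: visit candidates in increasing cost; drop if overlapping a keeper
  ord <- order(tab$cum_cost)
  kept_cells <- list()
  for (o in ord) {
    if (!tab$kept[o]) next
    cl <- paths[[o]]$cells
    dup <- any(vapply(kept_cells, function(kc) {
      length(intersect(kc, cl)) / min(length(kc), length(cl)) >= overlap_dedup
    }, logical(1)))
    if (dup) {
      tab$kept[o] <- FALSE
      tab$drop_reason[o] <- "duplicate"
    } else {
      kept_cells[[length(kept_cells) + 1]] <- cl
    }
  }
  structure(list(table = tab, paths = paths, cell_size = surface$cell_size,
                 dim = dim(surface$values), origin = surface$origin),
            class = "cost_path_set")
}

#' @export
print.cost_path_set <- function(x, ...) {
  cat(sprintf("<cost_path_set> %d pair paths, %d kept\n",
              nrow(x$table), sum(x$table$kept)))
  print(x$table)
  invisible(x)
}

#' Gravity-model interaction between corridor endpoints
#'
#' `G_ij = Lmax^2 ln(a_i) ln(a_j) / L_ij^2`, with `L_ij` the cumulative
#' resistance of the corridor, `Lmax` the maximum cumulative resistance
#' among the surviving corridors, and areas expressed in `area_unit` so
#' that `ln(a) > 0`.
#'
#' @param pathset A `cost_path_set` from [least_cost_paths()].
#' @param patches Patch tibble carrying `id` and `area_km2` (e.g.
#'   `ps$patches`).
#' @param area_unit `"ha"` (default) or `"km2"`: unit fed to `ln`.
#' @return Tibble with one row per kept corridor: `src`, `dst`,
#'   `length_km`, `cum_cost`, `gravity`; `l_max` as an attribute.
#' @export
gravity_ranking <- function(pathset, patches, area_unit = c("ha", "km2")) {
  stopifnot(inherits(pathset, "cost_path_set"))
  area_unit <- match.arg(area_unit)
  tab <- dplyr::filter(pathset$table, .data$kept)
  if (nrow(tab) == 0) {
    out <- tibble::tibble(src = integer(0), dst = integer(0),
                          length_km = numeric(0), cum_cost = numeric(0),
                          gravity = numeric(0))
    attr(out, "l_max") <- NA_real_
    return(out)
  }
  a <- patches$area_km2 * if (area_unit == "ha") 100 else 1
  if (any(a[c(tab$src, tab$dst)] <= 1)) {
    abort_validation(paste0(
      "patch area <= 1 ", area_unit, " makes ln(area) non-positive; ",
      "choose a smaller `area_unit`"))
  }
  l_max <- max(tab$cum_cost)
  out <- tab |>
    dplyr::mutate(gravity = l_max^2 * log(a[.data$src]) * log(a[.data$dst]) /
                    .data$cum_cost^2) |>
    dplyr::select("src", "dst", "length_km", "cum_cost", "gravity")
  attr(out, "l_max") <- l_max
  out
}

#' Tier corridors by gravity value
#'
#' With bounds `(b1, b2, b3)` (default 1, 10, 100): gravity above `b3` is
#' level 1, in `(b2, b3]` level 2, in `(b1, b2]` level 3, and at or below
#' `b1` the corridor is excluded from the network.
#'
#' @param gravity_tbl Tibble from [gravity_ranking()] (or any tibble with a
#'   `gravity` column).
#' @param bounds Three ascending tier bounds.
#' @return A `corridor_set` tibble: input columns plus `id` and `level`
#'   (`NA` for excluded corridors), ordered by decreasing gravity; kept
#'   corridors are numbered 1..k.
#' @export
classify_corridors <- function(gravity_tbl, bounds = c(1, 10, 100)) {
  if (length(bounds) != 3 || is.unsorted(bounds, strictly = TRUE)) {
    abort_validation("`bounds` must be three strictly increasing numbers")
  }
  out <- gravity_tbl |>
    dplyr::mutate(level = dplyr::case_when(
      .data$gravity > bounds[3] ~ 1L,
      .data$gravity > bounds[2] ~ 2L,
      .data$gravity > bounds[1] ~ 3L,
      TRUE ~ NA_integer_)) |>
    dplyr::arrange(dplyr::desc(.data$gravity))
  out$id <- NA_integer_
  kept <- !is.na(out$level)
  out$id[kept] <- seq_len(sum(kept))
  out <- dplyr::relocate(out, "id")
  class(out) <- c("corridor_set", class(out))
  out
}
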