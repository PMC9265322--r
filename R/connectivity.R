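#' Pairwise edge-to-edge distances between patches
#'
#' Distance between two patches is the minimum cell-centre distance between
#' their boundary cells minus one cell size, floored at zero -- a cheap,
#' deterministic proxy for polygon edge-to-edge distance. Adjacent patches
#' therefore sit at 0 m.
#'
#' @param ps A `patch_set`.
#' @return Symmetric matrix of distances in metres (0 on the diagonal).
#' @export
patch_distances <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  n <- nrow(ps$patches)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  nr <- ps$dim[1]
  bcoords <- lapply(ps$cells, function(ix) {
    rows <- ((ix - 1) %% nr) + 1
    cols <- ((ix - 1) %/% nr) + 1
    # boundary cells: a 4-neighbour outside the patch (or the map)
    inpatch <- matrix(FALSE, ps$dim[1], ps$dim[2])
    inpatch[ix] <- TRUE
    on_b <- !(shift_mat(inpatch, 1, 0, FALSE)[ix] &
                shift_mat(inpatch, -1, 0, FALSE)[ix] &
                shift_mat(inpatch, 0, 1, FALSE)[ix] &
                shift_mat(inpatch, 0, -1, FALSE)[ix])
    cbind(x = ps$origin[1] + (cols[on_b] - 0.5) * ps$cell_size,
          y = ps$origin[2] - (rows[on_b] - 0.5) * ps$cell_size)
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- bcoords[[i]]; b <- bcoords[[j]]
      dx <- outer(a[, 1], b[, 1], "-")
      dy <- outer(a[, 2], b[, 2], "-")
      dmin <- sqrt(min(dx^2 + dy^2))
      d[i, j] <- d[j, i] <- max(dmin - ps$cell_size, 0)
    }
  }
  d
}

#' Build a patch connectivity graph
#'
#' Patches are linked when their edge-to-edge distance does not exceed the
#' dispersal threshold. The direct dispersal probability between linked
#' patches is a negative exponential calibrated so that
#' `probability_at_threshold` is reached exactly at `threshold_m`.
#'
#' @param ps A `patch_set`.
#' @param threshold_m Dispersal-distance threshold in metres.
#' @param probability_at_threshold Dispersal probability at the threshold
#'   distance (default 0.5).
#' @param total_area_km2 The denominator area SL. Defaults to the summed
#'   patch area of the analysis set; pass the full study area to use the
#'   landscape-area convention instead (importance percentages are
#'   invariant to this choice).
#' @param distances Optional precomputed matrix from [patch_distances()].
#' @return A `patch_graph`.
#' @export
patch_graph <- function(ps, threshold_m, probability_at_threshold = 0.5,
                        total_area_km2 = NULL, distances = NULL) {
  stopifnot(inherits(ps, "patch_set"))
  if (nrow(ps$patches) < 1) abort_validation("patch set is empty")
  if (probability_at_threshold <= 0 || probability_at_threshold >= 1) {
    abort_validation("`probability_at_threshold` must lie in (0, 1)")
  }
  if (is.null(distances)) distances <- patch_distances(ps)
  sl <- if (is.null(total_area_km2)) sum(ps$patches$area_km2) else total_area_km2
  if (sl <= 0) abort_validation("total area SL must be positive")
  structure(list(patches = ps$patches, d = distances,
                 threshold = threshold_m,
                 probability = probability_at_threshold, sl = sl),
            class = "patch_graph")
}

graph_adjacency <- function(g, ids = seq_len(nrow(g$patches))) {
  d <- g$d[ids, ids, drop = FALSE]
  adj <- d <= g$threshold
  diag(adj) <- FALSE
  adj
}

# igraph over the threshold graph; weights = -log direct probability
threshold_igraph <- function(g, ids = seq_len(nrow(g$patches))) {
  adj <- graph_adjacency(g, ids)
  d <- g$d[ids, ids, drop = FALSE]
  k <- log(g$probability) / g$threshold
  el <- which(adj & upper.tri(adj), arr.ind = TRUE)
  gr <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (nrow(el)) {
    gr <- igraph::add_edges(gr, t(el))
    igraph::E(gr)$hops <- 1
    igraph::E(gr)$nlp <- -k * d[el]   # -log p_ij, >= 0
  }
  gr
}

#' Landscape coincidence probability (LCP)
#'
#' `LCP = sum over components (Delta_i / SL)^2`, where `Delta_i` is the
#' summed patch area of component i at the current threshold.
#'
#' @param g A `patch_graph`.
#' @param ids Patch indices included (used by the removal experiment).
#' @return A single number.
#' @export
compute_lcp <- function(g, ids = seq_len(nrow(g$patches))) {
  gr <- threshold_igraph(g, ids)
  memb <- igraph::components(gr)$membership
  comp_area <- tapply(g$patches$area_km2[ids], memb, sum)
  sum((comp_area / g$sl)^2)
}

#' Integral index of connectivity (IIC)
#'
#' `IIC = [sum_ij a_i a_j / (1 + nl_ij)] / SL^2`, with `nl_ij` the number of
#' links on the topological shortest path between i and j in the threshold
#' graph; pairs in different components contribute nothing.
#'
#' @param g A `patch_graph`.
#' @param ids Patch indices included (used by the removal experiment).
#' @return A single number.
#' @export
compute_iic <- function(g, ids = seq_len(nrow(g$patches))) {
  gr <- threshold_igraph(g, ids)
  nl <- if (igraph::ecount(gr)) {
    igraph::distances(gr, weights = igraph::E(gr)$hops)
  } else {
    igraph::distances(gr)
  }
  a <- g$patches$area_km2[ids]
  num <- outer(a, a) / (1 + nl)
  sum(num[is.finite(nl)]) / g$sl^2
}

#' Probability of connectivity (PC)
#'
#' Direct dispersal probability `p_ij = exp(k d_ij)` with
#' `k = ln(p_thr)/threshold`; `mu*_ij` is the maximum product of direct
#' probabilities over paths (a shortest path on `-log p` weights);
#' `PC = sum_ij a_i a_j mu*_ij / SL^2`.
#'
#' @param g A `patch_graph`.
#' @param ids Patch indices included (used by the removal experiment).
#' @return A single number.
#' @export
compute_pc <- function(g, ids = seq_len(nrow(g$patches))) {
  gr <- threshold_igraph(g, ids)
  nlp <- if (igraph::ecount(gr)) {
    igraph::distances(gr, weights = igraph::E(gr)$nlp)
  } else {
    igraph::distances(gr)
  }
  mu <- exp(-nlp)          # Inf -> 0 for disconnected pairs
  mu[!is.finite(nlp)] <- 0
  diag(mu) <- 1
  a <- g$patches$area_km2[ids]
  sum(outer(a, a) * mu) / g$sl^2
}

#' Number of components at the current threshold
#' @param g A `patch_graph`.
#' @return Integer component count.
#' @export
compute_nc <- function(g) {
  igraph::components(threshold_igraph(g))$no
}

#' Whole-graph connectivity indices
#'
#' @param g A `patch_graph`.
#' @return One-row tibble with `n_patches`, `nc`, `lcp`, `iic`, `pc`.
#' @export
connectivity_indices <- function(g) {
  stopifnot(inherits(g, "patch_graph"))
  tibble::tibble(n_patches = nrow(g$patches), nc = compute_nc(g),
                 lcp = compute_lcp(g), iic = compute_iic(g),
                 pc = compute_pc(g))
}

#' Per-patch importance (dLCP / dIIC / dPC)
#'
#' Recomputes an index with each patch removed in turn (SL held fixed) and
#' reports the percentage drop `100 * (phi - phi_removed) / phi`. When the
#' full-graph index is zero the importance is undefined and returned as NA.
#'
#' @param g A `patch_graph` with at least two patches.
#' @param index `"LCP"`, `"IIC"`, `"PC"` or `"all"`.
#' @return Tibble with `id`, `area_km2` and a `d<index>` column per index,
#'   in percent.
#' @export
patch_importance <- function(g, index = "all") {
  stopifnot(inherits(g, "patch_graph"))
  n <- nrow(g$patches)
  if (n < 2) abort_validation("patch importance needs at least 2 patches")
  index <- match.arg(index, c("LCP", "IIC", "PC", "all"))
  wanted <- if (index == "all") c("LCP", "IIC", "PC") else index
  fns <- list(LCP = compute_lcp, IIC = compute_iic, PC = compute_pc)
  out <- tibble::tibble(id = g$patches$id, area_km2 = g$patches$area_km2)
  for (ix in wanted) {
    phi <- fns[[ix]](g)
    dphi <- vapply(seq_len(n), function(x) {
      if (phi == 0) return(NA_real_)
      100 * (phi - fns[[ix]](g, ids = setdiff(seq_len(n), x))) / phi
    }, numeric(1))
    out[[paste0("d", ix)]] <- dphi
  }
  out
}

#' Sweep dispersal-distance thresholds
#'
#' Recomputes the connectivity indices and per-patch importance summaries at
#' each candidate threshold, mirroring the tabular threshold-selection
#' procedure. An optional heuristic labels as `suggested` the smallest
#' threshold at which the ranking of the top `k` patches by dPC has
#' stabilised (equals the ranking at the next threshold).
#'
#' @param ps A `patch_set` with at least 2 patches.
#' @param thresholds_m Vector of at least 2 thresholds, metres.
#' @param probability_at_threshold Dispersal probability at each threshold.
#' @param total_area_km2 Optional SL override (see [patch_graph()]).
#' @param suggest_top_k Patches considered by the stability heuristic.
#' @return Tibble with one row per threshold: `threshold_m`, `nc`, `lcp`,
#'   `iic`, `pc`, mean and max of each importance measure, and `suggested`.
#' @export
threshold_sweep <- function(ps, thresholds_m,
                            probability_at_threshold = 0.5,
                            total_area_km2 = NULL, suggest_top_k = 3L) {
  if (length(thresholds_m) < 2) {
    abort_validation("`thresholds_m` must contain at least 2 thresholds")
  }
  dmat <- patch_distances(ps)
  rankings <- list()
  rows <- lapply(sort(thresholds_m), function(thr) {
    g <- patch_graph(ps, thr, probability_at_threshold, total_area_km2,
                     distances = dmat)
    imp <- patch_importance(g)
    rankings[[as.character(thr)]] <<-
      imp$id[order(-imp$dPC)][seq_len(min(suggest_top_k, nrow(imp)))]
    dplyr::bind_cols(tibble::tibble(threshold_m = thr),
                     connectivity_indices(g)[, c("nc", "lcp", "iic", "pc")],
                     tibble::tibble(
                       mean_dlcp = mean(imp$dLCP), max_dlcp = max(imp$dLCP),
                       mean_diic = mean(imp$dIIC), max_diic = max(imp$dIIC),
                       mean_dpc = mean(imp$dPC), max_dpc = max(imp$dPC)))
  })
  out <- dplyr::bind_rows(rows)
  stable <- vapply(seq_len(nrow(out) - 1), function(i) {
    identical(rankings[[i]], rankings[[i + 1]])
  }, logical(1))
  out$suggested <- FALSE
  if (any(stable)) out$suggested[which(stable)[1]] <- TRUE
  out
}

#' Select ecological sources by dPC
#'
#' @param importances Tibble from [patch_importance()] containing `dPC`.
#' @param min_dpc Strict lower bound, in percent (default 1).
#' @return Tibble of selected patches sorted by decreasing dPC.
#' @export
select_sources <- function(importances, min_dpc = 1) {
  stopifnot("dPC" %in% names(importances))
  importances |>
    dplyr::filter(!is.na(.data$dPC), .data$dPC > min_dpc) |>
    dplyr::arrange(dplyr::desc(.data$dPC))
}
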