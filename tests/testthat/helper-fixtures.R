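# Fixture builders and independent brute-force oracles. The oracles
# deliberately avoid the package's vectorised machinery: they answer each
# query by exhaustive search so they can arbitrate the fast paths.

# build a patch_set by hand from a list of cell-index vectors
make_patch_set <- function(cells, dims, cell_size = 1000, origin = c(0, 0)) {
  nr <- dims[1]
  cent <- t(vapply(cells, function(ix) {
    rows <- ((ix - 1) %% nr) + 1
    cols <- ((ix - 1) %/% nr) + 1
    c(origin[1] + (mean(cols) - 0.5) * cell_size,
      origin[2] - (mean(rows) - 0.5) * cell_size)
  }, numeric(2)))
  structure(list(
    patches = tibble::tibble(
      id = seq_along(cells),
      area_cells = vapply(cells, length, integer(1)),
      area_km2 = vapply(cells, length, integer(1)) * (cell_size / 1000)^2,
      centroid_x = cent[, 1], centroid_y = cent[, 2]),
    cells = cells, dim = dims, cell_size = cell_size, origin = origin),
    class = "patch_set")
}

# a patch graph straight from an explicit distance matrix and areas
graph_from_matrix <- function(areas, d, threshold, prob = 0.5, sl = NULL) {
  cells <- as.list(seq_along(areas))
  ps <- make_patch_set(cells, dims = c(1, length(areas)), cell_size = 1000)
  ps$patches$area_km2 <- areas
  patch_graph(ps, threshold, prob, total_area_km2 = sl, distances = d)
}

small_demo_spec <- function(seed = 42L, ...) {
  synth_spec(shape = c(60L, 60L), cell_size = 600, seed = seed, ...)
}

# ---------------------------------------------------------------------
# MSPA oracle: per-cell classification by exhaustive distance and
# connectivity queries on small grids.

oracle_chebyshev <- function(r, c, mask, outside = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- Inf
  if (outside) d <- min(r, nr + 1 - r, c, nc + 1 - c)
  wm <- which(mask, arr.ind = TRUE)
  if (nrow(wm)) {
    d <- min(d, min(pmax(abs(wm[, 1] - r), abs(wm[, 2] - c))))
  }
  d
}

# queue flood fill, independent of igraph
oracle_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1) %% nr) + 1; c <- ((cur - 1) %/% nr) + 1
      for (i in seq_len(nrow(nb))) {
        r2 <- r + nb[i, 1]; c2 <- c + nb[i, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          j <- (c2 - 1) * nr + r2
          if (mask[j] && lab[j] == 0) { lab[j] <- k; queue <- c(queue, j) }
        }
      }
    }
  }
  lab
}

oracle_mspa <- function(fg, w, connectivity = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  codes <- mspa_codes()
  out <- matrix(codes[["background"]], nr, nc)
  bg <- !fg
  d_bg <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d_bg[r, c] <- oracle_chebyshev(r, c, bg, outside = TRUE)
  }
  core <- fg & d_bg > w
  comp <- oracle_components(fg, connectivity)
  core_comps <- unique(comp[core])
  bg_lab <- oracle_components(bg, if (connectivity == 8) 4 else 8)
  border_ids <- unique(c(bg_lab[1, ], bg_lab[nr, ], bg_lab[, 1], bg_lab[, nc]))
  outside_bg <- bg & matrix(bg_lab %in% setdiff(border_ids, 0), nr, nc)
  d_core <- matrix(Inf, nr, nc)
  d_out <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d_core[r, c] <- oracle_chebyshev(r, c, core)
    d_out[r, c] <- oracle_chebyshev(r, c, outside_bg, outside = TRUE)
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!fg[r, c]) next
    if (core[r, c]) { out[r, c] <- codes[["core"]]; next }
    if (!(comp[r, c] %in% core_comps)) { out[r, c] <- codes[["islet"]]; next }
    if (d_core[r, c] <= w) {
      out[r, c] <- if (d_out[r, c] <= w) codes[["edge"]] else codes[["perforation"]]
    }
  }
  # connectors: remaining cells, classified per component
  conn <- fg & matrix(comp %in% core_comps, nr, nc) & !core & d_core > w
  conn_lab <- oracle_components(conn, connectivity)
  core_lab <- oracle_components(core, 8)
  if (max(conn_lab) > 0) {
    for (cid in seq_len(max(conn_lab))) {
      cells <- which(conn_lab == cid)
      own <- comp[cells[1]]
      touched <- integer(0)
      zones <- list()
      for (k in seq_len(max(core_lab))) {
        if (comp[which(core_lab == k)[1]] != own) next
        contact <- vapply(cells, function(j) {
          r <- ((j - 1) %% nr) + 1; c <- ((j - 1) %/% nr) + 1
          oracle_chebyshev(r, c, core_lab == k) <= w + 1
        }, logical(1))
        if (any(contact)) {
          touched <- c(touched, k)
          zmask <- matrix(FALSE, nr, nc); zmask[cells[contact]] <- TRUE
          zones[[length(zones) + 1]] <- zmask
        }
      }
      cls <- if (length(touched) >= 2) codes[["bridge"]]
      else if (length(touched) == 1) {
        if (max(oracle_components(zones[[1]], 8)) >= 2) codes[["loop"]]
        else codes[["branch"]]
      } else codes[["islet"]]
      out[cells] <- cls
    }
  }
  storage.mode(out) <- "double"
  out
}

# ---------------------------------------------------------------------
# exhaustive simple-path enumeration for mu* (max product of direct
# probabilities) and nl (min links); n <= 6 patches
oracle_paths <- function(adj, p, i, j) {
  n <- nrow(adj)
  best_mu <- if (i == j) 1 else 0
  best_nl <- if (i == j) 0 else Inf
  recurse <- function(cur, visited, mu, nl) {
    if (cur == j) {
      if (mu > best_mu) best_mu <<- mu
      if (nl < best_nl) best_nl <<- nl
      return()
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && adj[cur, nxt]) {
        visited2 <- visited; visited2[nxt] <- TRUE
        recurse(nxt, visited2, mu * p[cur, nxt], nl + 1)
      }
    }
  }
  if (i != j) {
    v <- rep(FALSE, n); v[i] <- TRUE
    recurse(i, v, 1, 0)
  }
  list(mu = best_mu, nl = best_nl)
}

# ---------------------------------------------------------------------
# Bellman value-iteration oracle for cost distance on tiny grids
oracle_cost_distance <- function(res, src_cells) {
  nr <- nrow(res); nc <- ncol(res)
  cost <- matrix(Inf, nr, nc)
  cost[src_cells] <- 0
  nb <- cbind(c(0, 1, 1, 1, 0, -1, -1, -1), c(1, 1, 0, -1, -1, -1, 0, 1))
  len <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      for (i in seq_len(8)) {
        r2 <- r + nb[i, 1]; c2 <- c + nb[i, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          cand <- cost[r2, c2] + (res[r, c] + res[r2, c2]) / 2 * len[i]
          if (cand < cost[r, c] - 1e-12) { cost[r, c] <- cand; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }
  cost
}

expect_tbl_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
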