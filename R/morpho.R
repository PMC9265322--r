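# Shared raster morphology: distance transforms and component labeling.

# Chebyshev (8-neighbourhood chamfer) distance to `mask`; cells in the mask
# get 0. `outside` = TRUE treats everything beyond the map edge as part of
# the mask (one virtual ring). Computed by breadth-first dilation.
chebyshev_dist <- function(mask, outside = FALSE, max_dist = Inf) {
  if (outside) {
    nr <- nrow(mask); nc <- ncol(mask)
    padded <- matrix(TRUE, nr + 2, nc + 2)
    padded[2:(nr + 1), 2:(nc + 1)] <- mask
    d <- chebyshev_dist(padded, outside = FALSE, max_dist = max_dist)
    return(d[2:(nr + 1), 2:(nc + 1), drop = FALSE])
  }
  d <- matrix(Inf, nrow(mask), ncol(mask))
  reached <- mask
  d[mask] <- 0
  k <- 0
  while (any(reached) && !all(reached) && k < max_dist) {
    k <- k + 1
    grown <- dilate_mask(reached, 1L)
    newly <- grown & !reached
    if (!any(newly)) break
    d[newly] <- k
    reached <- grown
  }
  d
}

# Label connected components of a logical mask. Returns an integer matrix
# (0 outside the mask) with labels 1..k assigned in scan order of the first
# cell of each component.
label_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  off <- if (connectivity == 8L) {
    list(dr = c(0, 1, 1, 1), dc = c(1, 0, 1, -1))
  } else {
    list(dr = c(0, 1), dc = c(1, 0))
  }
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  edges <- NULL
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  for (d in seq_along(off$dr)) {
    r2 <- rows + off$dr[d]; c2 <- cols + off$dc[d]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    nb <- (c2[ok] - 1) * nr + r2[ok]
    keep <- mask[nb]
    if (any(keep)) {
      edges <- rbind(edges, cbind(pos[idx[ok][keep]], pos[nb[keep]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel in scan order of first occurrence
  first <- tapply(seq_along(idx), memb, min)
  relabel <- integer(max(memb))
  relabel[order(first)] <- seq_along(first)
  lab[idx] <- relabel[memb]
  lab
}
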