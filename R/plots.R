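#' Plot a raster grid
#'
#' @param object An `eco_grid`.
#' @param ... Unused.
#' @return A ggplot raster map.
#' @export
autoplot.eco_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an MSPA classification
#'
#' @param object An `mspa_raster`.
#' @param ... Unused.
#' @return A ggplot map with the conventional MSPA colour scheme.
#' @export
autoplot.mspa_raster <- function(object, ...) {
  codes <- mspa_codes()
  df <- as_tibble(object)
  df$class <- factor(names(codes)[match(df$value, codes)],
                     levels = names(codes))
  pal <- c(background = "grey95", core = "#1a9641", islet = "#b8860b",
           edge = "#000000", bridge = "#d7191c", branch = "#ff7f00",
           loop = "#ffff33", perforation = "#2b83ba")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = pal, na.value = "white",
                               drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "MSPA class") +
    ggplot2::theme_minimal()
}

#' Plot a land-cover raster
#'
#' @param object A `land_cover`.
#' @param ... Unused.
#' @return A ggplot categorical map.
#' @export
autoplot.land_cover <- function(object, ...) {
  df <- as_tibble(object)
  df$class <- factor(names(object$legend)[match(df$value, object$legend)],
                     levels = names(object$legend))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_brewer(palette = "Set2", na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "land cover") +
    ggplot2::theme_minimal()
}

#' Map of corridors and nodes over a resistance surface
#'
#' @param surface A `resistance_surface` (background).
#' @param corridors A `corridor_set`.
#' @param pathset The matching `cost_path_set`.
#' @param nodes Optional `node_set`.
#' @return A ggplot map.
#' @export
plot_network <- function(surface, corridors, pathset, nodes = NULL) {
  p <- autoplot.eco_grid(surface)
  kept <- corridors[!is.na(corridors$level), ]
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(kept)), function(i) {
    q <- Filter(function(z) z$src == kept$src[i] && z$dst == kept$dst[i],
                pathset$paths)[[1]]
    nr <- pathset$dim[1]
    rows <- ((q$cells - 1) %% nr) + 1
    cols <- ((q$cells - 1) %/% nr) + 1
    tibble::tibble(id = kept$id[i], level = factor(kept$level[i]),
                   x = pathset$origin[1] + (cols - 0.5) * pathset$cell_size,
                   y = pathset$origin[2] - (rows - 0.5) * pathset$cell_size)
  }))
  if (nrow(segs)) {
    p <- p + ggplot2::geom_path(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   group = .data$id, colour = .data$level),
      inherit.aes = FALSE, linewidth = 0.7)
  }
  if (!is.null(nodes) && nrow(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$node_type),
      inherit.aes = FALSE, colour = "white", size = 2)
  }
  p
}
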