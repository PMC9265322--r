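# GeoJSON export -------------------------------------------------------

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry,
       properties = properties)
}

#' Write corridors as a GeoJSON FeatureCollection of LineStrings
#'
#' @param corridors A `corridor_set`.
#' @param pathset The `cost_path_set` holding each pair's cell sequence.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corridors_geojson <- function(corridors, pathset, path) {
  kept <- corridors[!is.na(corridors$level), ]
  feats <- lapply(seq_len(nrow(kept)), function(i) {
    p <- Filter(function(q) q$src == kept$src[i] && q$dst == kept$dst[i],
                pathset$paths)[[1]]
    nr <- pathset$dim[1]
    rows <- ((p$cells - 1) %% nr) + 1
    cols <- ((p$cells - 1) %/% nr) + 1
    coords <- lapply(seq_along(rows), function(k) {
      c(pathset$origin[1] + (cols[k] - 0.5) * pathset$cell_size,
        pathset$origin[2] - (rows[k] - 0.5) * pathset$cell_size)
    })
    geojson_feature(
      list(type = "LineString", coordinates = coords),
      list(id = kept$id[i], src = kept$src[i], dst = kept$dst[i],
           length_km = kept$length_km[i], cum_cost = kept$cum_cost[i],
           gravity = kept$gravity[i], level = kept$level[i]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

#' Write ecological nodes as a GeoJSON FeatureCollection of Points
#'
#' @param nodes A `node_set` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nodes_geojson <- function(nodes, path) {
  feats <- lapply(seq_len(nrow(nodes)), function(i) {
    geojson_feature(
      list(type = "Point", coordinates = c(nodes$x[i], nodes$y[i])),
      list(node_id = nodes$node_id[i], node_type = nodes$node_type[i],
           provenance = nodes$provenance[i]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

# Pipeline --------------------------------------------------------------

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 class = "econetr_stage_error")
  })
}

#' Run the full ecological-network pipeline
#'
#' Chains every stage -- MSPA segmentation, source selection by dPC,
#' resistance-surface construction, least-cost corridors with gravity
#' tiering, hydrological node extraction and network structural evaluation
#' -- and writes the inspectable artifact set into `out_dir`:
#' `mspa.asc`, `sources.csv`, `resistance.asc`, `corridors.geojson`,
#' `corridors.csv`, `nodes.geojson`, `network_metrics.csv` and
#' `params.yaml`. A run is a pure function of `(inputs, config)`: repeated
#' runs with the same seed produce identical tabular outputs.
#'
#' @param config A [pipeline_config()].
#' @param inputs Named list with `landcover` (a `land_cover` or a raster
#'   path), `dem` (an `eco_grid` or path), optional `slope` (derived from
#'   the DEM when absent) and optional logical road/river masks `roads`,
#'   `rivers`.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lay <- run_stage("inputs", {
    lc <- inputs$landcover
    if (is.character(lc)) lc <- land_cover(read_raster(lc, "categorical"))
    dem <- inputs$dem
    if (is.character(dem)) dem <- read_raster(dem, "continuous")
    slope <- inputs$slope
    if (is.character(slope)) slope <- read_raster(slope, "continuous")
    if (is.null(slope)) slope <- slope_from_dem(dem)
    aligned <- align_stack(list(landcover = lc, dem = dem, slope = slope))
    aligned$landcover$legend <- lc$legend
    class(aligned$landcover) <- class(lc)
    aligned
  })

  mspa <- run_stage("mspa", {
    m <- mspa_classify(binarize(lay$landcover, config$foreground_classes),
                       edge_width_cells = config$mspa_edge_width_cells,
                       connectivity = config$mspa_connectivity)
    write_raster(m, file.path(out_dir, "mspa.asc"))
    m
  })

  src <- run_stage("connectivity", {
    ps <- extract_cores(mspa, min_area_cells = config$min_core_area_cells)
    if (nrow(ps$patches) < 2) {
      stop("fewer than two core patches; cannot build a network")
    }
    g <- patch_graph(ps, config$threshold_m,
                     config$connectivity_probability)
    imp <- patch_importance(g)
    sel <- select_sources(imp, config$min_dpc)
    if (nrow(sel) < 2) {
      warning("fewer than two patches exceed the dPC threshold; ",
              "keeping the two highest-dPC patches")
      sel <- imp |> dplyr::arrange(dplyr::desc(.data$dPC)) |>
        utils::head(2)
    }
    imp$selected <- imp$id %in% sel$id
    readr::write_csv(imp, file.path(out_dir, "sources.csv"))
    sources <- ps
    keep <- match(sort(sel$id), ps$patches$id)
    sources$patches <- ps$patches[keep, ]
    sources$cells <- ps$cells[keep]
    sources$patches$id <- seq_len(nrow(sources$patches))
    list(patch_set = ps, graph = g, importance = imp, sources = sources)
  })

  resist <- run_stage("resistance", {
    r <- build_resistance(mspa, lay$landcover, lay$dem, lay$slope,
                          config$resistance)
    write_raster(r, file.path(out_dir, "resistance.asc"))
    r
  })

  corr <- run_stage("corridors", {
    paths <- least_cost_paths(resist, src$sources,
                              min_length_km = config$corridor_min_length_km,
                              overlap_dedup = config$corridor_overlap_dedup)
    grav <- gravity_ranking(paths, src$sources$patches,
                            area_unit = config$gravity_area_unit)
    cs <- classify_corridors(grav, bounds = config$gravity_tier_bounds)
    readr::write_csv(
      dplyr::select(tibble::as_tibble(cs), "id", "src", "dst", "length_km",
                    "cum_cost", "gravity", "level"),
      file.path(out_dir, "corridors.csv"))
    write_corridors_geojson(cs, paths, file.path(out_dir, "corridors.geojson"))
    list(paths = paths, gravity = grav, corridors = cs)
  })

  nodes <- run_stage("nodes", {
    vr <- valleys_and_ridges(resist, quantile = config$hydro_quantile)
    lcv <- lay$landcover$values
    legend <- lay$landcover$legend
    masks <- list(
      rivers = if (!is.null(inputs$rivers)) inputs$rivers else
        (!is.na(lcv) & lcv == legend[["water_area"]]),
      paddy = !is.na(lcv) & lcv == legend[["paddy_field"]])
    if (!is.null(inputs$roads)) masks$roads <- inputs$roads
    ns <- classify_nodes(vr$ridges, vr$valleys, corr$corridors, corr$paths,
                         masks = masks,
                         merge_radius = config$node_merge_radius_cells)
    write_nodes_geojson(ns, file.path(out_dir, "nodes.geojson"))
    list(vr = vr, nodes = ns)
  })

  metrics <- run_stage("evaluate", {
    met <- evaluate_subnetworks(corr$corridors, nodes$nodes)
    readr::write_csv(
      dplyr::select(met, "subnetwork", "L", "V",
                    total_length = "total_length_km", "alpha", "beta",
                    "gamma", "cost_ratio"),
      file.path(out_dir, "network_metrics.csv"))
    met
  })

  run_stage("log", {
    yaml::write_yaml(list(config = unclass_deep(config),
                          n_patches = nrow(src$patch_set$patches),
                          n_sources = nrow(src$sources$patches),
                          n_paths = nrow(corr$paths$table),
                          n_corridors = sum(!is.na(corr$corridors$level)),
                          n_nodes = nrow(nodes$nodes)),
                     file.path(out_dir, "params.yaml"))
  })

  invisible(list(layers = lay, mspa = mspa, sources = src,
                 resistance = resist, corridors = corr, nodes = nodes,
                 metrics = metrics, out_dir = out_dir))
}
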