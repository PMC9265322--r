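#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow, with defaults matching
#' the published Zhengzhou study settings: foreground = paddy field,
#' woodland, grassland, water area and bottomland; MSPA edge width 1 cell;
#' dispersal-distance thresholds 100/500/1000/1500/2000 m with connectivity
#' probability 0.5 at the chosen threshold (1000 m); source selection at
#' dPC > 1; corridors shorter than 10 km dropped; gravity tier bounds
#' 1/10/100; ridge/valley accumulation quantile 0.95.
#'
#' @param foreground_classes Land-cover codes treated as MSPA foreground.
#' @param mspa_edge_width_cells Positive integer edge width, in cells.
#' @param mspa_connectivity 4 or 8; foreground connectivity for components.
#' @param thresholds_m Dispersal-distance thresholds swept, metres.
#' @param threshold_m The working threshold, metres.
#' @param connectivity_probability Dispersal probability at `threshold_m`.
#' @param min_dpc dPC percentage above which a patch is an ecological source.
#' @param min_core_area_cells Core components smaller than this are dropped.
#' @param corridor_min_length_km Minimum corridor length retained.
#' @param corridor_overlap_dedup Fractional cell overlap above which two
#'   paths count as duplicates.
#' @param gravity_tier_bounds Ascending bounds `(excluded|3, 3|2, 2|1)`.
#' @param gravity_area_unit `"ha"` or `"km2"`: unit fed to `ln` in the
#'   gravity model.
#' @param hydro_quantile Flow-accumulation quantile defining valley (and,
#'   on the inverted surface, ridge) cells.
#' @param node_merge_radius_cells Cluster radius when merging node cells.
#' @param resistance A [resistance_config()].
#' @param seed Integer seed governing every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(foreground_classes = c(1L, 3L, 4L, 5L, 6L),
                            mspa_edge_width_cells = 1L,
                            mspa_connectivity = 8L,
                            thresholds_m = c(100, 500, 1000, 1500, 2000),
                            threshold_m = 1000,
                            connectivity_probability = 0.5,
                            min_dpc = 1,
                            min_core_area_cells = 4L,
                            corridor_min_length_km = 10,
                            corridor_overlap_dedup = 0.9,
                            gravity_tier_bounds = c(1, 10, 100),
                            gravity_area_unit = "ha",
                            hydro_quantile = 0.95,
                            node_merge_radius_cells = 3L,
                            resistance = resistance_config(),
                            seed = 1L) {
  cfg <- list(foreground_classes = as.integer(foreground_classes),
              mspa_edge_width_cells = as.integer(mspa_edge_width_cells),
              mspa_connectivity = as.integer(mspa_connectivity),
              thresholds_m = as.numeric(thresholds_m),
              threshold_m = as.numeric(threshold_m),
              connectivity_probability = as.numeric(connectivity_probability),
              min_dpc = as.numeric(min_dpc),
              min_core_area_cells = as.integer(min_core_area_cells),
              corridor_min_length_km = as.numeric(corridor_min_length_km),
              corridor_overlap_dedup = as.numeric(corridor_overlap_dedup),
              gravity_tier_bounds = as.numeric(gravity_tier_bounds),
              gravity_area_unit = match.arg(gravity_area_unit, c("ha", "km2")),
              hydro_quantile = as.numeric(hydro_quantile),
              node_merge_radius_cells = as.integer(node_merge_radius_cells),
              resistance = resistance,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$foreground_classes) == 0) {
    abort_validation("`foreground_classes` must not be empty")
  }
  if (cfg$mspa_edge_width_cells < 1) {
    abort_validation("`mspa_edge_width_cells` must be >= 1")
  }
  if (!cfg$mspa_connectivity %in% c(4L, 8L)) {
    abort_validation("`mspa_connectivity` must be 4 or 8")
  }
  if (cfg$connectivity_probability <= 0 || cfg$connectivity_probability >= 1) {
    abort_validation("`connectivity_probability` must lie in (0, 1)")
  }
  if (length(cfg$gravity_tier_bounds) != 3 ||
      is.unsorted(cfg$gravity_tier_bounds, strictly = TRUE)) {
    abort_validation("`gravity_tier_bounds` must be three strictly increasing numbers")
  }
  if (cfg$hydro_quantile <= 0 || cfg$hydro_quantile >= 1) {
    abort_validation("`hydro_quantile` must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  res <- raw$resistance
  raw$resistance <- NULL
  args <- lapply(raw, unlist_keep_names)
  if (!is.null(res)) {
    args$resistance <- do.call(resistance_config, lapply(res, unlist_keep_names))
  }
  do.call(pipeline_config, args)
}

unlist_keep_names <- function(x) if (is.list(x)) unlist(x) else x

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) {
    lapply(x, unclass_deep)
  } else if (!is.null(names(x))) {
    as.list(x)          # yaml keeps map keys, not vector names
  } else {
    x
  }
}
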