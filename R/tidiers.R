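#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a patch graph into its per-patch importance table
#'
#' @param x A `patch_graph`.
#' @param ... Passed to [patch_importance()] (e.g. `index`).
#' @return Tibble of per-patch dLCP/dIIC/dPC percentages.
#' @export
tidy.patch_graph <- function(x, ...) {
  patch_importance(x, ...)
}

#' One-row summary of a patch graph
#'
#' @param x A `patch_graph`.
#' @param ... Unused.
#' @return Tibble with the whole-graph connectivity indices and settings.
#' @export
glance.patch_graph <- function(x, ...) {
  dplyr::bind_cols(connectivity_indices(x),
                   tibble::tibble(threshold_m = x$threshold,
                                  probability = x$probability,
                                  sl_km2 = x$sl))
}

#' Tidy a transition matrix into long format
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return Tibble `from`, `to`, `cells`, `area_km2`, `probability`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  nm <- rownames(x$counts)
  grid <- expand.grid(from = nm, to = nm, stringsAsFactors = FALSE)
  tibble::tibble(from = grid$from, to = grid$to,
                 cells = as.vector(x$counts),
                 area_km2 = as.vector(x$areas_km2),
                 probability = as.vector(x$probabilities))
}

#' One-row summary of a transition matrix
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return Tibble with total cells, fraction unchanged and class count.
#' @export
glance.transition_matrix <- function(x, ...) {
  tibble::tibble(n_cells = sum(x$counts),
                 fraction_unchanged = sum(diag(x$counts)) / sum(x$counts),
                 n_classes = nrow(x$counts))
}

#' Tidy a CA allocation result
#'
#' @param x A `ca_result`.
#' @param ... Unused.
#' @return Tibble of the per-iteration total absolute demand deficit.
#' @export
tidy.ca_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$deficit_trace) - 1L,
                 total_abs_deficit = x$deficit_trace)
}

#' One-row summary of a CA allocation result
#'
#' @param x A `ca_result`.
#' @param ... Unused.
#' @return Tibble with iterations used and final deficit.
#' @export
glance.ca_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 final_abs_deficit = utils::tail(x$deficit_trace, 1))
}
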