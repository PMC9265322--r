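#' Round half away from zero
#'
#' Plain decimal rounding (0.125 -> 0.13 at 2 digits), as used in printed
#' index tables, rather than R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny relative nudge so decimal halves stored just below .5 still go up
  sign(x) * floor(abs(x) * p * (1 + 1e-12) + 0.5) / p
}

#' Structural indices of a corridor-node network
#'
#' Classical graph indices of an ecological network with `L` corridors
#' (links) and `V` nodes: closure `alpha = (L - V + 1) / (2V - 5)`, node
#' connection rate `beta = L / V`, connectivity `gamma = L / (3 (V - 2))`,
#' and the length-efficiency `cost_ratio = 1 - L / C` with `C` the total
#' corridor length (km). `alpha` and `gamma` require `V >= 3` and are `NA`
#' otherwise; the cost ratio is `NA` when no lengths are given or `C = 0`.
#'
#' @param L Number of corridors.
#' @param V Number of nodes.
#' @param lengths_km Corridor lengths in km (any order).
#' @param label Optional subnetwork label.
#' @return One-row tibble `subnetwork`, `L`, `V`, `total_length_km`,
#'   `alpha`, `beta`, `gamma`, `cost_ratio` at full precision.
#' @export
evaluate_network <- function(L, V, lengths_km = numeric(0),
                             label = "network") {
  if (V < 0) abort_validation("`V` must be >= 0")
  if (L < 0) abort_validation("`L` must be >= 0")
  C <- sum(lengths_km)
  tibble::tibble(
    subnetwork = label, L = as.integer(L), V = as.integer(V),
    total_length_km = C,
    alpha = if (V >= 3) (L - V + 1) / (2 * V - 5) else NA_real_,
    beta = if (V >= 1) L / V else NA_real_,
    gamma = if (V >= 3) L / (3 * (V - 2)) else NA_real_,
    cost_ratio = if (length(lengths_km) && C > 0) 1 - L / C else NA_real_)
}

#' Split the network into the standard reported subnetworks
#'
#' Emits the three standard pairings -- level-1 corridors with strategic
#' nodes, level-2/3 corridors with natural nodes, level-2/3 corridors with
#' artificial nodes -- plus a whole-network row.
#'
#' @param corridors A `corridor_set` (rows with `level` NA are excluded
#'   corridors and never counted).
#' @param nodes A `node_set` tibble with a `node_type` column.
#' @return Tibble `subnetwork`, `L`, `V` and a `lengths_km` list-column.
#' @export
subnetworks <- function(corridors, nodes) {
  kept <- corridors[!is.na(corridors$level), ]
  pick <- function(levels_in, types) {
    list(L = sum(kept$level %in% levels_in),
         V = sum(nodes$node_type %in% types),
         lengths = kept$length_km[kept$level %in% levels_in])
  }
  defs <- list(
    `level1_strategic` = pick(1L, "strategic"),
    `level23_natural` = pick(c(2L, 3L), "natural"),
    `level23_artificial` = pick(c(2L, 3L), "artificial"),
    `whole_network` = list(L = nrow(kept), V = nrow(nodes),
                           lengths = kept$length_km))
  dplyr::bind_rows(lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    tibble::tibble(subnetwork = nm, L = as.integer(d$L), V = as.integer(d$V),
                   lengths_km = list(d$lengths))
  }))
}

#' Evaluate every subnetwork
#'
#' @param corridors A `corridor_set`.
#' @param nodes A `node_set`.
#' @param digits Decimal places of the rounded report columns.
#' @return Tibble with one row per subnetwork: full-precision indices plus
#'   `alpha_r`, `beta_r`, `gamma_r`, `cost_ratio_r` rounded half-up.
#' @export
evaluate_subnetworks <- function(corridors, nodes, digits = 2) {
  sn <- subnetworks(corridors, nodes)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(sn)), function(i) {
    evaluate_network(sn$L[i], sn$V[i], sn$lengths_km[[i]],
                     label = sn$subnetwork[i])
  }))
  dplyr::mutate(out,
                alpha_r = round_half_up(.data$alpha, digits),
                beta_r = round_half_up(.data$beta, digits),
                gamma_r = round_half_up(.data$gamma, digits),
                cost_ratio_r = round_half_up(.data$cost_ratio, digits))
}
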