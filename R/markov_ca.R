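#' Estimate a land-class transition matrix from two dates
#'
#' Cross-tabulates per-cell class pairs between an earlier and a later
#' raster.
#'
#' @param a,b Aligned `land_cover` rasters with the same legend.
#' @return A `transition_matrix`: list with `counts` (class x class),
#'   row-stochastic `probabilities`, `areas_km2`, and the legend.
#' @export
estimate_transitions <- function(a, b) {
  stopifnot(inherits(a, "land_cover"), inherits(b, "land_cover"))
  if (!identical(a$legend, b$legend)) {
    abort_validation("legend mismatch between rasters")
  }
  if (!all(dim(a$values) == dim(b$values))) {
    abort_validation("rasters must share shape")
  }
  ok <- !is.na(a$values) & !is.na(b$values)
  lv <- unname(a$legend)
  counts <- table(factor(a$values[ok], levels = lv),
                  factor(b$values[ok], levels = lv))
  counts <- matrix(as.numeric(counts), length(lv), length(lv),
                   dimnames = list(names(a$legend), names(a$legend)))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- 0
  diag(probs)[rs == 0] <- 1      # absent classes stay put
  structure(list(counts = counts, probabilities = probs,
                 areas_km2 = counts * (a$cell_size / 1000)^2,
                 legend = a$legend),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> cells:", sum(x$counts), "\n")
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Off-diagonal transfer-area table
#'
#' Long-format area (km2) moved between distinct classes, the layout used
#' for reporting land transfer between two dates.
#'
#' @param tm A `transition_matrix`.
#' @return Tibble `from`, `to`, `area_km2` with `from != to`.
#' @export
transfer_table <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  as.data.frame.table(tm$areas_km2, responseName = "area_km2") |>
    tibble::as_tibble() |>
    rlang::set_names(c("from", "to", "area_km2")) |>
    dplyr::mutate(from = as.character(.data$from),
                  to = as.character(.data$to)) |>
    dplyr::filter(.data$from != .data$to)
}

#' Project class demand by Markov chain
#'
#' `demand = current %*% P^steps`, rounded to integers with
#' largest-remainder correction so the total cell count is conserved
#' exactly.
#'
#' @param tm A `transition_matrix` (its `probabilities` are used).
#' @param current Named vector of current class cell counts (legend order).
#' @param steps Number of matrix applications (>= 1).
#' @return Tibble `class`, `current`, `demand`.
#' @export
project_demand <- function(tm, current, steps = 1L) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (steps < 1) abort_validation("`steps` must be >= 1")
  P <- tm$probabilities
  Pk <- diag(nrow(P))
  for (i in seq_len(steps)) Pk <- Pk %*% P
  raw <- as.vector(current %*% Pk)
  demand <- largest_remainder_round(raw, sum(current))
  tibble::tibble(class = rownames(P), current = as.numeric(current),
                 demand = demand)
}

largest_remainder_round <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  out <- fl
  if (rem > 0) {
    give <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    out[give] <- out[give] + 1
  }
  as.numeric(out)
}

#' Multinomial-logistic land-suitability surfaces
#'
#' Pluggable default for the per-class development-probability layer of the
#' cellular automaton: a multinomial logistic model of the later class
#' given predictor rasters, fitted on a seeded subsample of cells and
#' evaluated everywhere, normalised per cell.
#'
#' @param predictors Named list of continuous `eco_grid`s.
#' @param training A `land_cover` providing the response classes (typically
#'   the later date of a calibration pair).
#' @param sample_frac Fraction of cells used for fitting (default 1%).
#' @param seed Integer seed for the subsample.
#' @return Named list of `eco_grid`s, one per legend class, per-cell sums
#'   equal to 1.
#' @export
default_suitability <- function(predictors, training, sample_frac = 0.01,
                                seed = 1L) {
  stopifnot(inherits(training, "land_cover"), length(predictors) >= 1)
  X <- do.call(cbind, lapply(predictors, function(g) as.vector(g$values)))
  colnames(X) <- names(predictors)
  y <- as.vector(training$values)
  ok <- stats::complete.cases(X) & !is.na(y)
  legend <- training$legend
  prior <- vapply(legend, function(k) mean(y[ok] == k), numeric(1))
  classes_present <- names(legend)[prior > 0]
  mk <- function(m) eco_grid(m, cell_size = training$cell_size,
                             origin = training$origin,
                             crs_tag = training$crs_tag)
  dims <- dim(training$values)
  uniform_out <- function() {
    lapply(stats::setNames(nm = names(legend)), function(k) {
      p <- if (sum(prior) > 0) prior[[k]] else 1 / length(legend)
      mk(matrix(p, dims[1], dims[2]))
    })
  }
  if (length(classes_present) < 2) {
    warning("training raster has a single class; returning uniform suitability")
    return(uniform_out())
  }
  withr_seed(seed, {
    idx <- which(ok)
    n <- max(50L, ceiling(sample_frac * length(idx)))
    samp <- sample(idx, min(n, length(idx)))
    df <- data.frame(y = droplevels(factor(y[samp], levels = unname(legend))),
                     X[samp, , drop = FALSE])
    fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300)
    newdata <- data.frame(X)
    pr <- stats::predict(fit, newdata = newdata, type = "probs")
    if (is.null(dim(pr))) {                      # 2-class case
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- levels(df$y)
    }
    out <- lapply(stats::setNames(nm = names(legend)), function(k) {
      code <- as.character(legend[[k]])
      m <- if (code %in% colnames(pr)) {
        matrix(pr[, code], dims[1], dims[2])
      } else {
        matrix(0, dims[1], dims[2])
      }
      m[is.na(training$values)] <- NA
      mk(m)
    })
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cellular-automaton demand allocation
#'
#' Iteratively converts cells until per-class counts approach the demand
#' targets. Each iteration scores every convertible cell for every class as
#' `suitability x neighbourhood density x class inertia`, where the
#' neighbourhood density is the fraction of the k x k window already in the
#' class and the inertia multiplier is raised (lowered) for classes still
#' under (over) their demand. Cells are converted by seeded roulette over a
#' random subset each iteration; restricted cells never change. Iteration
#' stops when every class is within `tolerance` of demand or at
#' `max_iter`.
#'
#' @param current A `land_cover` starting raster.
#' @param suitability Named list of per-class probability `eco_grid`s (see
#'   [default_suitability()]).
#' @param demand Tibble from [project_demand()] (`class`, `demand`).
#' @param restricted Optional logical matrix; `TRUE` cells are frozen.
#' @param convertibility Optional 0/1 class x class matrix (legend order);
#'   0 forbids that conversion. Default allows everything except
#'   construction land reverting to water.
#' @param neighborhood Odd window size (default 3).
#' @param tolerance Relative demand tolerance (default 0.005).
#' @param max_iter Iteration cap (default 300).
#' @param change_frac Fraction of convertible cells scored per iteration.
#' @param seed Integer seed.
#' @return A `ca_result`: list with the allocated `land_cover`, the
#'   per-iteration deficit trace, and the iteration count.
#' @export
ca_allocate <- function(current, suitability, demand, restricted = NULL,
                        convertibility = NULL, neighborhood = 3L,
                        tolerance = 0.005, max_iter = 300L,
                        change_frac = 0.05, seed = 1L) {
  stopifnot(inherits(current, "land_cover"))
  legend <- current$legend
  K <- length(legend)
  if (neighborhood %% 2 != 1) abort_validation("`neighborhood` must be odd")
  dem <- stats::setNames(demand$demand, demand$class)[names(legend)]
  v <- current$values
  n_valid <- sum(!is.na(v))
  if (abs(sum(dem) - n_valid) > 1e-9) {
    abort_validation(sprintf(
      "demand total (%g) does not match valid cell count (%d)",
      sum(dem), n_valid))
  }
  if (is.null(convertibility)) {
    convertibility <- matrix(1, K, K, dimnames = list(names(legend),
                                                      names(legend)))
    convertibility["construction_land", "water_area"] <- 0
  }
  if (is.null(restricted)) restricted <- matrix(FALSE, nrow(v), ncol(v))
  suit <- vapply(names(legend), function(k) as.vector(suitability[[k]]$values),
                 numeric(length(v)))
  half <- (neighborhood - 1L) / 2L
  counts_of <- function(m) {
    vapply(unname(legend), function(code) sum(m == code, na.rm = TRUE),
           numeric(1))
  }
  inertia <- rep(1, K)
  trace <- numeric(0)
  withr_seed(seed, {
    it <- 0L
    repeat {
      cnt <- counts_of(v)
      deficit <- dem - cnt
      trace <- c(trace, sum(abs(deficit)))
      if (all(abs(deficit) <= pmax(tolerance * pmax(dem, 1), 0.5)) ||
          it >= max_iter) break
      it <- it + 1L
      # class-level inertia follows the remaining deficit
      inertia <- inertia * exp(0.2 * sign(deficit) *
                                 pmin(abs(deficit) / pmax(dem, 1), 1))
      inertia <- pmin(pmax(inertia, 1e-3), 1e3)
      dens <- neighborhood_density(v, legend, half)
      convertible <- which(!is.na(v) & !restricted)
      donors <- names(legend)[deficit < 0]
      pool <- convertible[v[convertible] %in% legend[donors]]
      if (!length(pool)) break
      npick <- max(1L, ceiling(change_frac * length(pool)))
      pick <- sample(pool, min(npick, length(pool)))
      gain <- names(legend)[deficit > 0]
      if (!length(gain)) break
      for (cell in pick) {
        from_k <- which(unname(legend) == v[cell])
        if (deficit[from_k] >= 0) next   # donor already balanced

        score <- vapply(gain, function(kn) {
          k <- which(names(legend) == kn)
          if (convertibility[from_k, k] == 0) return(0)
          s <- suit[cell, k]
          if (is.na(s)) s <- 0
          s * (0.05 + dens[cell, k]) * inertia[k]
        }, numeric(1))
        if (all(score <= 0)) next
        new_k <- gain[sample.int(length(gain), 1, prob = score / sum(score))]
        # never overshoot a class's demand within an iteration
        k_idx <- which(names(legend) == new_k)
        if (deficit[k_idx] <= 0) next
        deficit[k_idx] <- deficit[k_idx] - 1
        deficit[from_k] <- deficit[from_k] + 1
        v[cell] <- legend[[new_k]]
      }
    }
    out <- current
    out$values <- v
    structure(list(landcover = out, deficit_trace = trace, iterations = it),
              class = "ca_result")
  })
}

neighborhood_density <- function(v, legend, half) {
  K <- length(legend)
  out <- matrix(0, length(v), K)
  tot <- matrix(0, nrow(v), ncol(v))
  shifts <- expand.grid(dr = -half:half, dc = -half:half)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  acc <- vector("list", K)
  for (k in seq_len(K)) acc[[k]] <- matrix(0, nrow(v), ncol(v))
  for (s in seq_len(nrow(shifts))) {
    sh <- shift_mat(v, shifts$dr[s], shifts$dc[s], NA)
    valid <- !is.na(sh)
    tot <- tot + valid
    for (k in seq_len(K)) {
      acc[[k]] <- acc[[k]] + (valid & sh == legend[[k]])
    }
  }
  for (k in seq_len(K)) out[, k] <- as.vector(acc[[k]] / pmax(tot, 1))
  out
}

#' Agreement between two categorical rasters
#'
#' Overall accuracy and Cohen's kappa from the cell-by-cell confusion
#' matrix.
#'
#' @param reference,simulated Aligned `land_cover` rasters sharing a legend.
#' @return One-row tibble `overall_accuracy`, `kappa`, `n_cells`.
#' @export
agreement <- function(reference, simulated) {
  stopifnot(inherits(reference, "land_cover"), inherits(simulated, "land_cover"))
  if (!identical(reference$legend, simulated$legend)) {
    abort_validation("legend mismatch")
  }
  ok <- !is.na(reference$values) & !is.na(simulated$values)
  lv <- unname(reference$legend)
  conf <- table(factor(reference$values[ok], levels = lv),
                factor(simulated$values[ok], levels = lv))
  n <- sum(conf)
  oa <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  tibble::tibble(overall_accuracy = oa,
                 kappa = if (pe < 1) (oa - pe) / (1 - pe) else 1,
                 n_cells = as.integer(n))
}
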