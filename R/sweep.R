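#' Configure a (beta, delta) parameter sweep
#'
#' Bundles everything one sweep needs: the performance distribution, colony
#' size, the `beta` and `delta` grids, the active-worker-count grid, the
#' number of Monte-Carlo replicates, the efficiency mode and the base seed.
#' Defaults are the study protocol: production cost 100 units per worker,
#' `beta` from 0.1 to 1 in steps of 0.05, `delta` from 0 to 10 in steps of
#' 0.1, active counts from 10 up to `n_workers` in steps of 5, and 1000
#' replicates.
#'
#' @param distribution A [dist_spec()].
#' @param n_workers Colony size (study values: 50, 500, 5000).
#' @param beta_grid Increasing values in \[0, 1\].
#' @param delta_grid Increasing values >= 0.
#' @param k_grid Increasing integer active-worker counts; must contain
#'   `n_workers` (appended automatically for the default grid). `NULL` for
#'   the default `seq(10, n_workers, by = 5)`.
#' @param n_replicates Replicates per (beta, delta) cell.
#' @param mode `"ratio"` (performance / cost) or `"difference"`
#'   (performance - cost).
#' @param base_seed Integer seed; every replicate draws from an independent
#'   L'Ecuyer-CMRG substream derived from it, so results are reproducible
#'   and independent of evaluation order.
#' @param production_cost Per-worker production cost (default 100).
#' @param common_random_numbers If `TRUE` (default) the same replicate
#'   samples are reused across all (beta, delta) cells, so differences
#'   between cells reflect the cost parameters rather than sampling noise;
#'   if `FALSE` each cell consumes fresh substreams.
#' @return A `sweep_config` object.
#' @examples
#' sweep_config(dist_spec("right_skew"), n_workers = 500)
#' @export
sweep_config <- function(distribution, n_workers,
                         beta_grid = seq(0.1, 1, by = 0.05),
                         delta_grid = seq(0, 10, by = 0.1),
                         k_grid = NULL,
                         n_replicates = 1000,
                         mode = c("ratio", "difference"),
                         base_seed = 1L,
                         production_cost = 100,
                         common_random_numbers = TRUE) {
  stopifnot(inherits(distribution, "dist_spec"))
  mode <- match.arg(mode)
  if (length(n_workers) != 1L || n_workers < 1 || n_workers != floor(n_workers)) {
    stop("`n_workers` must be a positive integer", call. = FALSE)
  }
  n_workers <- as.integer(n_workers)
  if (length(beta_grid) == 0 || is.unsorted(beta_grid, strictly = TRUE) ||
      any(beta_grid < 0) || any(beta_grid > 1)) {
    stop("`beta_grid` must be non-empty, strictly increasing, within [0, 1]",
         call. = FALSE)
  }
  if (length(delta_grid) == 0 || is.unsorted(delta_grid, strictly = TRUE) ||
      any(delta_grid < 0)) {
    stop("`delta_grid` must be non-empty, strictly increasing, >= 0", call. = FALSE)
  }
  if (is.null(k_grid)) {
    k_grid <- if (n_workers <= 10) seq_len(n_workers) else seq(10L, n_workers, by = 5L)
    if (k_grid[length(k_grid)] != n_workers) k_grid <- c(k_grid, n_workers)
  }
  k_grid <- as.integer(k_grid)
  if (is.unsorted(k_grid, strictly = TRUE) || any(k_grid < 1) ||
      any(k_grid > n_workers) || !n_workers %in% k_grid) {
    stop("`k_grid` must be strictly increasing in [1, n_workers] and contain n_workers",
         call. = FALSE)
  }
  if (length(n_replicates) != 1L || n_replicates < 1 ||
      n_replicates != floor(n_replicates)) {
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  }
  if (production_cost <= 0) stop("`production_cost` must be > 0", call. = FALSE)
  structure(
    list(distribution = distribution, n_workers = n_workers,
         beta_grid = as.numeric(beta_grid), delta_grid = as.numeric(delta_grid),
         k_grid = k_grid, n_replicates = as.integer(n_replicates),
         mode = mode, base_seed = as.integer(base_seed),
         production_cost = as.numeric(production_cost),
         common_random_numbers = isTRUE(common_random_numbers)),
    class = "sweep_config"
  )
}

#' @export
print.sweep_config <- function(x, ...) {
  cat("<sweep_config>\n")
  cat("  distribution :", x$distribution$kind, "\n")
  cat("  n_workers    :", x$n_workers, "\n")
  cat(sprintf("  beta grid    : %g..%g (%d values)\n",
              min(x$beta_grid), max(x$beta_grid), length(x$beta_grid)))
  cat(sprintf("  delta grid   : %g..%g (%d values)\n",
              min(x$delta_grid), max(x$delta_grid), length(x$delta_grid)))
  cat(sprintf("  k grid       : %d..%d (%d values)\n",
              min(x$k_grid), max(x$k_grid), length(x$k_grid)))
  cat("  replicates   :", x$n_replicates, " mode:", x$mode,
      " seed:", x$base_seed, "\n")
  invisible(x)
}

# One independent L'Ecuyer-CMRG RNG state per replicate, derived
# deterministically from the base seed; `skip` advances past streams already
# consumed (used when common random numbers are off).
replicate_streams <- function(base_seed, n, skip = 0L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  suppressWarnings(set.seed(base_seed, kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(skip)) s <- parallel::nextRNGStream(s)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

# Run `f()` with the RNG state `stream`, restoring the caller's state after.
with_rng_stream <- function(stream, f) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  assign(".Random.seed", stream, envir = globalenv())
  f()
}

#' Draw the replicate performance samples for a sweep
#'
#' Each replicate's colony is an independent draw of `n_workers`
#' performances from the configured distribution, generated on its own RNG
#' substream so that replicate `r` is reproducible regardless of how many
#' other replicates are evaluated.
#'
#' @param config A [sweep_config()].
#' @param stream_offset Number of substreams to skip before the first
#'   replicate (used internally when fresh samples are drawn per grid cell).
#' @return A numeric matrix with `n_replicates` rows and `n_workers`
#'   columns, class `performance_replicates`.
#' @export
run_replicates <- function(config, stream_offset = 0L) {
  stopifnot(inherits(config, "sweep_config"))
  streams <- replicate_streams(config$base_seed, config$n_replicates, stream_offset)
  m <- matrix(NA_real_, nrow = config$n_replicates, ncol = config$n_workers)
  for (r in seq_len(config$n_replicates)) {
    m[r, ] <- with_rng_stream(streams[[r]], function() {
      sample_performances(config$distribution, config$n_workers)$performance
    })
  }
  structure(m, class = c("performance_replicates", "matrix", "array"),
            distribution = config$distribution, base_seed = config$base_seed)
}

# Replicates x k_grid matrix of top-k performance sums (sort once per
# replicate, read the prefix sums at every k).
topk_prefix_matrix <- function(samples, k_grid) {
  out <- matrix(NA_real_, nrow = nrow(samples), ncol = length(k_grid))
  for (r in seq_len(nrow(samples))) {
    out[r, ] <- cumsum(sort.int(samples[r, ], decreasing = TRUE))[k_grid]
  }
  out
}

# Core of aggregate_curve operating on a precomputed top-k matrix, so
# run_sweep can share one matrix across all grid cells. In ratio mode the
# per-replicate normalized efficiency factorizes exactly as
# (P_rk / P_rN) * (C_N / C_k), so replicate statistics of P_rk / P_rN can
# also be shared across cells (passed as `ratio_stats`).
aggregate_curve_core <- function(topk, beta, delta, config, ratio_stats = NULL) {
  kk <- config$k_grid
  nk <- length(kk)
  params <- cost_params(config$production_cost, delta = delta, beta = beta)
  cost <- colony_cost(params, kk, config$n_workers)
  if (config$mode == "ratio") {
    if (is.null(ratio_stats)) ratio_stats <- topk_ratio_stats(topk)
    cost_ratio <- cost[nk] / cost
    mean_norm <- ratio_stats$mean * cost_ratio
    sd_norm <- ratio_stats$sd * cost_ratio
    normalized <- TRUE
  } else {
    eff <- topk - rep(cost, each = nrow(topk))
    ref <- eff[, nk]
    normalized <- all(ref > 0)
    if (normalized) eff <- eff / ref
    mean_norm <- colMeans(eff)
    sd_norm <- apply(eff, 2, stats::sd)
  }
  out <- tibble::tibble(
    beta = beta, delta = delta,
    k = kk, active_fraction = kk / config$n_workers,
    mean_normalized_efficiency = mean_norm,
    sd_normalized_efficiency = sd_norm
  )
  attr(out, "mode") <- config$mode
  attr(out, "distribution") <- config$distribution
  attr(out, "n_workers") <- config$n_workers
  attr(out, "n_replicates") <- nrow(topk)
  attr(out, "normalized") <- normalized
  class(out) <- c("efficiency_curve", class(out))
  out
}

topk_ratio_stats <- function(topk) {
  q <- topk / topk[, ncol(topk)]
  list(mean = colMeans(q), sd = apply(q, 2, stats::sd))
}

#' Replicate-averaged normalized efficiency curve
#'
#' For one (beta, delta) pair, computes each replicate's normalized
#' efficiency curve over the configured `k_grid` and averages pointwise
#' across replicates; the per-k standard deviation across replicates is
#' recorded alongside. In difference mode, if any replicate's all-active
#' efficiency is not positive, raw (unnormalized) differences are aggregated
#' instead and the curve's `normalized` attribute is `FALSE`; the location
#' of the maximum is unaffected for any fixed replicate.
#'
#' @param samples A [run_replicates()] matrix.
#' @param beta,delta Cost parameters for this cell.
#' @param config The [sweep_config()] the samples were drawn under.
#' @return A tibble of class `efficiency_curve` with columns `beta`,
#'   `delta`, `k`, `active_fraction`, `mean_normalized_efficiency`,
#'   `sd_normalized_efficiency`; the mode, distribution, colony size,
#'   replicate count, normalization flag and the per-replicate argmax
#'   fractions (`replicate_argmax`) are attached as attributes.
#' @export
aggregate_curve <- function(samples, beta, delta, config) {
  stopifnot(inherits(config, "sweep_config"), is.matrix(samples))
  topk <- topk_prefix_matrix(samples, config$k_grid)
  out <- aggregate_curve_core(topk, beta, delta, config)
  attr(out, "replicate_argmax") <- replicate_argmax_fractions(topk, beta, delta, config)
  out
}

# Diagnostic: the argmax fraction of every replicate's own normalized curve.
replicate_argmax_fractions <- function(topk, beta, delta, config) {
  kk <- config$k_grid
  params <- cost_params(config$production_cost, delta = delta, beta = beta)
  cost <- colony_cost(params, kk, config$n_workers)
  eff <- if (config$mode == "ratio") {
    topk / rep(cost, each = nrow(topk))
  } else {
    topk - rep(cost, each = nrow(topk))
  }
  idx <- apply(eff, 1, function(v) max(which(v == max(v))))
  kk[idx] / config$n_workers
}

#' Optimal active fraction of an efficiency curve
#'
#' Reads off the active fraction `k*/N` maximizing the mean normalized
#' efficiency. Exact ties are broken toward the largest `k`: when keeping
#' workers inactive saves nothing, the colony activates everyone.
#'
#' @param curve An [aggregate_curve()] (or [normalized_efficiency_curve()])
#'   tibble.
#' @return The optimal active fraction, a number in (0, 1\].
#' @export
optimal_active_fraction <- function(curve) {
  val <- if ("mean_normalized_efficiency" %in% names(curve)) {
    curve$mean_normalized_efficiency
  } else {
    curve$normalized_efficiency
  }
  curve$active_fraction[max(which(val == max(val)))]
}

#' Run a full (beta, delta) parameter sweep
#'
#' For every (beta, delta) pair in the configured grids, aggregates the
#' replicate efficiency curves and locates the optimal active fraction,
#' producing the data behind the optimal-activity heat maps. With common
#' random numbers (the default) all cells share one set of replicate
#' samples; the top-k prefix sums are computed once and reused, so a full
#' default grid (19 x 101 cells) runs in seconds in ratio mode.
#'
#' @param config A [sweep_config()].
#' @param per_replicate If `TRUE`, also record each cell's per-replicate
#'   argmax distribution (list-column `replicate_argmax`); off by default as
#'   it defeats the shared-statistics fast path.
#' @param verbose If `TRUE`, print one progress line per `beta` row.
#' @return A `sweep_result` object: a list with `grid` (tibble with one row
#'   per (beta, delta) cell: `distribution`, `n_workers`, `mode`, `beta`,
#'   `delta`, `optimal_active_fraction`, `efficiency_at_optimum`) and
#'   `config`. Rows are ordered beta-major, then delta.
#' @examples
#' cfg <- sweep_config(dist_spec("uniform"), n_workers = 50,
#'                     beta_grid = c(0.2, 1), delta_grid = c(0, 2),
#'                     n_replicates = 20)
#' run_sweep(cfg)
#' @export
run_sweep <- function(config, per_replicate = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  nb <- length(config$beta_grid)
  nd <- length(config$delta_grid)
  n_cells <- nb * nd
  topk <- NULL
  ratio_stats <- NULL
  if (config$common_random_numbers) {
    samples <- run_replicates(config)
    topk <- topk_prefix_matrix(samples, config$k_grid)
    if (config$mode == "ratio") ratio_stats <- topk_ratio_stats(topk)
  }
  opt_frac <- numeric(n_cells)
  opt_eff <- numeric(n_cells)
  beta_col <- numeric(n_cells)
  delta_col <- numeric(n_cells)
  argmax_list <- if (per_replicate) vector("list", n_cells)
  cell <- 0L
  for (b in config$beta_grid) {
    if (verbose) message(sprintf("beta = %.2f (%d/%d rows)", b,
                                 match(b, config$beta_grid), nb))
    for (d in config$delta_grid) {
      cell <- cell + 1L
      cell_topk <- if (config$common_random_numbers) {
        topk
      } else {
        cs <- run_replicates(config,
                             stream_offset = (cell - 1L) * config$n_replicates)
        topk_prefix_matrix(cs, config$k_grid)
      }
      curve <- aggregate_curve_core(cell_topk, b, d, config,
                                    ratio_stats = ratio_stats)
      val <- curve$mean_normalized_efficiency
      i <- max(which(val == max(val)))
      beta_col[cell] <- b
      delta_col[cell] <- d
      opt_frac[cell] <- curve$active_fraction[i]
      opt_eff[cell] <- val[i]
      if (per_replicate) {
        argmax_list[[cell]] <- replicate_argmax_fractions(cell_topk, b, d, config)
      }
    }
  }
  grid <- tibble::tibble(
    distribution = config$distribution$kind,
    n_workers = config$n_workers,
    mode = config$mode,
    beta = beta_col, delta = delta_col,
    optimal_active_fraction = opt_frac,
    efficiency_at_optimum = opt_eff
  )
  if (per_replicate) grid$replicate_argmax <- argmax_list
  structure(list(grid = grid, config = config), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", x$config$distribution$kind,
      sprintf("N = %d, %s mode, %d replicates\n",
              x$config$n_workers, x$config$mode, x$config$n_replicates))
  cat(sprintf("  %d (beta, delta) cells; optimal active fraction in [%.3g, %.3g]\n",
              nrow(x$grid), min(x$grid$optimal_active_fraction),
              max(x$grid$optimal_active_fraction)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sweep result into one row per (beta, delta) cell
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return The heat-map grid tibble.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) x$grid

#' One-row summary of a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble: distribution, colony size, mode, replicate
#'   count, number of grid cells, the range of the optimal active fraction,
#'   and the share of cells where some inactivity is optimal
#'   (`prop_inactivity_favoured`).
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    distribution = x$config$distribution$kind,
    n_workers = x$config$n_workers,
    mode = x$config$mode,
    n_replicates = x$config$n_replicates,
    n_cells = nrow(g),
    min_optimal_fraction = min(g$optimal_active_fraction),
    max_optimal_fraction = max(g$optimal_active_fraction),
    prop_inactivity_favoured = mean(g$optimal_active_fraction < 1)
  )
}
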