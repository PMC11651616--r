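#' Colony cost parameters
#'
#' A worker costs `production_cost` arbitrary units to produce, and
#' `delta * production_cost` units to maintain over its lifetime if active.
#' Inactive workers are cheaper to maintain by the factor `beta`: the total
#' colony cost with `k` of `N` workers active is
#'
#'   `production_cost * N + delta * production_cost * (k + beta * (N - k))`
#'
#' @param production_cost Per-worker production cost, > 0 (default 100).
#' @param delta Maintenance/production cost ratio, >= 0.
#' @param beta Inactive/active maintenance cost ratio, in \[0, 1\].
#' @return A `cost_params` object.
#' @examples
#' cost_params(delta = 2, beta = 0.2)
#' @export
cost_params <- function(production_cost = 100, delta, beta) {
  if (!is.numeric(production_cost) || length(production_cost) != 1L ||
      !is.finite(production_cost) || production_cost <= 0) {
    stop("`production_cost` must be a single number > 0", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta < 0) {
    stop("`delta` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0 || beta > 1) {
    stop("`beta` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(production_cost = production_cost, delta = delta, beta = beta),
            class = "cost_params")
}

#' @export
print.cost_params <- function(x, ...) {
  cat(sprintf("<cost_params> production_cost = %g, delta = %g, beta = %g\n",
              x$production_cost, x$delta, x$beta))
  invisible(x)
}

# Extract the raw performance vector from a performance_sample tibble, a
# plain data frame with a `performance` column, or a numeric vector.
performance_values <- function(sample) {
  if (is.numeric(sample)) return(as.numeric(sample))
  if (is.data.frame(sample) && "performance" %in% names(sample)) {
    return(sample$performance)
  }
  stop("`sample` must be a performance_sample (or numeric vector)", call. = FALSE)
}

#' Total colony cost for a given activity allocation
#'
#' @param params A [cost_params()].
#' @param n_active Number of active workers `k`, `0 < k <= n_total`.
#' @param n_total Colony size `N`.
#' @return Cost in the same units as `production_cost` (vectorized over
#'   `n_active`).
#' @examples
#' colony_cost(cost_params(100, delta = 2, beta = 0.2), n_active = 4, n_total = 10)
#' @export
colony_cost <- function(params, n_active, n_total) {
  stopifnot(inherits(params, "cost_params"))
  if (any(n_active < 1) || any(n_active > n_total)) {
    stop("`n_active` must satisfy 1 <= n_active <= n_total", call. = FALSE)
  }
  cp <- params$production_cost
  cp * n_total + params$delta * cp * (n_active + params$beta * (n_total - n_active))
}

#' Colony performance under top-k activation
#'
#' The `k` workers with the highest individual performance are activated and
#' the colony's performance is the sum of their performances. Selecting the
#' top `k` maximizes the sum over all size-`k` subsets; ties at the k-th rank
#' are broken by worker index, which leaves the sum unchanged.
#'
#' @param sample A [sample_performances()] result (or numeric vector).
#' @param k Number of active workers, `1 <= k <= n` (vectorized).
#' @return Sum of the `k` largest performances, per element of `k`.
#' @examples
#' colony_performance(c(0.9, 0.5, 0.1), k = 2)  # 1.4
#' @export
colony_performance <- function(sample, k) {
  x <- performance_values(sample)
  if (any(k < 1) || any(k > length(x)) || any(k != floor(k))) {
    stop("`k` must be an integer in [1, n]", call. = FALSE)
  }
  cumsum(sort(x, decreasing = TRUE))[k]
}

#' Identify the active workers
#'
#' @inheritParams colony_performance
#' @param k Single number of active workers.
#' @return A tibble with columns `worker`, `performance`, `active`; exactly
#'   the `k` best performers are marked active (index-order tie-break).
#' @export
activity_allocation <- function(sample, k) {
  x <- performance_values(sample)
  n <- length(x)
  if (length(k) != 1L || k < 1 || k > n || k != floor(k)) {
    stop("`k` must be a single integer in [1, n]", call. = FALSE)
  }
  ord <- order(x, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  tibble::tibble(
    worker = seq_len(n),
    performance = x,
    active = seq_len(n) %in% ord[seq_len(k)]
  )
}

#' Colony efficiency
#'
#' Ratio mode divides colony performance by total colony cost; difference
#' mode subtracts the cost (and may be negative).
#'
#' @inheritParams colony_performance
#' @param params A [cost_params()].
#' @param mode `"ratio"` or `"difference"`.
#' @return Efficiency value(s), one per element of `k`.
#' @examples
#' colony_efficiency(rep(1, 4), k = 4, cost_params(1, delta = 1, beta = 1))  # 0.5
#' @export
colony_efficiency <- function(sample, k, params, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  x <- performance_values(sample)
  perf <- colony_performance(x, k)
  cost <- colony_cost(params, k, length(x))
  if (mode == "ratio") perf / cost else perf - cost
}

#' Normalized efficiency curve for one replicate
#'
#' Computes colony efficiency at every `k` in `k_grid` and normalizes by the
#' all-active value (`k = n`), which must therefore be part of the grid. In
#' ratio mode the curve equals 1 at `k = n` by construction. In difference
#' mode, if the all-active efficiency is not positive the raw
#' (unnormalized) curve is returned and flagged via the `normalized`
#' attribute (and column); the location of the maximum is unaffected.
#'
#' @inheritParams colony_efficiency
#' @param k_grid Increasing integer vector of active-worker counts,
#'   containing `n`.
#' @return A tibble of class `efficiency_curve` with columns `k`,
#'   `active_fraction`, `efficiency`, `normalized_efficiency`, `normalized`
#'   (logical); `params` and `mode` are attached as attributes.
#' @export
normalized_efficiency_curve <- function(sample, k_grid, params,
                                        mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  x <- performance_values(sample)
  n <- length(x)
  if (is.unsorted(k_grid, strictly = TRUE)) {
    stop("`k_grid` must be strictly increasing", call. = FALSE)
  }
  if (!n %in% k_grid) {
    stop("`k_grid` must contain n (the all-active normalization reference)",
         call. = FALSE)
  }
  eff <- colony_efficiency(x, k_grid, params, mode)
  ref <- eff[length(eff)]
  normalized <- mode == "ratio" || ref > 0
  out <- tibble::tibble(
    k = as.integer(k_grid),
    active_fraction = k_grid / n,
    efficiency = eff,
    normalized_efficiency = if (normalized) eff / ref else eff,
    normalized = normalized
  )
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  class(out) <- c("efficiency_curve", class(out))
  out
}
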