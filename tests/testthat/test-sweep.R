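small_config <- function(kind = "right_skew", n = 60, reps = 25, seed = 11, ...) {
  sweep_config(dist_spec(kind), n_workers = n,
               beta_grid = c(0.2, 0.6, 1), delta_grid = c(0, 1, 2, 5),
               n_replicates = reps, base_seed = seed, ...)
}

test_that("sweep configuration validates its grids", {
  expect_error(sweep_config(dist_spec("uniform"), 50, beta_grid = c(0.5, 1.5)),
               "beta_grid")
  expect_error(sweep_config(dist_spec("uniform"), 50, delta_grid = c(2, 1)),
               "delta_grid")
  expect_error(sweep_config(dist_spec("uniform"), 50, k_grid = c(10, 20)),
               "k_grid")
  expect_error(sweep_config(dist_spec("uniform"), 50, n_replicates = 0),
               "n_replicates")
  cfg <- sweep_config(dist_spec("uniform"), 503)
  expect_equal(cfg$k_grid[length(cfg$k_grid)], 503L)  # n appended to default grid
})

test_that("replicate draws are reproducible and seed-sensitive", {
  cfg <- small_config(reps = 3, n = 40)
  a <- run_replicates(cfg)
  b <- run_replicates(cfg)
  expect_identical(unclass(a), unclass(b))
  expect_equal(dim(a), c(3, 40))
  expect_false(any(duplicated(a)))  # replicates are distinct draws
  other <- run_replicates(small_config(reps = 3, n = 40, seed = 12))
  expect_false(identical(unclass(a), unclass(other)))
  # substreams are indexed, not sequential: an offset shifts the replicates
  shifted <- run_replicates(cfg, stream_offset = 1L)
  expect_identical(a[2, ], shifted[1, ])
})

test_that("the grand mean of uniform replicate draws is unbiased", {
  cfg <- sweep_config(dist_spec("uniform"), 100,
                      n_replicates = 200, base_seed = 3)
  m <- run_replicates(cfg)
  se <- (1 / sqrt(12)) / sqrt(length(m))
  expect_lt(abs(mean(m) - 0.5), 3 * se)
})

test_that("aggregating a single replicate reproduces that replicate's curve", {
  cfg <- small_config(reps = 1, n = 50)
  samples <- run_replicates(cfg)
  agg <- aggregate_curve(samples, beta = 0.2, delta = 2, cfg)
  direct <- normalized_efficiency_curve(
    samples[1, ], cfg$k_grid,
    cost_params(cfg$production_cost, delta = 2, beta = 0.2), mode = "ratio")
  expect_equal(agg$mean_normalized_efficiency, direct$normalized_efficiency)
})

test_that("the shared-statistics ratio path equals per-replicate averaging", {
  cfg <- small_config(reps = 20, n = 50)
  samples <- run_replicates(cfg)
  agg <- aggregate_curve(samples, beta = 0.35, delta = 3.2, cfg)
  pars <- cost_params(cfg$production_cost, delta = 3.2, beta = 0.35)
  curves <- sapply(seq_len(nrow(samples)), function(r) {
    normalized_efficiency_curve(samples[r, ], cfg$k_grid, pars,
                                mode = "ratio")$normalized_efficiency
  })
  expect_equal(agg$mean_normalized_efficiency, rowMeans(curves))
  expect_equal(agg$sd_normalized_efficiency, apply(curves, 1, sd))
})

test_that("difference-mode aggregation matches per-replicate averaging too", {
  cfg <- small_config(reps = 10, n = 40, mode = "difference")
  samples <- run_replicates(cfg)
  agg <- aggregate_curve(samples, beta = 0.2, delta = 2, cfg)
  pars <- cost_params(cfg$production_cost, delta = 2, beta = 0.2)
  curves <- sapply(seq_len(nrow(samples)), function(r) {
    normalized_efficiency_curve(samples[r, ], cfg$k_grid, pars,
                                mode = "difference")$normalized_efficiency
  })
  expect_false(attr(agg, "normalized"))  # cost dwarfs performance here
  expect_equal(agg$mean_normalized_efficiency, rowMeans(curves))
})

test_that("constant-cost cells put the optimum at full activity", {
  cfg <- small_config(reps = 10)
  samples <- run_replicates(cfg)
  for (cell in list(c(1, 2), c(0.4, 0))) {  # beta = 1, and delta = 0
    curve <- aggregate_curve(samples, beta = cell[1], delta = cell[2], cfg)
    expect_true(all(diff(curve$mean_normalized_efficiency) > 0))
    expect_equal(optimal_active_fraction(curve), 1)
  }
})

test_that("exact efficiency ties resolve toward full activity", {
  flat <- tibble::tibble(k = c(10, 20, 40), active_fraction = c(0.25, 0.5, 1),
                         mean_normalized_efficiency = c(1, 1, 1))
  expect_equal(optimal_active_fraction(flat), 1)
  interior <- tibble::tibble(k = c(10, 15, 20), active_fraction = c(0.5, 0.75, 1),
                             mean_normalized_efficiency = c(0.9, 1.2, 1))
  expect_equal(optimal_active_fraction(interior), 0.75)
})

test_that("a sweep is deterministic and covers the whole grid in order", {
  cfg <- small_config(reps = 8)
  r1 <- run_sweep(cfg)
  r2 <- run_sweep(cfg)
  expect_identical(r1$grid, r2$grid)
  g <- r1$grid
  expect_equal(nrow(g), 12)
  expect_equal(g$beta, rep(cfg$beta_grid, each = 4))  # beta-major ordering
  expect_true(all(g$optimal_active_fraction > 0 & g$optimal_active_fraction <= 1))
  expect_true(all(g$optimal_active_fraction[g$beta == 1] == 1))
  expect_true(all(g$optimal_active_fraction[g$delta == 0] == 1))
})

test_that("fresh samples per cell stay deterministic but differ from shared ones", {
  cfg_crn <- small_config(reps = 6, n = 40)
  cfg_fresh <- small_config(reps = 6, n = 40, common_random_numbers = FALSE)
  f1 <- run_sweep(cfg_fresh)
  f2 <- run_sweep(cfg_fresh)
  expect_identical(f1$grid, f2$grid)
  c1 <- run_sweep(cfg_crn)
  expect_false(identical(c1$grid$efficiency_at_optimum,
                         f1$grid$efficiency_at_optimum))
})

test_that("per-replicate argmax diagnostics are recorded on request", {
  cfg <- small_config(reps = 7)
  samples <- run_replicates(cfg)
  curve <- aggregate_curve(samples, beta = 0.2, delta = 2, cfg)
  am <- attr(curve, "replicate_argmax")
  expect_length(am, 7)
  expect_true(all(am > 0 & am <= 1))
  res <- run_sweep(cfg, per_replicate = TRUE)
  expect_true("replicate_argmax" %in% names(res$grid))
  expect_length(res$grid$replicate_argmax[[1]], 7)
})

test_that("optimal fractions order by distribution shape at delta = 2, beta = 0.2", {
  opts <- vapply(c("right_skew", "uniform", "normal", "left_skew"), function(kind) {
    cfg <- sweep_config(dist_spec(kind), 500, beta_grid = 0.2, delta_grid = c(0, 2),
                        n_replicates = 150, base_seed = 21)
    g <- run_sweep(cfg)$grid
    g$optimal_active_fraction[g$delta == 2]
  }, numeric(1))
  # right-skewed performance favours the most inactivity; left-skewed the least
  expect_lt(opts[["right_skew"]], opts[["uniform"]])
  expect_lt(opts[["right_skew"]], opts[["normal"]])
  expect_lt(opts[["right_skew"]], opts[["left_skew"]])
  expect_lt(opts[["uniform"]], opts[["normal"]])
  expect_lt(opts[["normal"]], opts[["left_skew"]])
})

test_that("optimal fractions are insensitive to colony size", {
  opts <- vapply(c(50, 500), function(n) {
    cfg <- sweep_config(dist_spec("right_skew"), n, beta_grid = 0.2,
                        delta_grid = c(0, 2), n_replicates = 300, base_seed = 5)
    g <- run_sweep(cfg)$grid
    g$optimal_active_fraction[g$delta == 2]
  }, numeric(1))
  expect_lt(abs(opts[1] - opts[2]), 0.1)
})

test_that("tidy, glance and autoplot expose the sweep result", {
  res <- run_sweep(small_config(reps = 5))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("distribution", "n_workers", "mode", "beta", "delta",
                     "optimal_active_fraction", "efficiency_at_optimum"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(gl$prop_inactivity_favoured >= 0 && gl$prop_inactivity_favoured <= 1)
  expect_s3_class(autoplot(res), "ggplot")
  samples <- run_replicates(small_config(reps = 5))
  curve <- aggregate_curve(samples, 0.2, 2, small_config(reps = 5))
  expect_s3_class(autoplot(curve), "ggplot")
})
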