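#' @importFrom rlang .data %||%
NULL

dist_keys <- c("kind", "mean", "sd", "mean1", "sd1", "mean2", "sd2",
               "weight1", "skewness", "truncation")
config_keys <- c("distribution", "n_workers", "beta_grid", "delta_grid",
                 "k_grid", "n_replicates", "mode", "base_seed",
                 "production_cost", "common_random_numbers")

# A grid in a config file is either an explicit value list or a
# {from, to, by} block.
parse_grid <- function(x, key) {
  if (is.list(x) && !is.null(names(x)) && all(names(x) != "")) {
    bad <- setdiff(names(x), c("from", "to", "by"))
    if (length(bad) > 0) {
      stop(sprintf("config key `%s`: unknown field(s) %s (expected from/to/by or a value list)",
                   key, paste0("`", bad, "`", collapse = ", ")), call. = FALSE)
    }
    seq(x$from, x$to, by = x$by)
  } else {
    as.numeric(unlist(x))
  }
}

config_error <- function(key, cond) {
  stop(sprintf("config key `%s`: %s", key, conditionMessage(cond)), call. = FALSE)
}

#' Load a sweep configuration from a YAML file
#'
#' The file holds the [sweep_config()] fields as flat keys, with the
#' distribution as a nested block (keys: kind, mean, sd, mean1, sd1, mean2,
#' sd2, weight1, skewness, truncation). Grids may be explicit value lists or
#' `{from, to, by}` blocks. Omitted keys take the study defaults
#' (production cost 100, beta 0.1--1 step 0.05, delta 0--10 step 0.1, 1000
#' replicates). Unknown or out-of-range keys raise an error naming the key.
#'
#' @param path Path to a YAML config file.
#' @return A validated [sweep_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste0("`", unknown, "`", collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$distribution) || is.null(raw$distribution$kind)) {
    stop("config key `distribution`: a `kind` is required", call. = FALSE)
  }
  if (is.null(raw$n_workers)) {
    stop("config key `n_workers` is required", call. = FALSE)
  }
  dl <- raw$distribution
  unknown <- setdiff(names(dl), dist_keys)
  if (length(unknown) > 0) {
    stop("unknown distribution key(s): ", paste0("`", unknown, "`", collapse = ", "),
         call. = FALSE)
  }
  spec <- tryCatch(do.call(dist_spec, dl),
                   error = function(e) config_error("distribution", e))
  args <- list(distribution = spec, n_workers = raw$n_workers)
  for (key in c("beta_grid", "delta_grid", "k_grid")) {
    if (!is.null(raw[[key]])) args[[key]] <- parse_grid(raw[[key]], key)
  }
  for (key in c("n_replicates", "mode", "base_seed", "production_cost",
                "common_random_numbers")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  tryCatch(do.call(sweep_config, args), error = function(e) {
    # sweep_config errors already name the offending field
    stop(conditionMessage(e), call. = FALSE)
  })
}

# Config echo used by manifests and config round-trips.
config_as_list <- function(config) {
  list(
    distribution = config$distribution[dist_keys],
    n_workers = config$n_workers,
    beta_grid = config$beta_grid,
    delta_grid = config$delta_grid,
    k_grid = config$k_grid,
    n_replicates = config$n_replicates,
    mode = config$mode,
    base_seed = config$base_seed,
    production_cost = config$production_cost,
    common_random_numbers = config$common_random_numbers
  )
}

#' Write a sweep configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces an identical configuration.
#'
#' @param config A [sweep_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sweep_config"))
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

# Shortest decimal representation that parses back to the identical double,
# so written CSVs round-trip exactly.
shortest_roundtrip <- function(x) {
  out <- sprintf("%.15g", x)
  for (digits in 16:17) {
    bad <- which(is.finite(x) & as.numeric(out) != x)
    if (length(bad) == 0) break
    out[bad] <- sprintf(paste0("%.", digits, "g"), x[bad])
  }
  out[is.na(x)] <- NA_character_
  out
}

write_csv_exact <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) shortest_roundtrip(col) else col
  })
  readr::write_csv(df, path)
}

curve_csv_columns <- c("distribution", "n_workers", "mode", "beta", "delta",
                       "k", "active_fraction", "mean_normalized_efficiency",
                       "sd_normalized_efficiency", "n_replicates")

#' Write efficiency curves to CSV
#'
#' Columns: distribution, n_workers, mode, beta, delta, k, active_fraction,
#' mean_normalized_efficiency, sd_normalized_efficiency, n_replicates.
#' Rows are sorted beta-major, then delta, then k. Values round-trip exactly
#' through [readr::read_csv()].
#'
#' @param curve An [aggregate_curve()] tibble, or several row-bound together.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- tibble::as_tibble(curve)
  if (!"distribution" %in% names(df)) {
    df$distribution <- attr(curve, "distribution")$kind
  }
  if (!"n_workers" %in% names(df)) df$n_workers <- attr(curve, "n_workers")
  if (!"mode" %in% names(df)) df$mode <- attr(curve, "mode")
  if (!"n_replicates" %in% names(df)) df$n_replicates <- attr(curve, "n_replicates")
  df <- dplyr::arrange(df[curve_csv_columns], .data$beta, .data$delta, .data$k)
  write_csv_exact(df, path)
  invisible(path)
}

heatmap_csv_columns <- c("distribution", "n_workers", "mode", "beta", "delta",
                         "optimal_active_fraction", "efficiency_at_optimum")

#' Write a sweep heat map to CSV
#'
#' Columns: distribution, n_workers, mode, beta, delta,
#' optimal_active_fraction, efficiency_at_optimum. Rows sorted beta-major,
#' then delta.
#'
#' @param result A `sweep_result` (or its `tidy()` grid).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(result, path) {
  grid <- if (inherits(result, "sweep_result")) result$grid else tibble::as_tibble(result)
  grid <- dplyr::arrange(grid[heatmap_csv_columns], .data$beta, .data$delta)
  write_csv_exact(grid, path)
  invisible(path)
}

read_csv_exact <- function(path, int_cols = character(0)) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  known_chr <- c("distribution", "mode")
  df[] <- lapply(seq_along(df), function(i) {
    nm <- names(df)[i]
    if (nm %in% known_chr) return(df[[i]])
    if (nm %in% int_cols) as.integer(df[[i]]) else as.numeric(df[[i]])
  })
  df
}

#' Read back curve and heat-map CSVs
#'
#' Inverse of [write_curve_csv()] and [write_heatmap_csv()]. Numeric fields
#' are parsed with R's correctly rounded decimal converter, so values
#' round-trip bit for bit.
#'
#' @param path A CSV written by the corresponding writer.
#' @return A tibble with the schema's columns and types.
#' @export
read_curve_csv <- function(path) {
  read_csv_exact(path, int_cols = c("n_workers", "k", "n_replicates"))
}

#' @rdname read_curve_csv
#' @export
read_heatmap_csv <- function(path) {
  read_csv_exact(path, int_cols = "n_workers")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-for-byte: the full
#' configuration echo, the package version, the base seed, start and end
#' timestamps, the command that produced the outputs and the output file
#' names (relative to the manifest's directory).
#'
#' @param config The [sweep_config()] used.
#' @param outputs Character vector of output file names.
#' @param path Manifest path (JSON).
#' @param command The CLI subcommand or calling context.
#' @param extra_args Named list of extra arguments (e.g. beta/delta for a
#'   single-curve run).
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, outputs, path, command = "sweep",
                           extra_args = list(), started = Sys.time(),
                           finished = Sys.time()) {
  manifest <- list(
    tool = "colonyidle",
    version = as.character(utils::packageVersion("colonyidle")),
    command = command,
    args = extra_args,
    base_seed = config$base_seed,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    config = config_as_list(config),
    outputs = as.character(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Re-run the computation described by a manifest
#'
#' Reconstructs the configuration from a manifest written by
#' [write_manifest()] and regenerates its CSV outputs into `out_dir`. With
#' the same package version this reproduces the original files byte for
#' byte.
#'
#' @param manifest_path Path to a manifest JSON.
#' @param out_dir Directory for the regenerated outputs.
#' @return Character vector of the regenerated file paths, invisibly.
#' @export
rerun_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cl <- man$config
  spec <- do.call(dist_spec, as.list(cl$distribution))
  config <- sweep_config(
    distribution = spec, n_workers = cl$n_workers,
    beta_grid = cl$beta_grid, delta_grid = cl$delta_grid,
    k_grid = cl$k_grid, n_replicates = cl$n_replicates, mode = cl$mode,
    base_seed = cl$base_seed, production_cost = cl$production_cost,
    common_random_numbers = cl$common_random_numbers
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_command(man$command, config, as.list(man$args), out_dir)
}

# Execute one subcommand's computation and write its outputs; shared by
# cli_main and rerun_manifest so manifests replay exactly.
run_command <- function(command, config, args, out_dir) {
  out <- switch(
    command,
    sample = {
      samples <- run_replicates(config)
      df <- tibble::tibble(
        distribution = config$distribution$kind,
        replicate = rep(seq_len(nrow(samples)), each = ncol(samples)),
        worker = rep(seq_len(ncol(samples)), times = nrow(samples)),
        performance = as.vector(t(samples))
      )
      p <- file.path(out_dir, "performances.csv")
      readr::write_csv(df, p)
      p
    },
    curve = {
      beta <- args$beta %||% 0.2
      delta <- args$delta %||% 2
      samples <- run_replicates(config)
      curve <- aggregate_curve(samples, beta = beta, delta = delta, config)
      p <- file.path(out_dir, "curve.csv")
      write_curve_csv(curve, p)
      p
    },
    sweep = {
      res <- run_sweep(config)
      p <- file.path(out_dir, "heatmap.csv")
      write_heatmap_csv(res, p)
      p
    },
    stop("unknown command: ", command, call. = FALSE)
  )
  invisible(out)
}
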