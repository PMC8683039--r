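#' Plain-text key-value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are
#' parsed as numeric where possible, otherwise kept as strings; numeric
#' vectors may be comma-separated.
#'
#' @param x named list to write.
#' @param path file path.
#' @export
write_kv_config <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kv_config
#' @export
read_kv_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(items))
    out[[key]] <- if (!anyNA(num)) num else items
  }
  out
}

#' Experiment manifest
#'
#' @param experiment one of `"copy"`, `"spatial-replay"`, `"watermaze"`,
#'   `"cascade"`, `"overlap"`.
#' @param profile `"test"` or `"paper"`.
#' @param seed integer seed.
#' @param out output directory.
#' @param overrides named list of config overrides for the owning
#'   module's config constructor.
#' @export
experiment_manifest <- function(experiment = c("copy", "spatial-replay",
                                               "watermaze", "cascade",
                                               "overlap"),
                                profile = c("test", "paper"),
                                seed = 1, out = tempfile("ppcons-"),
                                overrides = list()) {
  experiment <- match.arg(experiment)
  profile <- match.arg(profile)
  structure(list(experiment = experiment, profile = profile,
                 seed = as.integer(seed), out = out,
                 overrides = overrides),
            class = "experiment_manifest")
}

validate_overrides <- function(overrides, cfg) {
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    stop("unknown config override(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

run_copy_manifest <- function(m) {
  cfg <- do.call(copy_experiment_config, c(list(profile = m$profile),
                                           m$overrides))
  res <- lapply(c("indirect_to_direct", "direct_to_indirect"),
                function(d) run_copy_experiment(d, seed = m$seed,
                                                config = cfg))
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(direction = r$direction, time_ms = r$times,
               correlation = r$correlation)))
  list(tables = list(correlation = df), config = cfg)
}

run_replay_manifest <- function(m) {
  cfg <- do.call(replay_experiment_config, c(list(profile = m$profile),
                                             m$overrides))
  res <- lapply(c(20, 1), function(sf)
    run_spatial_replay_experiment(speed_factor = sf, seed = m$seed,
                                  config = cfg))
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(speed_factor = r$speed_factor, time_ms = r$times,
               correlation = r$correlation)))
  list(tables = list(correlation = df), config = cfg)
}

run_watermaze_manifest <- function(m) {
  cfg <- do.call(hippocampal_config, c(list(profile = m$profile),
                                       m$overrides))
  scheds <- c("control", "lesion-before", "lesion-day21")
  occ <- list(); probes <- list()
  for (s in scheds) {
    r <- run_watermaze(cfg, schedule = s, seed = m$seed)
    occ[[s]] <- cbind(condition = s, r$occupancy)
    probes[[s]] <- cbind(condition = s, r$probes)
  }
  list(tables = list(occupancy = do.call(rbind, occ),
                     probes = do.call(rbind, probes)),
       config = cfg)
}

run_cascade_manifest <- function(m) {
  cfg <- do.call(cascade_config, c(list(profile = m$profile), m$overrides))
  curve <- trace_memory(cfg, seed = m$seed)
  df <- data.frame(day = rep(curve$days, cfg$L),
                   level = rep(seq_len(cfg$L), each = length(curve$days)),
                   correlation = as.vector(curve$cor))
  df_max <- data.frame(day = curve$days, max_correlation = curve$max,
                       hpc_correlation = curve$hpc)
  list(tables = list(levels = df, max = df_max), config = cfg,
       extra = curve$fits)
}

run_overlap_manifest <- function(m) {
  cfg <- do.call(overlap_config, m$overrides)
  traj <- integrate_overlaps(cfg)
  slopes <- max_overlap_powerlaw(traj)
  df <- as.data.frame(traj$O)
  df <- cbind(time_days = traj$times, df,
              max_overlap = slopes$max, local_slope = slopes$slope)
  list(tables = list(overlaps = df), config = cfg,
       extra = list(slope_range = slopes$slope_range))
}

#' Run an experiment manifest
#'
#' Dispatches to the owning module, writes tidy CSV tables, a JSON
#' metadata record (experiment, profile, seed, resolved parameters,
#' package version) and a plain-text log under the manifest's output
#' directory, which is created if missing.
#'
#' @param manifest an [experiment_manifest()].
#' @return list of result tables (invisibly), with the output paths in
#'   attribute `"paths"`.
#' @export
run_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  runner <- switch(manifest$experiment,
    "copy" = run_copy_manifest,
    "spatial-replay" = run_replay_manifest,
    "watermaze" = run_watermaze_manifest,
    "cascade" = run_cascade_manifest,
    "overlap" = run_overlap_manifest)
  # validate overrides against the owning config before running
  base_cfg <- switch(manifest$experiment,
    "copy" = copy_experiment_config(manifest$profile),
    "spatial-replay" = replay_experiment_config(manifest$profile),
    "watermaze" = hippocampal_config(manifest$profile),
    "cascade" = cascade_config(manifest$profile),
    "overlap" = overlap_config())
  validate_overrides(manifest$overrides, base_cfg)

  dir.create(manifest$out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- runner(manifest)
  paths <- character(0)
  for (nm in names(res$tables)) {
    p <- file.path(manifest$out,
                   sprintf("%s_%s.csv", manifest$experiment, nm))
    utils::write.csv(res$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    experiment = manifest$experiment, profile = manifest$profile,
    seed = manifest$seed, overrides = manifest$overrides,
    parameters = res$config[!vapply(res$config, is.function, logical(1))],
    package_version = as.character(utils::packageVersion("ppcons")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  meta_path <- file.path(manifest$out,
                         sprintf("%s_metadata.json", manifest$experiment))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_path <- file.path(manifest$out,
                        sprintf("%s_run.log", manifest$experiment))
  writeLines(sprintf("[%s] %s (%s profile, seed %d) finished in %.1f s",
                     format(t0), manifest$experiment, manifest$profile,
                     manifest$seed, meta$elapsed_s), log_path)
  attr(res$tables, "paths") <- c(paths, meta_path, log_path)
  invisible(res$tables)
}

#' Command-line entry point
#'
#' Parses `ppt <experiment> [--profile test|paper] [--seed N] [--out DIR]
#' [--set key=value ...]` and calls [run_manifest()].  Installed as the
#' executable script `cli/ppt`.
#'
#' @param args character vector of command-line arguments.
#' @export
ppt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ppt {copy|spatial-replay|watermaze|cascade|overlap}",
    "[--profile test|paper] [--seed N] [--out DIR] [--set key=value ...]")
  if (length(args) < 1) stop(usage, call. = FALSE)
  experiment <- args[1]
  profile <- "test"; seed <- 1L; out <- file.path(".", "ppt-out")
  overrides <- list()
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--profile") { profile <- args[i + 1]; i <- i + 2L }
    else if (a == "--seed") { seed <- as.integer(args[i + 1]); i <- i + 2L }
    else if (a == "--out") { out <- args[i + 1]; i <- i + 2L }
    else if (a == "--set") {
      kv <- strsplit(args[i + 1], "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad --set, expected key=value")
      num <- suppressWarnings(as.numeric(kv[2]))
      overrides[[kv[1]]] <- if (is.na(num)) kv[2] else num
      i <- i + 2L
    } else stop("unknown argument: ", a, "\n", usage, call. = FALSE)
  }
  m <- experiment_manifest(experiment, profile, seed, out, overrides)
  run_manifest(m)
  message("results written to ", out)
  invisible(out)
}
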