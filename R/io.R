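# File-level bindings: configuration files, trajectory/event output,
# run manifests. Numbers round-trip CSV at 12 significant digits.

#' Write / read a trajectory CSV
#'
#' Tidy comma-separated output (UTF-8, `.` decimal, mandatory header) with
#' 12 significant digits so values round-trip losslessly.
#'
#' @param traj A `culture_trajectory` or its `trajectory` data frame.
#' @param path Output path.
#' @return The path (write, invisibly) or the data frame (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- if (inherits(traj, "culture_trajectory")) traj$trajectory else traj
  df <- as.data.frame(lapply(df, function(x) {
    if (is.numeric(x)) signif(x, 12) else x
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}

#' Write an event log as JSON lines
#'
#' One JSON object per cell-cycle event.
#'
#' @param events Event data frame (from `simulate_culture()$events`).
#' @param path Output path.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

# Deterministic polynomial hash (mod 2^31 - 1) of a canonical JSON
# rendering; identifies a configuration in run manifests.
config_hash <- function(cfg) {
  canon <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                            force = TRUE)
  bytes <- as.integer(charToRaw(canon))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Scenario-config fields settable from a config file.
config_file_keys <- function() {
  c("preset", "I_i", "light_schedule", "pattern", "initial_dry_matter",
    "initial_cell_conc", "initial_DNA", "initial_cell_volume",
    "max_sequences", "cohort_fractions", "retardation",
    "rna_doubling_cap", "time_step", "horizon",
    "phase", "growth", "starch")
}

#' Read a scenario configuration file
#'
#' Flat YAML or JSON (by extension) with an optional `preset:` key naming a
#' packaged scenario whose fields the file then overrides. Unknown keys are
#' errors (fail-closed), preventing silently ignored misspellings.
#' `cohort_fractions` is a mapping from n to fraction; `phase`, `growth`
#' and `starch` are mappings overriding individual parameters.
#'
#' @param path Config file path.
#' @return A validated [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), config_file_keys())
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  build <- function(args) {
    if (!is.null(args$cohort_fractions)) {
      args$cohort_fractions <- unlist(args$cohort_fractions)
    }
    if (!is.null(args$retardation)) {
      args$retardation <- unlist(args$retardation)
    }
    if (!is.null(args$phase)) {
      args$phase <- do.call(phase_durations, as.list(args$phase))
    }
    if (!is.null(args$growth)) {
      args$growth <- do.call(growth_params, as.list(args$growth))
    }
    if (!is.null(args$starch)) {
      args$starch <- do.call(starch_params, as.list(args$starch))
    }
    args
  }
  if (!is.null(raw$preset)) {
    nm <- raw$preset
    raw$preset <- NULL
    do.call(preset, c(list(name = nm), build(raw)))
  } else {
    if (is.null(raw$pattern)) {
      stop("configuration is missing required key: pattern")
    }
    do.call(scenario_config, build(raw))
  }
}

#' Run a simulation from a configuration file
#'
#' Reads the configuration, runs [simulate_culture()], and writes
#' `trajectory.csv`, `events.jsonl` and `manifest.json` into the output
#' directory.
#'
#' @param config_path Path to a YAML/JSON scenario file.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the output paths and the trajectory.
#' @export
run_simulate <- function(config_path, out_dir) {
  cfg <- read_scenario_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_culture(cfg)
  paths <- list(trajectory = file.path(out_dir, "trajectory.csv"),
                events = file.path(out_dir, "events.jsonl"),
                manifest = file.path(out_dir, "manifest.json"))
  write_trajectory_csv(traj, paths$trajectory)
  write_events_jsonl(traj$events, paths$events)
  manifest <- list(
    config_file = normalizePath(config_path),
    config_hash = config_hash(unclass(cfg)[setdiff(names(cfg), "attenuation")]),
    package_version = as.character(utils::packageVersion("multifission")),
    truncated = traj$truncated,
    outputs = lapply(paths, identity),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, list(trajectory = traj)))
}

#' Compute division statistics from a trajectory CSV
#'
#' Thin file binding of [division_stats()]: reads a tidy series (and
#' optionally a control series), computes the statistics and writes them as
#' JSON.
#'
#' @param series_csv Path to the treated series.
#' @param control_csv Optional path to the control series.
#' @param out_json Optional output path for the JSON result.
#' @return The statistics data frame (invisibly when writing).
#' @export
run_stats <- function(series_csv, control_csv = NULL, out_json = NULL) {
  series <- read_trajectory_csv(series_csv)
  control <- if (!is.null(control_csv)) read_trajectory_csv(control_csv)
  stats <- division_stats(series, control = control)
  if (!is.null(out_json)) {
    jsonlite::write_json(as.list(stats), out_json, auto_unbox = TRUE,
                         digits = NA)
    return(invisible(stats))
  }
  stats
}

#' Calibrate an attenuation model from an anchors CSV
#'
#' Thin file binding of [calibrate_attenuation()].
#'
#' @param anchors_csv CSV with header `incident,mean,dry_matter`.
#' @param out_json Optional output path for the fitted model.
#' @return The fitted [attenuation_model()].
#' @export
run_calibrate <- function(anchors_csv, out_json = NULL) {
  model <- calibrate_attenuation(read_light_anchors(anchors_csv))
  if (!is.null(out_json)) write_attenuation_model(model, out_json)
  model
}

#' Write noisy observations as tidy CSV
#'
#' Thin file binding of [generate_observations()]: runs the configured
#' scenario, samples it with the noise model, and writes a tidy CSV with a
#' `replicate` column.
#'
#' @param config_path Scenario configuration file.
#' @param out_csv Output path.
#' @param noise A [noise_model()].
#' @return The output path, invisibly.
#' @export
run_synth <- function(config_path, out_csv, noise = noise_model()) {
  cfg <- read_scenario_config(config_path)
  obs <- generate_observations(simulate_culture(cfg), noise)
  utils::write.csv(as.data.frame(lapply(obs, function(x) {
    if (is.numeric(x)) signif(x, 12) else x
  })), out_csv, row.names = FALSE, quote = FALSE)
  invisible(out_csv)
}
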