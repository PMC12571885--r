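# Run configuration: a structured YAML file drives the CLI subcommands.
# Every stochastic stage takes an explicit seed; nothing relies on implicit
# global randomness.

.run_config_defaults <- list(
  seed = 1L,
  timestep = 0.5,            # fs
  friction = 0.01,           # 1/fs
  temperatures = c(300, 500, 700),
  temperature = 300,
  thermalize_ps = 5,
  production_ps = 50,
  explore_ps = 5,
  committee_size = 3L,
  per_temperature = 5L,
  frames_per_mode = 10L,
  threshold_cm1 = 5,
  max_iterations = 40L,
  acf_depth_fs = 1000,
  n_trajectories = 3L,
  record_every = 10L,
  testset_md_ps = 10,
  testset_n_sub = 200L,
  suite = list(n_molecules = 8L, size_min = 2L, size_max = 6L)
)

#' Read a run-configuration file
#'
#' YAML key/value file with nested sections; unspecified keys fall back to
#' the documented protocol defaults. All counts must be positive integers
#' and the seed must be explicit (the default configuration carries
#' `seed: 1`).
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .run_config_defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(user[[k]]) && is.list(cfg[[k]]))
        utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
    }
  }
  counts <- c("committee_size", "per_temperature", "frames_per_mode",
              "max_iterations", "n_trajectories", "record_every")
  for (k in counts) {
    v <- cfg[[k]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      stop("config field '", k, "' must be a positive integer")
  }
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed))
    stop("config must carry an explicit integer seed")
  if (cfg$timestep <= 0 || cfg$friction < 0)
    stop("timestep must be > 0 and friction >= 0")
  structure(cfg, class = "run_config")
}

#' Append records to a JSON-lines log
#'
#' Machine-readable per-iteration logging used by the CLI: one JSON object
#' per line.
#'
#' @param records a list (one record) or data.frame (one record per row).
#' @param path log file path; created when absent.
#' @return `path`, invisibly.
#' @export
write_json_log <- function(records, path) {
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  else if (!is.null(names(records))) records <- list(records)
  con <- file(path, open = "at")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}
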