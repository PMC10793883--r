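#' Write a session log to a directory
#'
#' Plain-text container: `header.json` (format version, configs, group
#' spec with normalization constants, unit snapshot), `spikes.csv` (10 ms
#' count matrix), `trials.jsonl` (one JSON object per trial) and
#' `frames.csv` (per-100 ms-bin decoded state).  All numeric content
#' round-trips losslessly (counts exactly, floats at full precision).
#'
#' @param log a `session_log`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  if (!inherits(log, "session_log")) stop("'log' must be a session_log")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  h <- log$header
  header <- list(
    format_version = h$format_version,
    session_index = h$session_index,
    engagement = h$engagement,
    decoder_config = unclass(h$decoder_config),
    task_config = unclass(h$task_config),
    groups = list(groups = h$groups$groups, mu = h$groups$mu,
                  delta = h$groups$delta),
    units = h$units,
    n_channels = ncol(log$spikes),
    n_spike_bins = nrow(log$spikes)
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  utils::write.csv(as.data.frame(log$spikes), file.path(path, "spikes.csv"),
                   row.names = FALSE)
  con <- file(file.path(path, "trials.jsonl"), "w")
  on.exit(close(con))
  if (nrow(log$trials)) {
    for (i in seq_len(nrow(log$trials)))
      writeLines(jsonlite::toJSON(as.list(log$trials[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
  }
  frames <- log$frames
  utils::write.csv(format(frames, digits = 17, trim = TRUE, scientific = FALSE),
                   file.path(path, "frames.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#'
#' Validates the format version, the spike-matrix dimensions against the
#' header, the 10 ms/100 ms grid alignment, and that every trial's bin
#' range lies within the frame table.
#'
#' @param path directory containing the log files.
#' @return a `session_log`.
#' @export
read_session_log <- function(path) {
  hp <- file.path(path, "header.json")
  if (!file.exists(hp)) stop("not a session log: missing header.json in ", path)
  h <- jsonlite::read_json(hp, simplifyVector = TRUE)
  if (!identical(h$format_version, "1.0"))
    stop("unknown session-log format version: ",
         h$format_version %||% "<missing>")
  spikes <- as.matrix(utils::read.csv(file.path(path, "spikes.csv")))
  dimnames(spikes) <- NULL
  storage.mode(spikes) <- "integer"
  if (nrow(spikes) != h$n_spike_bins || ncol(spikes) != h$n_channels)
    stop(sprintf(
      "spikes.csv: matrix is %d x %d but header declares %d x %d",
      nrow(spikes), ncol(spikes), h$n_spike_bins, h$n_channels))
  frames <- utils::read.csv(file.path(path, "frames.csv"))
  frames$frozen <- as.logical(frames$frozen)
  frames$engaged <- as.logical(frames$engaged)
  if (nrow(frames) * 10L != nrow(spikes))
    stop("frames.csv: frame count does not align with the 10 ms spike grid")
  tl <- readLines(file.path(path, "trials.jsonl"))
  trials <- if (length(tl)) {
    do.call(rbind, lapply(tl, function(s)
      as.data.frame(jsonlite::fromJSON(s), stringsAsFactors = FALSE)))
  } else {
    data.frame(index = integer(), target_x = numeric(), target_y = numeric(),
               target_angle = numeric(), is_center = logical(),
               freeze_duration = numeric(), outcome = character(),
               movement_duration = numeric(), start_bin = integer(),
               end_bin = integer())
  }
  if (nrow(trials)) {
    trials$target_angle <- as.numeric(trials$target_angle)
    if (any(trials$start_bin < 1L) || any(trials$end_bin > nrow(frames)))
      stop("trials.jsonl: trial bin range outside the frame table")
  }
  dcfg <- do.call(decoder_config, h$decoder_config)
  tc <- h$task_config
  tcfg <- task_config(variant = tc$variant, target_radius = tc$target_radius,
                      target_distance = tc$target_distance,
                      hold_time = tc$hold_time, trial_timeout = tc$trial_timeout,
                      freeze_range = if (tc$variant == "T") tc$freeze_range else NULL,
                      workspace = tc$workspace, dt = tc$dt)
  groups <- group_spec(h$groups$groups, mu = h$groups$mu, delta = h$groups$delta)
  structure(
    list(header = list(format_version = h$format_version,
                       session_index = h$session_index,
                       engagement = h$engagement, decoder_config = dcfg,
                       task_config = tcfg, groups = groups,
                       units = as.data.frame(h$units)),
         spikes = spikes, trials = trials, frames = frames),
    class = "session_log"
  )
}

#' Default run configuration
#'
#' All tunable constants of a training run with their standard values:
#' decoder constants, task geometry and timing, synthetic population and
#' learning schedule, and baseline settings.
#'
#' @return nested list with sections `decoder`, `task`, `population`,
#'   `schedule`, `baseline`, `run` and `seed`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    decoder = list(bin_width = 0.1, smoothing_bins = 5L, c = 1, w = 0.375,
                   v_max = 15, delta_floor = 0.1),
    task = list(variant = "T", target_radius = 1.5, target_distance = 7,
                hold_time = 0.2, trial_timeout = 10, freeze_range = c(2.5, 5),
                workspace = c(-15, 15, -12.5, 12.5), dt = 0.1),
    population = list(n_direct_per_group = 4L, n_indirect = 16L,
                      baseline_rate = 10, modulation_depth = 8,
                      rate_noise_sd = 18, indirect_depth = 1.5),
    schedule = list(pd_rotation_per_session = 0.12,
                    noise_decay_per_session = 0.82, engagement = 0.4,
                    engagement_gain_per_session = 0.045,
                    engagement_max = 0.95),
    run = list(n_sessions = 12L, session_duration_s = 120,
               pre_duration_s = 60),
    baseline = list(reps = 5L, trial_duration_s = 10)
  )
}

#' Read a run configuration file
#'
#' YAML (or JSON) config with the sections of [default_run_config()].
#' Missing keys fall back to the defaults; unknown keys are rejected.
#'
#' @param path config file path, or NULL for the defaults.
#' @return validated nested config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_section <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    base[names(upd)] <- upd
    base
  }
  unknown_top <- setdiff(names(user), names(cfg))
  if (length(unknown_top))
    stop("unknown config section(s): ", paste(unknown_top, collapse = ", "))
  for (sec in names(user)) {
    if (sec == "seed") cfg$seed <- user$seed
    else cfg[[sec]] <- merge_section(cfg[[sec]], user[[sec]],
                                     where = sec)
  }
  cfg
}

#' Build the component objects from a run config
#' @param cfg list from [read_run_config()].
#' @return list with `dcfg`, `tcfg`, `units`, `schedule`, plus the raw
#'   `run` and `baseline` sections.
#' @export
build_run <- function(cfg = default_run_config()) {
  tc <- cfg$task
  list(
    dcfg = do.call(decoder_config, cfg$decoder),
    tcfg = task_config(variant = tc$variant, target_radius = tc$target_radius,
                       target_distance = tc$target_distance,
                       hold_time = tc$hold_time,
                       trial_timeout = tc$trial_timeout,
                       freeze_range = if (tc$variant == "T") tc$freeze_range else NULL,
                       workspace = tc$workspace, dt = tc$dt),
    population = cfg$population,
    schedule = do.call(learning_schedule, cfg$schedule),
    run = cfg$run, baseline = cfg$baseline, seed = cfg$seed
  )
}
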