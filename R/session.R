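#' Simulate an idle recording segment
#'
#' Units fire at baseline (plus rate noise) with no task-directed intent;
#' used to estimate the first session's normalization constants, as in a
#' pre-experiment recorded while the user is idle.
#'
#' @param units a [synthetic_population()].
#' @param duration_s segment duration in seconds.
#' @param cfg a [decoder_config()] (sets the bin width).
#' @return matrix of spike counts, one row per 100 ms bin.
#' @export
simulate_idle_counts <- function(units, duration_s, cfg = decoder_config()) {
  n_bins <- round(duration_s / cfg$bin_width)
  if (n_bins < 1L) stop("'duration_s' shorter than one decoder bin")
  n_units <- nrow(units)
  counts <- matrix(0L, n_bins, n_units)
  for (b in seq_len(n_bins)) {
    rates <- unit_rate(units, intent = NULL)
    counts[b, ] <- colSums(matrix(
      sample_spikes(rep(rates, each = 10L), bin = 0.01), nrow = 10L))
  }
  counts
}

#' Run one closed-loop bio-feedback session
#'
#' Per 100 ms bin: the simulated user forms an intent (straight to target,
#' absent during freeze or disengaged bins), units fire rectified-cosine
#' Poisson spikes at 10 ms resolution, the decoder converts the summed
#' counts to a velocity, the cursor integrates it (locked during freeze),
#' and the task state machine advances.  All randomness is drawn from the
#' current RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param units a [synthetic_population()].
#' @param groups a normalized [group_spec()].
#' @param dcfg a [decoder_config()].
#' @param tcfg a [task_config()].
#' @param duration_s session duration, seconds.
#' @param engagement per-bin probability of task-directed intent.
#' @param session_index bookkeeping index stored in the log header.
#' @return a `session_log`: list with `header` (configs, group spec, unit
#'   snapshot), `spikes` (10 ms count matrix), `trials` (data frame of
#'   completed trials) and `frames` (per-bin decoded state).
#' @export
run_closed_loop_session <- function(units, groups, dcfg = decoder_config(),
                                    tcfg = task_config(), duration_s = 120,
                                    engagement = 0.9, session_index = 1L) {
  if (!is_normalized(groups))
    stop("groups must carry normalization constants (mu, delta)")
  n_bins <- round(duration_s / tcfg$dt)
  n_units <- nrow(units)
  spikes <- matrix(0L, n_bins * 10L, n_units)
  fr <- list(a1 = numeric(n_bins), a2 = numeric(n_bins), a3 = numeric(n_bins),
             a4 = numeric(n_bins), vx = numeric(n_bins), vy = numeric(n_bins),
             x = numeric(n_bins), y = numeric(n_bins),
             trial = integer(n_bins), frozen = logical(n_bins),
             engaged = logical(n_bins))
  trials <- list()
  st <- decoder_state(n_units, dcfg)
  position <- c(0, 0)
  ts <- NULL
  prev_target <- NULL
  trial_idx <- 0L
  trial_start_bin <- 1L
  for (b in seq_len(n_bins)) {
    if (is.null(ts)) {
      trial_idx <- trial_idx + 1L
      trial_start_bin <- b
      target <- next_target(tcfg, prev_target)
      ts <- trial_init(target, tcfg)
    }
    frozen <- ts$freeze_left > 1e-9
    engaged <- !frozen && stats::runif(1L) <= engagement
    intent <- if (engaged)
      intent_direction(position, ts$target$position, frozen = FALSE) else NULL
    rates <- unit_rate(units, intent)
    counts10 <- matrix(sample_spikes(rep(rates, each = 10L), bin = 0.01),
                       nrow = 10L)
    spikes[(10L * (b - 1L) + 1L):(10L * b), ] <- counts10
    step <- decoder_step(st, colSums(counts10), groups, dcfg)
    st <- step$state
    if (!frozen) position <- integrate_position(position, step$v, tcfg)
    res <- step_trial(ts, position, tcfg)
    ts <- res$state
    fr$a1[b] <- step$a[1L]; fr$a2[b] <- step$a[2L]
    fr$a3[b] <- step$a[3L]; fr$a4[b] <- step$a[4L]
    fr$vx[b] <- step$v[["vx"]]; fr$vy[b] <- step$v[["vy"]]
    fr$x[b] <- position[1L]; fr$y[b] <- position[2L]
    fr$trial[b] <- trial_idx; fr$frozen[b] <- frozen; fr$engaged[b] <- engaged
    if (res$event %in% c("success", "fail")) {
      trials[[trial_idx]] <- data.frame(
        index = trial_idx, target_x = ts$target$position[1L],
        target_y = ts$target$position[2L],
        target_angle = ts$target$angle,
        is_center = isTRUE(ts$target$is_center),
        freeze_duration = ts$freeze_duration,
        outcome = res$event, movement_duration = ts$move_elapsed,
        start_bin = trial_start_bin, end_bin = b)
      prev_target <- ts$target
      ts <- NULL
      if (tcfg$variant == "T") position <- c(0, 0)
    }
  }
  trials <- if (length(trials)) do.call(rbind, trials) else
    data.frame(index = integer(), target_x = numeric(), target_y = numeric(),
               target_angle = numeric(), is_center = logical(),
               freeze_duration = numeric(), outcome = character(),
               movement_duration = numeric(), start_bin = integer(),
               end_bin = integer())
  frames <- data.frame(bin = seq_len(n_bins),
                       t = seq_len(n_bins) * tcfg$dt, fr,
                       stringsAsFactors = FALSE)
  structure(
    list(header = list(format_version = "1.0", session_index = session_index,
                       engagement = engagement, decoder_config = dcfg,
                       task_config = tcfg, groups = groups,
                       units = as.data.frame(units)),
         spikes = spikes, trials = trials, frames = frames),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  n_tr <- nrow(x$trials)
  sr <- if (n_tr) mean(x$trials$outcome == "success") else NA_real_
  cat(sprintf("Session log (variant %s, session %s): %d bins, %d channels\n",
              x$header$task_config$variant, x$header$session_index,
              nrow(x$frames), ncol(x$spikes)))
  cat(sprintf("  %d completed trials, success rate %s\n", n_tr,
              ifelse(is.na(sr), "NA", sprintf("%.2f", sr))))
  invisible(x)
}

#' @export
summary.session_log <- function(object, ...) {
  print(object)
  cat(sprintf("  mean |v| = %.2f cm/s; action-value means: %s\n",
              mean(sqrt(object$frames$vx^2 + object$frames$vy^2)),
              paste(sprintf("%.2f", colMeans(
                object$frames[, c("a1", "a2", "a3", "a4")])), collapse = ", ")))
  invisible(object)
}

#' Success rate of a session log
#' @param log a `session_log`.
#' @return proportion of completed trials that succeeded.
#' @export
session_success_rate <- function(log) {
  if (!nrow(log$trials)) return(NA_real_)
  mean(log$trials$outcome == "success")
}

#' Run a multi-session training course
#'
#' Runs a chained practice schedule: before each session a
#' pre-experiment segment is recorded and used to estimate that session's
#' normalization constants.  The first pre-experiment is recorded idle;
#' later pre-experiments are themselves closed-loop brain control under
#' the previous session's constants, which chains the normalization across
#' sessions.  Between sessions the learning schedule rotates direct units'
#' PDs toward their assigned directions, anneals rate noise, and raises
#' engagement.  Trial timeout follows the practice course: 10 s for the
#' first three sessions, 15 s afterwards.
#'
#' @param units a [synthetic_population()].
#' @param schedule a [learning_schedule()]; a schedule with zero rotation,
#'   decay 1 and zero engagement gain is the no-learning control.
#' @param n_sessions number of sessions.
#' @param dcfg,tcfg decoder and task configurations.
#' @param session_duration_s duration of each practice session, seconds.
#' @param pre_duration_s duration of each pre-experiment segment, seconds.
#' @param timeouts optional vector of per-session trial timeouts (seconds);
#'   default 10 s for sessions 1-3 and 15 s after.
#' @param seed optional integer seed applied before any randomness.
#' @return list with `logs` (one `session_log` per session) and `units`
#'   (population state after the last session).
#' @export
run_training <- function(units, schedule = learning_schedule(),
                         n_sessions = 12L, dcfg = decoder_config(),
                         tcfg = task_config(), session_duration_s = 120,
                         pre_duration_s = 60, timeouts = NULL,
                         seed = NULL) {
  if (n_sessions < 1L) stop("'n_sessions' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(timeouts))
    timeouts <- ifelse(seq_len(n_sessions) <= 3L, 10, 15)
  timeouts <- rep_len(timeouts, n_sessions)
  groups <- select_groups(population_unit_table(units))
  # map channel ids to spike-matrix columns (identity for synthetic units)
  logs <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    eng <- engagement_at(schedule, i)
    tcfg_i <- tcfg
    tcfg_i$trial_timeout <- timeouts[i]
    pre_counts <- if (i == 1L) {
      simulate_idle_counts(units, pre_duration_s, dcfg)
    } else {
      pre <- run_closed_loop_session(units, groups, dcfg, tcfg_i,
                                     duration_s = pre_duration_s,
                                     engagement = eng, session_index = i)
      bin_decoder_counts(pre$spikes)
    }
    groups <- estimate_normalization(pre_counts, groups, dcfg)
    logs[[i]] <- run_closed_loop_session(units, groups, dcfg, tcfg_i,
                                         duration_s = session_duration_s,
                                         engagement = eng, session_index = i)
    if (i < n_sessions) units <- advance_learning(units, schedule)
  }
  list(logs = logs, units = units)
}
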