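#' Extract the movement-epoch 10 ms spike frame from a session log
#'
#' Movement portions are the bins that belong to a trial and are not
#' freeze bins; inter-trial segments (none in these task variants) and
#' freeze periods are excluded.
#'
#' @param log a `session_log`.
#' @return matrix of 10 ms spike counts restricted to movement bins.
#' @export
movement_spike_frame <- function(log) {
  keep100 <- which(log$frames$trial > 0L & !log$frames$frozen)
  if (!length(keep100)) stop("log contains no movement bins")
  rows <- as.vector(vapply(keep100, function(b) (10L * (b - 1L) + 1L):(10L * b),
                           integer(10L)))
  log$spikes[rows, , drop = FALSE]
}

#' Jointly shuffle the time order of 10 ms spike bins
#'
#' Permutes whole 10 ms bins across time, keeping each bin's across-channel
#' population vector intact.  This destroys the temporal relation between
#' neural activity and task cues while preserving every bin's instantaneous
#' channel correlations and the per-channel count multisets.
#'
#' @param frame matrix of 10 ms spike counts (rows = bins).
#' @return the row-permuted matrix.
#' @export
shuffle_bins <- function(frame) {
  frame <- as.matrix(frame)
  if (nrow(frame) < 2L) stop("need at least 2 bins to shuffle")
  frame[sample.int(nrow(frame)), , drop = FALSE]
}

#' Replay a shuffled spike frame through decoder and task offline
#'
#' The chance-baseline procedure: shuffled 10 ms bins are re-summed into
#' 100 ms decoder bins and fed through the decoder and an offline task
#' simulation using the session's parameters, except that every trial
#' consumes a fixed 10 s window of data; failure to reach the target and
#' hold within the window is a failed trial.  There is no freeze period in
#' the offline replay.  Variant "T" resets the cursor to the center after
#' each trial; variant "K" relocates the cursor to the center of the last
#' target, as if it had been reached.
#'
#' @param frame matrix of 10 ms spike counts (typically the output of
#'   [shuffle_bins()] on [movement_spike_frame()]).
#' @param groups a normalized [group_spec()].
#' @param dcfg a [decoder_config()].
#' @param tcfg a [task_config()]; its variant decides the relocation rule.
#' @param trial_duration_s fixed data window per trial, seconds.
#' @return list with `rate` (success proportion), `n_trials`, and
#'   `outcomes` (logical per trial).
#' @export
simulate_baseline <- function(frame, groups, dcfg = decoder_config(),
                              tcfg = task_config(), trial_duration_s = 10) {
  counts <- bin_decoder_counts(as.matrix(frame))
  bins_per_trial <- round(trial_duration_s / tcfg$dt)
  n_trials <- nrow(counts) %/% bins_per_trial
  if (n_trials < 1L) stop("shuffled frame too short for one fixed-duration trial")
  st <- decoder_state(ncol(counts), dcfg)
  position <- c(0, 0)
  outcomes <- logical(n_trials)
  prev_target <- NULL
  b <- 0L
  for (tr in seq_len(n_trials)) {
    target <- next_target(tcfg, prev_target)
    ts <- trial_init(target, tcfg, freeze_duration = 0)
    ts_timeout_ok <- TRUE
    succeeded <- FALSE
    for (k in seq_len(bins_per_trial)) {
      b <- b + 1L
      step <- decoder_step(st, counts[b, ], groups, dcfg)
      st <- step$state
      position <- integrate_position(position, step$v, tcfg)
      if (!succeeded) {
        res <- step_trial(ts, position, tcfg)
        ts <- res$state
        if (res$event == "success") succeeded <- TRUE
        # a timeout event cannot occur before the window ends when
        # trial_timeout >= trial_duration_s; remaining bins are consumed
        # regardless so that every trial spans exactly the fixed window
        if (res$event == "fail") ts_timeout_ok <- FALSE
      }
    }
    outcomes[tr] <- succeeded
    prev_target <- target
    position <- if (tcfg$variant == "T") c(0, 0) else target$position
  }
  list(rate = mean(outcomes), n_trials = n_trials, outcomes = outcomes)
}

#' Shuffled-bin chance baseline of a session
#'
#' Repeats the shuffle-and-replay procedure on a session log's movement
#' epochs and reports per-repetition and mean baseline success rates.
#'
#' @param log a `session_log`.
#' @param reps number of independent shuffles.
#' @param seed optional integer seed.
#' @param tcfg optional [task_config()] override (e.g. a different target
#'   radius); defaults to the session's own task parameters.
#' @param trial_duration_s fixed data window per trial, seconds.
#' @return object of class `baseline_result` with fields `per_rep_rate`,
#'   `mean_rate`, `n_trials` (per repetition) and `seed`.
#' @export
baseline_success_rate <- function(log, reps = 1L, seed = NULL, tcfg = NULL,
                                  trial_duration_s = 10) {
  if (!is.null(seed)) set.seed(seed)
  tcfg <- tcfg %||% log$header$task_config
  # fixed-duration replay windows must not be cut short by the online timeout
  tcfg$trial_timeout <- max(tcfg$trial_timeout, trial_duration_s)
  frame <- movement_spike_frame(log)
  dcfg <- log$header$decoder_config
  groups <- log$header$groups
  rates <- numeric(reps)
  n_trials <- integer(reps)
  for (r in seq_len(reps)) {
    res <- simulate_baseline(shuffle_bins(frame), groups, dcfg, tcfg,
                             trial_duration_s = trial_duration_s)
    rates[r] <- res$rate
    n_trials[r] <- res$n_trials
  }
  structure(list(per_rep_rate = rates, mean_rate = mean(rates),
                 n_trials = n_trials, seed = seed),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("Shuffled-bin baseline: mean success rate %.3f over %d repetition(s) (%s trials each)\n",
              x$mean_rate, length(x$per_rep_rate),
              paste(unique(x$n_trials), collapse = "/")))
  invisible(x)
}
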