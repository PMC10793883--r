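#' Smoothed per-channel firing rates of a whole session
#'
#' Recomputes, offline, the same smoothed rate signal the decoder saw:
#' 10 ms spikes are summed into 100 ms bins and passed through the trailing
#' moving average.
#'
#' @param log a `session_log`.
#' @return matrix of rates (Hz), one row per 100 ms bin.
#' @export
session_rates <- function(log) {
  cfg <- log$header$decoder_config
  counts <- bin_decoder_counts(log$spikes)
  st <- decoder_state(ncol(counts), cfg)
  rates <- matrix(NA_real_, nrow(counts), ncol(counts))
  for (b in seq_len(nrow(counts))) {
    sm <- smooth_firing_rates(st, counts[b, ], cfg)
    st <- sm$state
    rates[b, ] <- sm$rates
  }
  rates
}

#' Per-bin target direction for tuning analyses
#'
#' For fixed-target variants the absolute target direction of the bin's
#' trial; for out-and-back variants the target direction relative to the
#' cursor (angle of the vector from the cursor to the target center).
#'
#' @param log a `session_log`.
#' @param relative use the cursor-relative direction (default for variant
#'   "K").
#' @return per-bin angle in radians (NA outside completed trials or, in
#'   absolute mode, for center targets).
#' @export
bin_target_angles <- function(log, relative = log$header$task_config$variant == "K") {
  n <- nrow(log$frames)
  ang <- rep(NA_real_, n)
  for (i in seq_len(nrow(log$trials))) {
    tr <- log$trials[i, ]
    idx <- tr$start_bin:tr$end_bin
    if (relative) {
      dx <- tr$target_x - log$frames$x[idx]
      dy <- tr$target_y - log$frames$y[idx]
      a <- atan2(dy, dx)
      a[dx == 0 & dy == 0] <- NA_real_
      ang[idx] <- a
    } else {
      ang[idx] <- tr$target_angle
    }
  }
  ang
}

#' Direction-tuning fits for every channel of a session
#'
#' Fits cosine direction tuning on movement bins (freeze bins excluded).
#' For variant "K" the angles are cursor-relative and the medium-speed
#' filter is applied, as in the tuning analyses of out-and-back sessions.
#'
#' @param log a `session_log`.
#' @param channels channel indices to fit (default all).
#' @param speed_filter apply the 25-75% of maximum speed filter (default
#'   for variant "K").
#' @return data frame with one row per channel: `channel_id`, `pd_angle`,
#'   `tuning_depth`, `r2`, `n_bins`.
#' @export
unit_tuning_table <- function(log, channels = seq_len(ncol(log$spikes)),
                              speed_filter = log$header$task_config$variant == "K") {
  rates <- session_rates(log)
  ang <- bin_target_angles(log)
  keep <- log$frames$trial > 0L & !log$frames$frozen & !is.na(ang)
  if (speed_filter) {
    spd <- sqrt(log$frames$vx^2 + log$frames$vy^2)
    vmax <- log$header$decoder_config$v_max
    keep <- keep & spd >= 0.25 * vmax & spd <= 0.75 * vmax
  }
  out <- lapply(channels, function(ch) {
    fit <- tryCatch(fit_direction_tuning(rates[keep, ch], ang[keep]),
                    error = function(e) NULL)
    if (is.null(fit))  # too few movement bins or distinct angles this session
      return(data.frame(channel_id = ch, pd_angle = NA_real_,
                        tuning_depth = NA_real_, r2 = NA_real_,
                        n_bins = sum(keep)))
    data.frame(channel_id = ch, pd_angle = fit$pd_angle,
               tuning_depth = fit$tuning_depth, r2 = fit$r2, n_bins = fit$n)
  })
  do.call(rbind, out)
}

#' Per-trial output-potent and output-null means of a session
#'
#' @param log a `session_log`.
#' @param speed_filter apply the medium-speed filter (default for variant
#'   "K", matching the group-activity analyses).
#' @return data frame with one row per non-center completed trial:
#'   `index`, `outcome`, `sector`, `potent_mean`, `null_mean`.
#' @export
session_potent_null <- function(log,
                                speed_filter = log$header$task_config$variant == "K") {
  a_cols <- as.matrix(log$frames[, c("a1", "a2", "a3", "a4")])
  spd <- sqrt(log$frames$vx^2 + log$frames$vy^2)
  vmax <- log$header$decoder_config$v_max
  rows <- lapply(seq_len(nrow(log$trials)), function(i) {
    tr <- log$trials[i, ]
    if (is.na(tr$target_angle)) return(NULL)  # center targets have no sector
    idx <- tr$start_bin:tr$end_bin
    idx <- idx[!log$frames$frozen[idx]]
    if (!length(idx)) return(NULL)
    pn <- potent_null_values(a_cols[idx, , drop = FALSE], tr$target_angle,
                             speed = spd[idx], speed_filter = speed_filter,
                             v_max = vmax)
    data.frame(index = tr$index, outcome = tr$outcome, sector = pn$sector,
               potent_mean = pn$potent_mean, null_mean = pn$null_mean)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(index = integer(), outcome = character(),
                      sector = character(), potent_mean = numeric(),
                      null_mean = numeric()))
  do.call(rbind, rows)
}

#' Trajectory scores of a session's successful trials
#'
#' @param log a `session_log`.
#' @return data frame with `index`, `sector`, `score` for each successful
#'   non-center trial (freeze bins excluded from the path; the start point
#'   is the cursor position at movement onset).
#' @export
session_trajectory_scores <- function(log) {
  rows <- lapply(seq_len(nrow(log$trials)), function(i) {
    tr <- log$trials[i, ]
    if (tr$outcome != "success" || is.na(tr$target_angle)) return(NULL)
    idx <- tr$start_bin:tr$end_bin
    idx <- idx[!log$frames$frozen[idx]]
    if (length(idx) < 1L) return(NULL)
    start <- if (log$header$task_config$variant == "T") c(0, 0) else
      c(log$frames$x[max(1L, idx[1L] - 1L)], log$frames$y[max(1L, idx[1L] - 1L)])
    if (tr$start_bin == 1L && log$header$task_config$variant == "K")
      start <- c(0, 0)
    path <- rbind(start, cbind(log$frames$x[idx], log$frames$y[idx]))
    tc <- c(tr$target_x, tr$target_y)
    if (sqrt(sum((tc - start)^2)) == 0) return(NULL)
    data.frame(index = tr$index, sector = sector_of(tr$target_angle),
               score = trajectory_score(path, tc, start = start))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(index = integer(), sector = character(), score = numeric()))
  do.call(rbind, rows)
}

#' Per-session learning metrics for a training course
#'
#' @param logs list of `session_log` objects from [run_training()].
#' @param tuning also fit per-channel direction tuning (slower)?
#' @return list with `sessions` (data frame: session, n_trials,
#'   success_rate, mean trajectory score, mean potent/null), `trials`
#'   (pooled per-trial table with session index), `trend` (a
#'   [fit_success_logistic()] fit) and, when `tuning` is TRUE, `tuning`
#'   (pooled per-session unit tuning table).
#' @export
analyze_training <- function(logs, tuning = TRUE) {
  per <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    pn <- session_potent_null(log)
    sc <- session_trajectory_scores(log)
    data.frame(
      session = i, n_trials = nrow(log$trials),
      success_rate = session_success_rate(log),
      trajectory_score = if (nrow(sc)) mean(sc$score) else NA_real_,
      potent_mean = if (nrow(pn)) mean(pn$potent_mean, na.rm = TRUE) else NA_real_,
      null_mean = if (nrow(pn)) mean(pn$null_mean, na.rm = TRUE) else NA_real_)
  })
  sessions <- do.call(rbind, per)
  trials <- do.call(rbind, lapply(seq_along(logs), function(i) {
    tr <- logs[[i]]$trials
    if (!nrow(tr)) return(NULL)
    data.frame(session_index = i, target_angle = tr$target_angle,
               outcome = tr$outcome,
               movement_duration = tr$movement_duration)
  }))
  trend <- fit_success_logistic(trials)
  out <- list(sessions = sessions, trials = trials, trend = trend)
  if (tuning) {
    out$tuning <- do.call(rbind, lapply(seq_along(logs), function(i) {
      direct <- which(logs[[i]]$header$units$direct)
      tt <- unit_tuning_table(logs[[i]], channels = direct)
      tt$session <- i
      tt$assigned_direction <-
        logs[[i]]$header$units$assigned_direction[direct]
      tt$pd_ad <- pd_ad_distance(ifelse(is.na(tt$pd_angle), 0, tt$pd_angle),
                                 tt$assigned_direction)
      tt$pd_ad[is.na(tt$pd_angle)] <- NA_real_
      tt
    }))
  }
  out
}
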