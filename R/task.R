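#' Center-out task configuration
#'
#' Two task variants are supported.  Variant "T": only peripheral targets
#' at the four cardinal angles, a random pre-movement freeze period during
#' which the cursor is locked, and cursor reset to the center after every
#' trial.  Variant "K": center and peripheral targets alternate without
#' delay, peripheral targets appear at uniformly random angles, no freeze,
#' and no reset (out-and-back movements).
#'
#' @param variant "T" or "K".
#' @param target_radius capture radius of the target, cm (the visual ring
#'   is treated as a disk for containment).
#' @param target_distance center-to-periphery distance, cm.
#' @param hold_time continuous in-target time required for success, s.
#' @param trial_timeout movement-time limit per trial, s (excludes freeze).
#' @param freeze_range length-2 interval (s) from which the freeze
#'   duration is drawn uniformly; used by variant "T" only.
#' @param workspace rectangle `c(xmin, xmax, ymin, ymax)` in cm; the cursor
#'   is clipped to it.
#' @param dt decoder/task update interval, s.
#' @return an object of class `task_config`.
#' @export
task_config <- function(variant = c("T", "K"), target_radius = 1.5,
                        target_distance = 7, hold_time = 0.2,
                        trial_timeout = 10,
                        freeze_range = c(2.5, 5),
                        workspace = c(-15, 15, -12.5, 12.5), dt = 0.1) {
  variant <- match.arg(variant)
  stopifnot_scalar_num(hold_time, "hold_time", positive = TRUE)
  stopifnot_scalar_num(trial_timeout, "trial_timeout", positive = TRUE)
  stopifnot_scalar_num(dt, "dt", positive = TRUE)
  stopifnot_scalar_num(target_radius, "target_radius", positive = TRUE)
  stopifnot_scalar_num(target_distance, "target_distance", positive = TRUE)
  if (length(workspace) != 4L || workspace[1] >= workspace[2] || workspace[3] >= workspace[4])
    stop("'workspace' must be c(xmin, xmax, ymin, ymax) with min < max")
  if (target_distance + target_radius > min(abs(workspace)))
    stop("target geometry does not fit inside the workspace")
  if (variant == "K") freeze_range <- NULL
  if (!is.null(freeze_range) &&
      (length(freeze_range) != 2L || any(freeze_range < 0) ||
       freeze_range[1] > freeze_range[2]))
    stop("'freeze_range' must be a non-negative interval c(lo, hi)")
  structure(
    list(variant = variant, target_radius = target_radius,
         target_distance = target_distance, hold_time = hold_time,
         trial_timeout = trial_timeout, freeze_range = freeze_range,
         workspace = as.numeric(workspace), dt = dt),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("Center-out task, variant %s\n", x$variant))
  cat(sprintf("  target: radius %g cm at distance %g cm; hold %g s; timeout %g s\n",
              x$target_radius, x$target_distance, x$hold_time, x$trial_timeout))
  if (!is.null(x$freeze_range))
    cat(sprintf("  freeze: %g-%g s before movement\n",
                x$freeze_range[1], x$freeze_range[2]))
  cat(sprintf("  workspace: [%g, %g] x [%g, %g] cm, dt = %g s\n",
              x$workspace[1], x$workspace[2], x$workspace[3], x$workspace[4], x$dt))
  invisible(x)
}

#' Draw the next target
#'
#' Variant "T": uniformly one of the four cardinal targets (0, 90, 180,
#' 270 degrees) at `target_distance` from the center.  Variant "K": a
#' peripheral target at a uniformly random angle, alternating with the
#' center target (a peripheral trial is always followed by a center
#' trial).
#'
#' @param cfg a [task_config()].
#' @param previous the previous trial's target (a list with `is_center`),
#'   or NULL at session start.
#' @return list with `position` (cm), `angle` (radians; NA for the center
#'   target) and `is_center`.
#' @export
next_target <- function(cfg, previous = NULL) {
  if (cfg$variant == "T") {
    ang <- sample(c(0, pi / 2, pi, -pi / 2), 1L)
    list(position = cfg$target_distance * c(cos(ang), sin(ang)),
         angle = ang, is_center = FALSE)
  } else {
    if (!is.null(previous) && !previous$is_center) {
      list(position = c(0, 0), angle = NA_real_, is_center = TRUE)
    } else {
      ang <- wrap_angle_lower(stats::runif(1L, 0, 2 * pi))
      list(position = cfg$target_distance * c(cos(ang), sin(ang)),
           angle = ang, is_center = FALSE)
    }
  }
}

#' Integrate cursor position over one bin
#'
#' @param position length-2 position, cm.
#' @param velocity length-2 velocity, cm/s.
#' @param cfg a [task_config()].
#' @return new position, clipped to the workspace rectangle.
#' @export
integrate_position <- function(position, velocity, cfg) {
  p <- position + as.numeric(velocity) * cfg$dt
  c(clamp(p[1], cfg$workspace[1], cfg$workspace[2]),
    clamp(p[2], cfg$workspace[3], cfg$workspace[4]))
}

#' Initialize one trial's state
#'
#' @param target a target from [next_target()].
#' @param cfg a [task_config()].
#' @param freeze_duration freeze duration in seconds; drawn uniformly from
#'   `cfg$freeze_range` when NULL (variant "T"); 0 for variant "K".
#' @return list holding the trial clock state (class `trial_state`).
#' @export
trial_init <- function(target, cfg, freeze_duration = NULL) {
  if (is.null(freeze_duration)) {
    freeze_duration <- if (is.null(cfg$freeze_range)) 0 else
      stats::runif(1L, cfg$freeze_range[1], cfg$freeze_range[2])
  }
  structure(
    list(target = target, freeze_left = freeze_duration,
         freeze_duration = freeze_duration, move_elapsed = 0,
         hold_elapsed = 0, done = FALSE, outcome = NA_character_),
    class = "trial_state"
  )
}

#' Advance the trial state machine by one bin
#'
#' During the freeze period (variant "T") decoded velocity is ignored and
#' the cursor does not move.  Once moving, the hold clock accumulates only
#' while the cursor is inside the target disk and resets on exit; the trial
#' succeeds when the hold reaches `hold_time` and fails when movement time
#' exceeds `trial_timeout`.
#'
#' @param ts a `trial_state` from [trial_init()].
#' @param position cursor position *after* this bin's movement (ignored
#'   during freeze).
#' @param cfg a [task_config()].
#' @return list with `state` (updated) and `event`, one of
#'   `"freeze_active"`, `"moving"`, `"hold_in_progress"`, `"success"`,
#'   `"fail"`.
#' @export
step_trial <- function(ts, position, cfg) {
  if (ts$done) stop("trial already finished")
  if (ts$freeze_left > 1e-9) {
    ts$freeze_left <- ts$freeze_left - cfg$dt
    return(list(state = ts, event = "freeze_active"))
  }
  ts$move_elapsed <- ts$move_elapsed + cfg$dt
  inside <- sqrt(sum((position - ts$target$position)^2)) <= cfg$target_radius
  if (inside) ts$hold_elapsed <- ts$hold_elapsed + cfg$dt else ts$hold_elapsed <- 0
  if (ts$hold_elapsed >= cfg$hold_time - 1e-9) {
    ts$done <- TRUE; ts$outcome <- "success"
    return(list(state = ts, event = "success"))
  }
  if (ts$move_elapsed > cfg$trial_timeout + 1e-9) {
    ts$done <- TRUE; ts$outcome <- "fail"
    return(list(state = ts, event = "fail"))
  }
  list(state = ts, event = if (inside) "hold_in_progress" else "moving")
}
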