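#' Synthetic cosine-tuned population
#'
#' Builds a population of simulated multi-units.  "Direct" units are
#' organized four per direction sector, carry an assigned direction (AD,
#' the cursor direction their group drives) and an initial preferred
#' direction (PD) drawn uniformly inside the assigned sector; they are the
#' units a grouping step will select.  "Indirect" units are weakly tuned
#' at random angles and are recorded but never fed to the decoder.
#'
#' Firing follows rectified cosine tuning: when the simulated user intends
#' direction theta, a unit's rate is
#' `max(0, baseline + depth * cos(theta - pd) + N(0, noise_sd))`.
#'
#' @param n_direct_per_group direct units per direction group.
#' @param n_indirect number of weakly tuned indirect units.
#' @param baseline_rate baseline firing rate, Hz.
#' @param modulation_depth cosine modulation amplitude of direct units, Hz.
#' @param rate_noise_sd SD of the per-bin Gaussian rate noise, Hz
#'   (annealed across sessions by the learning schedule).
#' @param indirect_depth modulation amplitude of indirect units, Hz.
#' @param stable_days value for the `days_recorded` bookkeeping column.
#' @return data frame of class `synthetic_population`, one row per unit,
#'   with columns `channel_id`, `direct`, `baseline_rate`,
#'   `modulation_depth`, `pd_angle`, `rate_noise_sd`, `assigned_direction`
#'   (NA for indirect units) and `days_recorded`.
#' @export
synthetic_population <- function(n_direct_per_group = 4L, n_indirect = 16L,
                                 baseline_rate = 10, modulation_depth = 8,
                                 rate_noise_sd = 18, indirect_depth = 1.5,
                                 stable_days = 30L) {
  ads <- c(right = 0, left = pi, up = pi / 2, down = -pi / 2)
  n_direct <- 4L * n_direct_per_group
  ad <- rep(unname(ads), each = n_direct_per_group)
  # initial PDs uniform inside the assigned sector (AD +/- 45 degrees)
  pd_direct <- wrap_angle_lower(ad + stats::runif(n_direct, -pi / 4, pi / 4))
  pd_indirect <- wrap_angle_lower(stats::runif(n_indirect, -pi, pi))
  units <- data.frame(
    channel_id = seq_len(n_direct + n_indirect),
    direct = c(rep(TRUE, n_direct), rep(FALSE, n_indirect)),
    baseline_rate = baseline_rate,
    modulation_depth = c(rep(modulation_depth, n_direct),
                         rep(indirect_depth, n_indirect)),
    pd_angle = c(pd_direct, pd_indirect),
    rate_noise_sd = rate_noise_sd,
    assigned_direction = c(ad, rep(NA_real_, n_indirect)),
    days_recorded = as.integer(stable_days)
  )
  class(units) <- c("synthetic_population", "data.frame")
  units
}

#' Learning schedule for the synthetic user
#'
#' Imposed learning dynamics that reproduce the statistical signatures of
#' bio-feedback practice: each session, direct units' PDs rotate along the
#' shorter arc toward their assigned direction, rate noise is annealed
#' multiplicatively, and the per-bin probability of task-directed intent
#' (engagement) grows.
#'
#' @param pd_rotation_per_session PD rotation per session, radians.
#' @param noise_decay_per_session multiplicative noise decay in (0, 1].
#' @param engagement initial probability of task-directed intent per bin.
#' @param engagement_gain_per_session additive engagement increase.
#' @param engagement_max engagement ceiling.
#' @return an object of class `learning_schedule`.
#' @export
learning_schedule <- function(pd_rotation_per_session = 0.12,
                              noise_decay_per_session = 0.82,
                              engagement = 0.4,
                              engagement_gain_per_session = 0.045,
                              engagement_max = 0.95) {
  if (pd_rotation_per_session < 0) stop("'pd_rotation_per_session' must be >= 0")
  if (noise_decay_per_session <= 0 || noise_decay_per_session > 1)
    stop("'noise_decay_per_session' must be in (0, 1]")
  if (engagement < 0 || engagement > 1) stop("'engagement' must be in [0, 1]")
  structure(
    list(pd_rotation_per_session = pd_rotation_per_session,
         noise_decay_per_session = noise_decay_per_session,
         engagement = engagement,
         engagement_gain_per_session = engagement_gain_per_session,
         engagement_max = engagement_max),
    class = "learning_schedule"
  )
}

#' Engagement level at a given session
#' @param schedule a [learning_schedule()].
#' @param session_index 1-based session number.
#' @return probability of task-directed intent per bin.
#' @export
engagement_at <- function(schedule, session_index) {
  min(schedule$engagement_max,
      schedule$engagement +
        schedule$engagement_gain_per_session * (session_index - 1L))
}

#' Intended movement direction of the simulated user
#'
#' Greedy straight-to-target policy: the unit vector from the cursor to
#' the target center, or `NULL` during freeze bins, disengaged bins, or
#' when the cursor sits exactly on the target center.
#'
#' @param position cursor position, cm.
#' @param target target center, cm.
#' @param frozen logical; is the cursor frozen this bin?
#' @return length-2 unit vector, or NULL.
#' @export
intent_direction <- function(position, target, frozen = FALSE) {
  if (isTRUE(frozen)) return(NULL)
  d <- target - position
  len <- sqrt(sum(d^2))
  if (len == 0) return(NULL)
  d / len
}

#' Instantaneous firing rates of the population
#'
#' @param units a [synthetic_population()] (any subset of rows).
#' @param intent length-2 unit vector of intended direction, or NULL for
#'   baseline firing (freeze/disengaged/idle bins).
#' @return per-unit rate in Hz (rectified at 0); Gaussian rate noise is
#'   drawn from the current RNG stream.
#' @export
unit_rate <- function(units, intent = NULL) {
  mod <- 0
  if (!is.null(intent)) {
    theta <- atan2(intent[2], intent[1])
    mod <- units$modulation_depth * cos(theta - units$pd_angle)
  }
  pmax(0, units$baseline_rate + mod +
         stats::rnorm(nrow(units), 0, units$rate_noise_sd))
}

#' Sample spike counts for one 10 ms bin
#'
#' Poisson spiking at the 10 ms resolution used in session logs; ten such
#' bins are summed into each 100 ms decoder bin.
#'
#' @param rate per-unit rate, Hz (held constant within the decoder bin).
#' @param bin bin width in seconds.
#' @return integer vector of Poisson counts.
#' @export
sample_spikes <- function(rate, bin = 0.01) {
  if (any(rate < 0)) stop("'rate' must be non-negative")
  stats::rpois(length(rate), rate * bin)
}

#' Advance the population by one session of learning
#'
#' Direct units rotate their PD along the shorter arc toward the assigned
#' direction by at most the schedule's per-session rotation, and their
#' rate noise decays multiplicatively.  Indirect units keep their PD; all
#' units share the noise annealing (recording noise is population-wide).
#'
#' @param units a [synthetic_population()].
#' @param schedule a [learning_schedule()].
#' @return the updated population.
#' @export
advance_learning <- function(units, schedule) {
  direct <- which(units$direct)
  gap <- wrap_angle(units$assigned_direction[direct] - units$pd_angle[direct])
  step <- sign(gap) * pmin(abs(gap), schedule$pd_rotation_per_session)
  units$pd_angle[direct] <- wrap_angle_lower(units$pd_angle[direct] + step)
  units$rate_noise_sd <- units$rate_noise_sd * schedule$noise_decay_per_session
  units
}

#' Express the population's true tuning as a unit table
#'
#' Maps each unit's generative cosine tuning onto the linear
#' velocity-tuning scale used by [select_groups()], with
#' preferred-direction magnitude proportional to modulation depth.  This
#' is the calibration product a joystick session would otherwise provide.
#'
#' @param units a [synthetic_population()].
#' @return data frame accepted by [select_groups()].
#' @export
population_unit_table <- function(units) {
  mag <- units$modulation_depth / 2
  data.frame(
    channel_id = units$channel_id,
    days_recorded = units$days_recorded,
    b0 = units$baseline_rate,
    b1 = mag * cos(units$pd_angle),
    b2 = mag * sin(units$pd_angle),
    r2 = NA_real_,
    pd_angle = units$pd_angle,
    pd_magnitude = mag
  )
}
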