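# Shared fixtures, built in code at test time.

# Signed angular difference a - b wrapped to (-pi, pi]
wrap_angle_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

# A group spec over 8 channels, 2 per group, with fixed normalization.
fixture_groups <- function(mu = rep(20, 4), delta = rep(5, 4)) {
  group_spec(list(1:2, 3:4, 5:6, 7:8), mu = mu, delta = delta)
}

# Deterministic unit table: 16 units, 4 clearly in each sector, plus
# controls for stability and tuning-strength edge cases.
fixture_unit_table <- function() {
  sec_centers <- rep(c(0, pi, pi / 2, -pi / 2), each = 4L)
  jitter <- rep(c(-0.3, -0.1, 0.1, 0.3), times = 4L)
  ang <- sec_centers + jitter
  mag <- rep(c(5, 4, 3, 2), times = 4L)
  data.frame(channel_id = 1:16, days_recorded = 10L,
             b0 = 10, b1 = mag * cos(ang), b2 = mag * sin(ang),
             r2 = 0.5, pd_angle = ang, pd_magnitude = mag)
}

# Small trained closed-loop session shared across io/analysis/cli tests.
# Built once per test run and cached.
fixture_session_env <- new.env(parent = emptyenv())

fixture_trained_session <- function() {
  if (is.null(fixture_session_env$log)) {
    set.seed(424242)
    units <- synthetic_population(rate_noise_sd = 4)
    units$pd_angle[units$direct] <- units$assigned_direction[units$direct]
    res <- run_training(units, learning_schedule(engagement = 0.9),
                        n_sessions = 1L, session_duration_s = 120,
                        pre_duration_s = 30, seed = 424243)
    fixture_session_env$log <- res$logs[[1L]]
  }
  fixture_session_env$log
}
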