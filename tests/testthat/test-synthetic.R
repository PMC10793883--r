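test_that("intent is a unit vector toward the target, absent when frozen or on-target", {
  i1 <- intent_direction(c(0, 0), c(7, 0))
  expect_equal(i1, c(1, 0))
  i2 <- intent_direction(c(3, 4), c(0, 0))
  expect_equal(sqrt(sum(i2^2)), 1)
  expect_equal(i2, -c(3, 4) / 5)
  expect_null(intent_direction(c(0, 0), c(7, 0), frozen = TRUE))
  expect_null(intent_direction(c(7, 0), c(7, 0)))
})

test_that("unit rates follow rectified cosine tuning", {
  units <- synthetic_population(rate_noise_sd = 0)
  u <- units[units$direct & units$channel_id == 1L, ]
  u$pd_angle <- 0
  aligned <- unit_rate(u, c(1, 0))
  expect_equal(aligned, u$baseline_rate + u$modulation_depth)
  orth <- unit_rate(u, c(0, 1))
  expect_equal(orth, u$baseline_rate, tolerance = 1e-12)
  u2 <- u
  u2$modulation_depth <- u$baseline_rate + 5  # opposite intent drives below 0
  expect_equal(unit_rate(u2, c(-1, 0)), 0)
  expect_equal(unit_rate(u, intent = NULL), u$baseline_rate)
})

test_that("spike sampling is Poisson at the 10 ms resolution and seed-reproducible", {
  expect_equal(sample_spikes(0), 0L)
  set.seed(12)
  counts <- sample_spikes(rep(50, 1e5), bin = 0.01)
  expect_true(all(counts >= 0 & counts == round(counts)))
  # Poisson oracle: mean 0.5, SE sqrt(0.5/1e5)
  expect_lt(abs(mean(counts) - 0.5), 3 * sqrt(0.5 / 1e5))
  set.seed(99); a <- sample_spikes(rep(20, 1000))
  set.seed(99); b <- sample_spikes(rep(20, 1000))
  expect_identical(a, b)
  expect_error(sample_spikes(-1), "non-negative")
})

test_that("learning rotates PDs along the shorter arc and anneals noise", {
  units <- synthetic_population()
  units$pd_angle[1] <- units$assigned_direction[1] + 30 * pi / 180
  sch <- learning_schedule(pd_rotation_per_session = 10 * pi / 180,
                           noise_decay_per_session = 0.9)
  u1 <- advance_learning(units, sch)
  expect_equal(abs(wrap_angle_diff(u1$pd_angle[1], u1$assigned_direction[1])),
               20 * pi / 180, tolerance = 1e-12)
  # at the assigned direction: fixed point
  units$pd_angle[2] <- units$assigned_direction[2]
  u2 <- advance_learning(units, sch)
  expect_equal(u2$pd_angle[2], units$assigned_direction[2])
  # overshoot is capped: a 5-degree gap closes exactly
  units$pd_angle[3] <- units$assigned_direction[3] - 5 * pi / 180
  u3 <- advance_learning(units, sch)
  expect_equal(abs(wrap_angle_diff(u3$pd_angle[3], u3$assigned_direction[3])), 0,
               tolerance = 1e-12)
  expect_equal(u1$rate_noise_sd, units$rate_noise_sd * 0.9)
  # indirect units keep their PD
  ind <- which(!units$direct)
  expect_equal(u1$pd_angle[ind], units$pd_angle[ind])
  # null schedule is a fixed point of the population
  null_sch <- learning_schedule(pd_rotation_per_session = 0,
                                noise_decay_per_session = 1,
                                engagement_gain_per_session = 0)
  expect_equal(advance_learning(units, null_sch), units)
})

test_that("normalized |PD-AD| is non-increasing across sessions under a schedule", {
  set.seed(3)
  units <- synthetic_population()
  sch <- learning_schedule()
  d_prev <- pd_ad_distance(units$pd_angle[units$direct],
                           units$assigned_direction[units$direct])
  for (s in 1:6) {
    units <- advance_learning(units, sch)
    d <- pd_ad_distance(units$pd_angle[units$direct],
                        units$assigned_direction[units$direct])
    expect_true(all(d <= d_prev + 1e-12))
    d_prev <- d
  }
})

test_that("well-aligned low-noise units give high closed-loop success", {
  set.seed(71)
  units <- synthetic_population(rate_noise_sd = 3)
  units$pd_angle[units$direct] <- units$assigned_direction[units$direct]
  dcfg <- decoder_config()
  groups <- select_groups(population_unit_table(units))
  groups <- estimate_normalization(simulate_idle_counts(units, 30, dcfg),
                                   groups, dcfg)
  tcfg <- task_config(variant = "T", freeze_range = c(0.2, 0.5))
  log <- run_closed_loop_session(units, groups, dcfg, tcfg,
                                 duration_s = 90, engagement = 0.95)
  expect_gt(nrow(log$trials), 5)
  expect_gt(session_success_rate(log), 0.9)
  # log invariants
  expect_true(all(log$spikes >= 0))
  expect_equal(nrow(log$spikes), 10L * nrow(log$frames))
  expect_true(all(log$trials$end_bin <= nrow(log$frames)))
  expect_true(all(log$trials$movement_duration <= tcfg$trial_timeout + tcfg$dt))
})

test_that("unmodulated populations perform at chance relative to their own baseline", {
  set.seed(72)
  units <- synthetic_population(modulation_depth = 0, indirect_depth = 0,
                                rate_noise_sd = 6)
  dcfg <- decoder_config()
  groups <- group_spec(list(1:4, 5:8, 9:12, 13:16))
  groups <- estimate_normalization(simulate_idle_counts(units, 30, dcfg),
                                   groups, dcfg)
  tcfg <- task_config(variant = "T", freeze_range = c(0.2, 0.5))
  log <- run_closed_loop_session(units, groups, dcfg, tcfg,
                                 duration_s = 240, engagement = 0.9)
  online <- session_success_rate(log)
  b <- baseline_success_rate(log, reps = 5, seed = 5)
  # two-proportion test: online vs shuffled baseline of the same log
  n_on <- nrow(log$trials)
  n_b <- sum(b$n_trials)
  tab <- rbind(c(round(online * n_on), n_on - round(online * n_on)),
               c(round(b$mean_rate * n_b), n_b - round(b$mean_rate * n_b)))
  expect_gt(fisher.test(tab)$p.value, 0.01)
})

test_that("training runs are seed-reproducible and chain normalization", {
  units <- synthetic_population()
  r1 <- run_training(units, n_sessions = 2L, session_duration_s = 30,
                     pre_duration_s = 20, seed = 5)
  r2 <- run_training(units, n_sessions = 2L, session_duration_s = 30,
                     pre_duration_s = 20, seed = 5)
  expect_identical(r1$logs[[1]]$spikes, r2$logs[[1]]$spikes)
  expect_identical(r1$logs[[2]]$frames, r2$logs[[2]]$frames)
  expect_identical(r1$units, r2$units)
  # session 2 normalization differs from session 1 (re-estimated from its
  # own pre-experiment under the previous constants)
  expect_false(identical(r1$logs[[1]]$header$groups$mu,
                         r1$logs[[2]]$header$groups$mu))
})
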