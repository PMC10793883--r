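test_that("trajectory score is path length over start-to-target distance", {
  expect_equal(trajectory_score(rbind(c(0, 0), c(5, 0)), c(5, 0)), 1)
  # right-angle path of legs 3 and 4 to a target 5 away: 7/5
  expect_equal(trajectory_score(rbind(c(0, 0), c(3, 0), c(3, 4)), c(3, 4)), 1.4)
  expect_error(trajectory_score(rbind(c(1, 1), c(2, 2)), c(1, 1)), "degenerate")
  # any path is at least as long as its chord
  set.seed(20)
  for (i in 1:20) {
    tr <- cbind(cumsum(rnorm(30)), cumsum(rnorm(30)))
    target <- c(5, 5)
    sc <- trajectory_score(tr, target)
    chord_ratio <- sqrt(sum((tr[30, ] - tr[1, ])^2)) / sqrt(sum((target - tr[1, ])^2))
    expect_gte(sc + 1e-12, chord_ratio)
  }
})

test_that("potent and null values use the target sector's opposing group pair", {
  a <- rbind(c(2, 0.5, 1, 1))
  pn <- potent_null_values(a, target_angle = 0)
  expect_equal(pn$potent, 1.5)
  expect_equal(pn$null, 2.5)
  expect_equal(pn$sector, "right")
  # toward-away orientation flips for the opposite target
  pn_left <- potent_null_values(a, target_angle = pi)
  expect_equal(pn_left$potent, -1.5)
  # equal opposing activation is output-null only
  pn0 <- potent_null_values(rbind(c(1.2, 1.2, 0, 0)), 0)
  expect_equal(pn0$potent, 0)
  # up/down pairs
  pn_up <- potent_null_values(a, pi / 2)
  expect_equal(pn_up$potent, 0)
  expect_equal(pn_up$null, 2)
  # null >= |potent| pointwise since action values are non-negative
  set.seed(4)
  am <- matrix(runif(40, 0, 3), 10, 4)
  pn_r <- potent_null_values(am, 0)
  expect_true(all(pn_r$null >= abs(pn_r$potent)))
})

test_that("medium-speed filter keeps bins between 25% and 75% of maximum speed", {
  a <- matrix(1, 5, 4); a[, 1] <- 1:5
  speed <- c(1, 4, 8, 11, 14)  # vs v_max = 15: keep 3.75..11.25
  pn <- potent_null_values(a, 0, speed = speed, speed_filter = TRUE, v_max = 15)
  expect_equal(length(pn$potent), 3L)
  expect_equal(pn$potent, (2:4) - 1)
  pn_none <- potent_null_values(a, 0, speed = rep(0, 5), speed_filter = TRUE)
  expect_true(pn_none$filtered_out)
  expect_true(is.na(pn_none$potent_mean))
  expect_error(potent_null_values(a, 0, speed_filter = TRUE), "required")
})

test_that("decoded on-axis velocity equals w times the potent value", {
  set.seed(41)
  cfg <- decoder_config()
  for (i in 1:50) {
    a <- runif(4, 0, 3)
    v <- decode_velocity(a, cfg)
    for (ang in c(0, pi / 2, pi, -pi / 2)) {
      pn <- potent_null_values(rbind(a), ang)
      axis_v <- switch(pn$sector, right = v[["vx"]], left = -v[["vx"]],
                       up = v[["vy"]], down = -v[["vy"]])
      expect_equal(axis_v, unname(cfg$w * pn$potent), tolerance = 1e-12)
    }
  }
})

test_that("cosine direction tuning recovers exact and degenerate cases", {
  th <- seq(-pi, pi, length.out = 100)
  fit <- fit_direction_tuning(10 + 4 * cos(th - pi / 2), th)
  expect_equal(fit$pd_angle, pi / 2, tolerance = 1e-9)
  expect_equal(fit$tuning_depth, 8, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  flat <- fit_direction_tuning(rep(7, 100), th)
  expect_equal(flat$tuning_depth, 0, tolerance = 1e-9)
  expect_equal(flat$r2, 0)
  expect_error(fit_direction_tuning(1:10, rep(c(0, 1), 5)), "distinct")
})

test_that("normalized |PD-AD| maps angular difference onto [0, 1]", {
  expect_equal(pd_ad_distance(1.3, 1.3), 0)
  expect_equal(pd_ad_distance(1.3 + pi, 1.3), 1)
  expect_equal(pd_ad_distance(pi / 4, 0), 0.25)
  # symmetric and 2*pi-periodic in both arguments
  set.seed(9)
  pd <- runif(50, -10, 10); ad <- runif(50, -10, 10)
  expect_equal(pd_ad_distance(pd, ad), pd_ad_distance(ad, pd))
  expect_equal(pd_ad_distance(pd + 2 * pi, ad), pd_ad_distance(pd, ad))
  expect_equal(pd_ad_distance(pd, ad - 2 * pi), pd_ad_distance(pd, ad))
  d <- pd_ad_distance(pd, ad)
  expect_true(all(d >= 0 & d <= 1))
  # image spans [0, 1]
  expect_equal(range(pd_ad_distance(seq(0, pi, length.out = 100), 0)), c(0, 1))
})

test_that("logistic trend fitting flags separation and reports McFadden R2", {
  set.seed(90)
  trials <- data.frame(session_index = rep(1:12, each = 100),
                       outcome = rbinom(1200, 1, rep(seq(0.1, 0.9, length.out = 12),
                                                     each = 100)))
  tr <- fit_success_logistic(trials)
  expect_gt(tr$slope, 0)
  expect_lt(tr$slope_p, 0.001)
  expect_true(tr$pseudo_r2 > 0 && tr$pseudo_r2 <= 1)
  expect_false(tr$separation)
  # all-success data is flagged as separated but still yields a fit
  all_s <- data.frame(session_index = rep(1:4, each = 10), outcome = 1)
  tr_s <- fit_success_logistic(all_s)
  expect_true(tr_s$separation)
  expect_true(is.finite(tr_s$slope))
  # step separation (all fail then all succeed) is detected
  step_tr <- data.frame(session_index = rep(1:6, each = 20),
                        outcome = rep(c(0, 1), each = 60))
  tr_step <- fit_success_logistic(step_tr)
  expect_true(tr_step$separation)
  expect_true(is.finite(tr_step$slope_p))
})

test_that("occupancy maps conserve counts and localize straight paths", {
  path <- cbind(seq(0, 7, by = 0.1), 0)
  g <- occupancy_map(path, xlim = c(-15, 15), ylim = c(-12.5, 12.5),
                     nx = 30, ny = 25)
  expect_equal(sum(g), nrow(path))
  # only cells along y ~ 0, x in [0, 7] are visited
  visited <- which(g > 0, arr.ind = TRUE)
  expect_true(all(visited[, 2] %in% c(13, 14)))
  expect_true(all(visited[, 1] >= 15 & visited[, 1] <= 23))
  expect_error(occupancy_map(cbind(100, 0)), "cover")
})

test_that("direction-binned success respects sectors and weighted means", {
  trials <- data.frame(
    target_angle = c(0, 0.1, pi / 2, pi, -pi / 2, -pi / 2, NA),
    outcome = c("success", "fail", "success", "success", "fail", "success",
                "success"))
  p <- direction_binned_success(trials)
  expect_equal(unname(p["right"]), 0.5)
  expect_equal(unname(p["up"]), 1)
  expect_equal(unname(p["down"]), 0.5)
  # weighted mean over non-missing bins equals the overall rate
  n_by <- table(sector_of(trials$target_angle[1:6]))
  overall <- mean(trials$outcome[1:6] == "success")
  expect_equal(sum(p[names(n_by)] * as.numeric(n_by)) / 6, overall)
  # all trials in one quadrant: others missing
  one <- data.frame(target_angle = rep(0, 5), outcome = "success")
  p1 <- direction_binned_success(one)
  expect_true(all(is.na(p1[c("up", "left", "down")])))
  expect_equal(unname(p1["right"]), 1)
})

test_that("session-level metrics integrate trials, tuning and group activity", {
  log <- fixture_trained_session()
  pn <- session_potent_null(log)
  expect_true(all(pn$null_mean >= abs(pn$potent_mean) - 1e-9))
  sc <- session_trajectory_scores(log)
  expect_true(all(sc$score >= 1 - log$header$task_config$target_radius /
                    log$header$task_config$target_distance - 1e-9))
  tt <- unit_tuning_table(log, channels = 1:4)
  expect_equal(nrow(tt), 4L)
  expect_true(all(tt$r2 >= 0 & tt$r2 <= 1))
  expect_true(all(tt$tuning_depth >= 0))
  # well-trained aligned units should tune to their assigned directions
  ad <- log$header$units$assigned_direction[1:4]
  expect_lt(max(pd_ad_distance(tt$pd_angle, ad)), 0.2)
})
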