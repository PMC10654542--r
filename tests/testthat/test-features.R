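test_that("trapezium time average matches hand computations", {
  expect_equal(time_average_trapezium(c(0, 1, 2), c(0, 1, 2), c(0, 2)), 1)
  # (0+2)/2*1 + (2+2)/2*2 = 5, over 3 s
  expect_equal(time_average_trapezium(c(0, 1, 3), c(0, 2, 2), c(0, 3)), 5 / 3)
  expect_equal(time_average_trapezium(c(0, 0.7, 2.2), rep(4.5, 3),
                                      c(0.2, 1.9)), 4.5)
  expect_true(is.na(time_average_trapezium(1, 2, c(0, 3))))
  expect_error(time_average_trapezium(c(0, 1, 1), c(1, 2, 3), c(0, 1)),
               "strictly increasing")
})

test_that("trapezium average equals its dense-resampling oracle", {
  set.seed(7)
  for (rep in 1:5) {
    t <- sort(runif(40, 0, 10))
    v <- sin(t) + 0.3 * t
    win <- sort(runif(2, 1, 9))
    if (diff(win) < 0.5) win[2] <- win[1] + 0.5
    # oracle: integrate the piecewise-linear interpolant on a 100x finer grid
    expect_equal(time_average_trapezium(t, v, win),
                 oracle_time_average(t, v, win, n_fine = 4000),
                 tolerance = 1e-6)
  }
})

test_that("outcome classification and interruption follow the event log", {
  expect_identical(classify_outcome(make_event_log(contact_time = 3)),
                   "virtual_death")
  expect_identical(classify_outcome(make_event_log(magical_force_time = 2)),
                   "virtual_death")
  expect_identical(classify_outcome(make_event_log(shelter_entry_time = 5)),
                   "escape_to_shelter")
  expect_identical(classify_outcome(make_event_log()), "survived")
  expect_error(classify_outcome(make_event_log(contact_time = 3,
                                               shelter_entry_time = 5)),
               "malformed-log")

  expect_true(interrupted_escape(TRUE, "survived"))
  expect_false(interrupted_escape(TRUE, "escape_to_shelter"))
  expect_true(is.na(interrupted_escape(FALSE, "survived")))
})

test_that("escape initiation detection requires sustained outward motion", {
  fruit <- c(0, 2.5)
  t <- seq(0, 6, by = 0.05)
  still <- make_recording(t, rep(0, length(t)), rep(2.5, length(t)))
  expect_false(detect_escape_initiation(still, 1, fruit)$initiated)

  # steps 0.6 m away at t = 2 and keeps walking
  y <- ifelse(t < 2, 2.5, 2.5 - 0.6 - 1.5 * (t - 2))
  walk <- make_recording(t, rep(0, length(t)), y)
  res <- detect_escape_initiation(walk, 1, fruit)
  expect_true(res$initiated)
  expect_equal(res$time, 2, tolerance = 0.1)

  # a brief 0.1 s excursion does not count (sustain rule, 0.3 s)
  y2 <- rep(2.5, length(t))
  y2[t >= 2 & t < 2.1] <- 2.5 - 0.6 - (t[t >= 2 & t < 2.1] - 2)
  blip <- make_recording(t, rep(0, length(t)), y2)
  expect_false(detect_escape_initiation(blip, 1, fruit)$initiated)
})

test_that("minimum distances use the head tracker", {
  t <- c(0, 1)
  rec <- make_recording(t, c(0, 0), c(2.5, 2.5))
  d <- min_distances(rec, shelter_position = c(0, -2.5))
  expect_equal(d$min_dist_shelter, 5)
  expect_true(is.na(d$min_dist_threat))

  rec2 <- make_recording(c(0, 1, 2), c(0, 0, 0), c(0, 0, 0),
                         threat_x = c(3, 2, 0), threat_y = c(0, 0, 0))
  expect_equal(min_distances(rec2, c(0, -2.5))$min_dist_threat, 0)
  rec3 <- make_recording(c(0, 1), c(0, 0), c(0, 0),
                         threat_x = c(3, 2), threat_y = c(0, 0))
  expect_equal(min_distances(rec3, c(0, -2.5))$min_dist_threat, 2)
})

test_that("escape speed statistics: peak, mean, and missingness", {
  t <- seq(0, 2.5, by = 0.01)
  rec <- make_recording(t, rep(0, length(t)), 2.5 - 2 * t)
  sp <- escape_speed_stats(rec, 0, 2.5)
  expect_equal(sp$peak, 2, tolerance = 1e-6)
  expect_equal(sp$mean, 2, tolerance = 1e-6)

  # 1 m/s then 3 m/s for equal durations: mean 2, peak 3
  t2 <- seq(0, 4, by = 0.01)
  y <- ifelse(t2 < 2, t2, 2 + 3 * (t2 - 2))
  rec2 <- make_recording(t2, rep(0, length(t2)), y)
  sp2 <- escape_speed_stats(rec2, 0, 4)
  expect_equal(sp2$peak, 3, tolerance = 0.01)
  expect_equal(sp2$mean, 2, tolerance = 0.02)

  expect_true(is.na(escape_speed_stats(rec, NA_real_, 2.5)$peak))
  expect_true(is.na(escape_speed_stats(rec, NA_real_, 2.5)$mean))
})

test_that("orientation cosine hits the landmark angles and is antisymmetric", {
  t <- seq(0, 2, by = 0.1)
  n <- length(t)
  toward <- make_recording(t, rep(0, n), rep(0, n),
                           head_fx = rep(0, n), head_fy = rep(1, n),
                           threat_x = rep(0, n), threat_y = rep(5, n))
  expect_equal(orientation_cosine(toward, "head", c(0, 2)), 1)
  expect_equal(orientation_cosine(toward, "pelvis", c(0, 2)), 1)

  away <- make_recording(t, rep(0, n), rep(0, n),
                         head_fx = rep(0, n), head_fy = rep(-1, n),
                         threat_x = rep(0, n), threat_y = rep(5, n))
  expect_equal(orientation_cosine(away, "head", c(0, 2)), -1)

  perp <- make_recording(t, rep(0, n), rep(0, n),
                         head_fx = rep(1, n), head_fy = rep(0, n),
                         threat_x = rep(0, n), threat_y = rep(5, n))
  expect_equal(orientation_cosine(perp, "head", c(0, 2)), 0)

  # antisymmetry on a generated mixed-orientation recording
  set.seed(3)
  ang <- runif(n, 0, 2 * pi)
  mixed <- make_recording(t, rep(0, n), rep(0, n),
                          head_fx = sin(ang), head_fy = cos(ang),
                          threat_x = rep(1, n), threat_y = rep(3, n))
  flipped <- mixed
  flipped$head_fx <- -flipped$head_fx
  flipped$head_fy <- -flipped$head_fy
  expect_equal(orientation_cosine(flipped, "head", c(0, 2)),
               -orientation_cosine(mixed, "head", c(0, 2)),
               tolerance = 1e-9)
})

test_that("visual scanning accumulates path length of the forward vector", {
  t <- seq(0, 3, by = 1 / 90)
  n <- length(t)
  static <- make_recording(t, rep(0, n), rep(0, n))
  expect_equal(visual_scanning_rate(static, "head", c(0, 3)), 0)

  yaw <- 30 * t * pi / 180   # constant 30 deg/s rotation
  rot <- make_recording(t, rep(0, n), rep(0, n),
                        head_fx = sin(yaw), head_fy = cos(yaw))
  expect_equal(visual_scanning_rate(rot, "head", c(0, 3)), 30,
               tolerance = 1e-6)

  # independent oracle: cumulative |yaw difference| on an oscillation
  yaw2 <- 10 * sin(2 * pi * t) * pi / 180
  osc <- make_recording(t, rep(0, n), rep(0, n),
                        head_fx = sin(yaw2), head_fy = cos(yaw2))
  win <- c(0, 1.5)
  sel <- t >= win[1] & t <= win[2]
  oracle <- sum(abs(diff(yaw2[sel]))) * 180 / pi / diff(win)
  expect_equal(visual_scanning_rate(osc, "head", win), oracle,
               tolerance = 1e-6)

  # sampling robustness: halving dt moves the constant-rate estimate < 1%
  t2 <- seq(0, 3, by = 1 / 180)
  yaw3 <- 30 * t2 * pi / 180
  rot2 <- make_recording(t2, rep(0, length(t2)), rep(0, length(t2)),
                         head_fx = sin(yaw3), head_fy = cos(yaw3))
  r1 <- visual_scanning_rate(rot, "head", c(0, 3))
  r2 <- visual_scanning_rate(rot2, "head", c(0, 3))
  expect_lt(abs(r2 - r1) / r1, 0.01)
})

test_that("fruit picking rate counts picks in a half-open window", {
  expect_equal(fruit_picking_rate(c(0.5, 1.2, 1.9), c(0, 2)), 1.5)
  expect_equal(fruit_picking_rate(numeric(0), c(0, 2)), 0)
  expect_equal(fruit_picking_rate(seq(0.4, 12.4, length.out = 14),
                                  c(0, 12.5)), 1.12)
  # boundary: a pick exactly at the window end is excluded
  expect_equal(fruit_picking_rate(c(2), c(0, 2)), 0)
})

test_that("epoch summaries respect the missingness contract", {
  sdv <- generate_epoch_scenario(threat_spec("dog", -3.5), "divert", "long",
                                 seed = 21)
  still <- simulate_epoch(sdv, agent_policy(escape_target = "none"),
                          seed = 22)
  su <- summarize_epoch(still$recording, still$event_log, sdv)
  expect_identical(su$outcome, "survived")
  expect_false(su$initiated_escape)
  esc_fields <- c("escape_initiation_time", "interrupted_escape",
                  "peak_speed", "mean_speed", "body_orient_escape",
                  "head_orient_escape", "fruit_rate_escape", "scan_escape")
  for (f in esc_fields) expect_true(is.na(su[[f]]), label = f)
  non_esc <- c("min_dist_shelter", "min_dist_threat", "body_orient_appear",
               "head_orient_appear", "fruit_rate_appear", "scan_appear")
  for (f in non_esc) expect_false(is.na(su[[f]]), label = f)

  # a textbook escape populates everything within bounds
  s <- generate_epoch_scenario(threat_spec("dog", -3.5), "attack", "long",
                               seed = 23)
  sim <- simulate_epoch(s, agent_policy(initiation_delay = 1.5,
                                        escape_speed = 2), seed = 24)
  su2 <- summarize_epoch(sim$recording, sim$event_log, s)
  expect_identical(su2$outcome, "escape_to_shelter")
  expect_true(su2$initiated_escape)
  for (f in c(esc_fields, non_esc)) {
    expect_false(is.na(su2[[f]]), label = f)
  }
  for (f in c("body_orient_appear", "body_orient_escape",
              "head_orient_appear", "head_orient_escape")) {
    expect_gte(su2[[f]], -1); expect_lte(su2[[f]], 1)
  }
  expect_gte(su2$scan_appear, 0)

  # determinism of the full pipeline epoch -> summary
  sim_b <- simulate_epoch(s, agent_policy(initiation_delay = 1.5,
                                          escape_speed = 2), seed = 24)
  expect_identical(su2, summarize_epoch(sim_b$recording, sim_b$event_log, s))
})

test_that("no-threat epochs anchor on a seeded reference time", {
  s <- generate_epoch_scenario(threat_spec("dog", -3.5), "attack", "long",
                               seed = 31)
  t <- seq(0, 15, by = 1 / 45)
  n <- length(t)
  rec <- make_recording(t, rep(0, n), rep(2.5, n))
  log <- make_event_log(threat_appearance_time = NA_real_,
                        fruit_pick_times = seq(1, 14, by = 1.1),
                        epoch_end_time = 15)
  su <- summarize_epoch(rec, log, s)
  expect_gte(su$reference_time_used, 1)
  expect_lte(su$reference_time_used, 11)
  expect_false(is.na(su$fruit_rate_appear))
  su_b <- summarize_epoch(rec, log, s)
  expect_identical(su$reference_time_used, su_b$reference_time_used)
})
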