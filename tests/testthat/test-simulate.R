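test_that("threat path follows the scenario schedule", {
  # attack with stationary participant at the fruit: arrival at nominal time
  s <- generate_epoch_scenario(threat_spec("dog", -3.5), "attack", "short",
                               approach_angle = 0, seed = 1)
  path <- simulate_threat_path(s, dt = 1 / 90)
  d_fruit <- sqrt((path$x - s$fruit_position_2d[1])^2 +
                    (path$y - s$fruit_position_2d[2])^2)
  arrive <- which(d_fruit < 0.05)[1]
  expect_lt(abs(path$t[arrive] - s$nominal_approach_time), 0.05 / 3.5 + 1.5 / 90)

  # divert: heading changes at 20% of the approach time (within one step)
  sd <- generate_epoch_scenario(threat_spec("dog", -3.5), "divert", "short",
                                approach_angle = -45, seed = 2)
  pd <- simulate_threat_path(sd, dt = 1 / 90)
  vx <- diff(pd$x); vy <- diff(pd$y)
  hd <- atan2(vx, vy)
  change <- which(abs(diff(hd)) > 1e-6)[1] + 1L
  expect_lt(abs(pd$t[change] - sd$divert_onset_time), 2 / 90)
  expect_lt(abs(attr(pd, "mode_switch_time") - sd$divert_onset_time),
            1.5 / 90)

  # ballistic rock divert: one straight line that misses the fruit
  sr <- generate_epoch_scenario(default_threats()$rock, "divert", "long",
                                seed = 3)
  pr <- simulate_threat_path(sr, dt = 1 / 90)
  hr <- atan2(diff(pr$x), diff(pr$y))
  expect_lt(max(abs(diff(hr))), 1e-9)
  d_fruit_r <- sqrt((pr$x - sr$fruit_position_2d[1])^2 +
                      (pr$y - sr$fruit_position_2d[2])^2)
  expect_gt(min(d_fruit_r), 0.1)
})

test_that("epoch outcomes follow escape feasibility", {
  s <- generate_epoch_scenario(threat_spec("dog", -3.5), "attack", "short",
                               seed = 4)
  # instant initiation at the assumed speed escapes a short-TTI fast threat
  quick <- simulate_epoch(s, agent_policy(initiation_delay = 0,
                                          escape_speed = 2), seed = 5)
  expect_identical(quick$event_log$outcome, "escape_to_shelter")

  # never moving under attack dies around the nominal approach time
  still <- simulate_epoch(s, agent_policy(escape_target = "none"), seed = 6)
  expect_identical(still$event_log$outcome, "virtual_death")
  expect_lt(abs(still$event_log$contact_time -
                  still$event_log$threat_appearance_time -
                  s$nominal_approach_time), 0.3)

  # never moving while a chasing threat diverts survives
  sdv <- generate_epoch_scenario(threat_spec("dog", -3.5), "divert", "short",
                                 seed = 7)
  sv <- simulate_epoch(sdv, agent_policy(escape_target = "none"), seed = 8)
  expect_identical(sv$event_log$outcome, "survived")
})

test_that("every epoch terminates with exactly one outcome, contact is consistent", {
  threats <- default_threats()
  set.seed(42)
  for (i in 1:12) {
    thr <- threats[[sample(length(threats), 1)]]
    s <- generate_epoch_scenario(thr, sample(c("attack", "divert"), 1),
                                 sample(c("short", "long"), 1),
                                 seed = 100 + i)
    pol <- agent_policy(initiation_delay = runif(1, 0, 3),
                        escape_speed = runif(1, 0.8, 2.5))
    sim <- simulate_epoch(s, pol, seed = 200 + i)
    log <- sim$event_log
    terminal <- c(shelter = !is.na(log$shelter_entry_time),
                  contact = !is.na(log$contact_time),
                  force = !is.na(log$magical_force_time))
    expect_lte(sum(terminal), 1L)
    expect_true(log$outcome %in%
                  c("escape_to_shelter", "survived", "virtual_death"))
    times <- c(log$threat_appearance_time, log$fruit_pick_times,
               log$shelter_entry_time, log$contact_time)
    expect_true(all(times[!is.na(times)] <= log$epoch_end_time + 1e-9))
    if (!is.na(log$contact_time)) {
      i_c <- which.min(abs(sim$recording$t - log$contact_time))
      d <- sqrt((sim$recording$head_x[i_c] - sim$recording$threat_x[i_c])^2 +
                  (sim$recording$head_y[i_c] - sim$recording$threat_y[i_c])^2)
      expect_lte(d, 0.4 + 0.05)
    }
  }
})

test_that("feasibility boundary: initiation at exactly T_Plan is a dead heat", {
  # disable door semantics to expose the raw kinematics: both movers should
  # reach the shelter within about one time step of each other
  s <- generate_epoch_scenario(threat_spec("p", -3), "attack", "short",
                               approach_angle = 0, seed = 9)
  pol <- agent_policy(initiation_delay = 1.5, escape_speed = 2,
                      pos_noise_sd = 0)
  sim <- simulate_epoch(s, pol, seed = 10, contact_radius = 0.01,
                        door_block_radius = 0, shelter_radius = 0.05)
  log <- sim$event_log
  rec <- sim$recording
  end <- nrow(rec)
  d_thr_shelter <- sqrt((rec$threat_x[end] - s$shelter_position_2d[1])^2 +
                          (rec$threat_y[end] - s$shelter_position_2d[2])^2)
  d_par_shelter <- sqrt((rec$head_x[end] - s$shelter_position_2d[1])^2 +
                          (rec$head_y[end] - s$shelter_position_2d[2])^2)
  # at epoch end both are at the shelter (within one step at their speeds)
  expect_lt(d_par_shelter, 0.05 + 2 * (1 / 90) * 2)
  expect_lt(d_thr_shelter, 0.05 + 2 * (1 / 90) * 3 + 0.1)
})

test_that("longer initiation delays never improve survival", {
  s <- generate_epoch_scenario(threat_spec("dog", -3.5), "attack", "short",
                               approach_angle = 0, seed = 11)
  escaped <- vapply(seq(0.2, 3, by = 0.4), function(d) {
    sim <- simulate_epoch(s, agent_policy(initiation_delay = d,
                                          escape_speed = 2), seed = 12)
    sim$event_log$outcome == "escape_to_shelter"
  }, logical(1))
  expect_true(all(diff(as.integer(escaped)) <= 0))
})

test_that("medusa force triggers on sustained gaze, inclusively at threshold", {
  t <- seq(0, 5, by = 0.02)
  # head locked on a stationary threat 2 m ahead
  rec_on <- make_recording(t, head_x = rep(0, length(t)),
                           head_y = rep(0, length(t)),
                           head_fx = rep(0, length(t)),
                           head_fy = rep(1, length(t)),
                           threat_x = rep(0, length(t)),
                           threat_y = rep(2, length(t)))
  log <- make_event_log(threat_appearance_time = 1)
  res <- medusa_force(rec_on, log)
  expect_true(res$triggered)
  expect_equal(res$time, 1 + 0.1, tolerance = 0.03)
  # cosine exactly at threshold still triggers (inclusive comparison)
  res_b <- medusa_force(rec_on, log, cos_threshold = 1)
  expect_true(res_b$triggered)

  rec_off <- make_recording(t, head_x = rep(0, length(t)),
                            head_y = rep(0, length(t)),
                            head_fx = rep(0, length(t)),
                            head_fy = rep(-1, length(t)),
                            threat_x = rep(0, length(t)),
                            threat_y = rep(2, length(t)))
  expect_false(medusa_force(rec_off, log)$triggered)
})

test_that("non-natural elements: force shield and hands-up", {
  s <- generate_epoch_scenario(threat_spec("panther", -4), "attack", "short",
                               seed = 13)
  shielded <- simulate_epoch(s, agent_policy(escape_target = "none"),
                             seed = 14,
                             condition_flags = list(force_shield = TRUE))
  expect_identical(shielded$event_log$outcome, "survived")
  expect_true(is.na(shielded$event_log$contact_time))

  hands <- simulate_epoch(s, agent_policy(initiation_delay = 1,
                                          escape_target = "none",
                                          hands_up = TRUE), seed = 15,
                          condition_flags = list(hands_up_signaled = TRUE))
  log <- hands$event_log
  expect_identical(log$outcome, "survived")
  rec <- hands$recording
  after <- which(rec$t > log$hands_up_time + 0.1 & !is.na(rec$threat_x))
  expect_lt(max(rec$threat_x[after]) - min(rec$threat_x[after]), 1e-9)
})

test_that("medusa epochs end in virtual death by magical force", {
  s <- generate_epoch_scenario(threat_spec("panther", -4), "attack", "long",
                               seed = 16)
  # a participant that stares at the threat (orientation 1) and never runs
  pol <- agent_policy(escape_target = "none", body_orientation = 1,
                      head_scan_base = 0, head_scan_burst = 0)
  sim <- simulate_epoch(s, pol, seed = 17,
                        condition_flags = list(medusa = TRUE))
  expect_identical(sim$event_log$outcome, "virtual_death")
  expect_false(is.na(sim$event_log$magical_force_time))
  expect_lte(sim$event_log$epoch_end_time,
             sim$event_log$threat_appearance_time + 0.5)
})

test_that("cohorts reproduce exactly under a seed and inject stated effects", {
  des <- default_design()[1:6, ]
  c1 <- generate_cohort(2, design = des, seed = 99, dt = 1 / 45)
  c2 <- generate_cohort(2, design = des, seed = 99, dt = 1 / 45)
  expect_identical(c1, c2)

  # zero between-subject SD and zero noise: the commanded initiation delay
  # in a cell is identical for every subject and epoch
  eff0 <- default_effect_spec(
    initiation_delay_subject_sd = 0, initiation_delay_noise_sd = 0,
    delay_q_coef = c(), orientation_q_coef = c(),
    escape_prob = c(attack_short = 1, attack_long = 1,
                    divert_short = 1, divert_long = 1))
  des1 <- data.frame(threat = "dog", tti = "short", behavior = "attack")
  c0 <- generate_cohort(3, design = des1, effect_spec = eff0, seed = 5,
                        dt = 1 / 45)
  delays <- vapply(c0$epochs, function(ep) {
    ep$event_log$escape_start_commanded - ep$event_log$threat_appearance_time
  }, numeric(1))
  expect_equal(max(delays) - min(delays), 0)
})

test_that("cohort recovers the injected initiation-delay gap at scale", {
  # short 1.3 s vs long 2.9 s, attack epochs from one fast threat:
  # cell-mean difference of measured initiation times ~ 1.6 s
  des <- expand.grid(threat = "dog", tti = c("short", "long"),
                     behavior = "attack", rep = 1:2,
                     stringsAsFactors = FALSE)[, 1:3]
  eff <- default_effect_spec(
    escape_prob = c(attack_short = 1, attack_long = 1,
                    divert_short = 1, divert_long = 1))
  co <- generate_cohort(15, design = des, effect_spec = eff, seed = 31,
                        dt = 1 / 45)
  su <- summarize_cohort(co)
  m <- tapply(su$escape_initiation_time, su$tti, mean, na.rm = TRUE)
  gap <- m[["long"]] - m[["short"]]
  sem <- sqrt(sum(tapply(su$escape_initiation_time, su$tti, function(x) {
    x <- x[!is.na(x)]
    stats::var(x) / length(x)
  })))
  expect_lt(abs(gap - 1.6), 3 * sem + 0.05)
})
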