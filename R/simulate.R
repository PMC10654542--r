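# Epoch simulation: threat and participant motion under a scenario_spec and a
# configurable participant policy, producing trajectory recordings and event
# logs with the statistical structure the downstream analysis assumes.

rot2 <- function(v, deg) {
  r <- deg * pi / 180
  c(cos(r) * v[1] - sin(r) * v[2], sin(r) * v[1] + cos(r) * v[2])
}

#' Participant behavior policy for synthetic epochs
#'
#' A stand-in for participant behavior: when and how fast they escape, how
#' they orient their body and head, how fast they pick fruit, and whether
#' they vocalize. All parameters can be condition-dependent when building a
#' cohort.
#'
#' @param initiation_delay Escape initiation delay after threat appearance,
#'   seconds. A single number, `Inf` for a participant who never moves, or a
#'   function `function(n)` returning draws.
#' @param escape_speed Escape running speed, m/s, >= 0.
#' @param escape_target `"shelter"` to run to the shelter, `"flee"` to run
#'   away from the threat without a goal, `"none"` to stay put.
#' @param interrupt_on_divert Abort (or withhold) the escape once a chasing
#'   threat visibly diverts.
#' @param body_orientation Mean cosine of the angle between the body forward
#'   vector and the participant-to-threat line after appearance: `1` faces
#'   the threat, `-1` faces directly away; any value in `[-1, 1]`.
#' @param head_scan_base Baseline cumulative head-scanning rate, deg/s.
#' @param head_scan_burst Additional scanning rate during the 1.5 s after
#'   threat appearance, deg/s.
#' @param fruit_pick_rate Fruit picking rate while at the bush, picks/s
#'   (must be < 1 because picks have a 1 s minimum gap).
#' @param vocalize_probability Per-epoch probability of a vocalization event.
#' @param hands_up Raise both hands at the would-be initiation time when the
#'   epoch signals hands-up sensitivity (stops the threat).
#' @param pos_noise_sd Gaussian tracker position noise, metres.
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(initiation_delay = 1.5,
                         escape_speed = 2,
                         escape_target = c("shelter", "flee", "none"),
                         interrupt_on_divert = FALSE,
                         body_orientation = -0.2,
                         head_scan_base = 25,
                         head_scan_burst = 45,
                         fruit_pick_rate = 0.8,
                         vocalize_probability = 0,
                         hands_up = FALSE,
                         pos_noise_sd = 0.003) {
  escape_target <- match.arg(escape_target)
  stopifnot(escape_speed >= 0,
            vocalize_probability >= 0, vocalize_probability <= 1,
            fruit_pick_rate >= 0,
            head_scan_base >= 0, head_scan_burst >= 0,
            pos_noise_sd >= 0)
  if (is.numeric(body_orientation)) {
    body_orientation <- max(-1, min(1, body_orientation))
  } else stop("body_orientation must be numeric in [-1, 1]")
  structure(
    list(initiation_delay = initiation_delay,
         escape_speed = escape_speed,
         escape_target = escape_target,
         interrupt_on_divert = isTRUE(interrupt_on_divert),
         body_orientation = body_orientation,
         head_scan_base = head_scan_base,
         head_scan_burst = head_scan_burst,
         fruit_pick_rate = fruit_pick_rate,
         vocalize_probability = vocalize_probability,
         hands_up = isTRUE(hands_up),
         pos_noise_sd = pos_noise_sd),
    class = "agent_policy"
  )
}

# Threat positions on a time grid (times since appearance), given aligned
# participant positions for pursuit. Straight approach toward the fruit
# position until the scheduled chase/divert onset; afterwards per-step pure
# pursuit of the participant's current head position (attack) or straight
# motion along the divert heading (divert). The ballistic rock never changes
# heading (its divert variant starts with the +/-5 degree offset baked in).
# Returns an n x 2 matrix with attribute "mode_switch_time" (NA when the
# threat never switches).
threat_path_on_grid <- function(spec, tt, participant_xy) {
  n <- length(tt)
  init <- spec$initial_threat_position
  fruit <- spec$fruit_position_2d
  v <- abs(spec$threat$speed)
  u <- fruit - init
  L <- sqrt(sum(u^2))
  u <- u / L
  if (!is.na(spec$rock_offset_deg)) u <- rot2(u, spec$rock_offset_deg)
  onset <- if (spec$behavior == "attack") spec$chase_onset_time
           else spec$divert_onset_time
  has_switch <- spec$threat$is_chasing && !is.na(onset)
  X <- matrix(NA_real_, n, 2)
  i0 <- if (has_switch) match(TRUE, tt >= onset) else NA_integer_
  straight_upto <- if (has_switch && !is.na(i0)) i0 else n
  idx <- seq_len(straight_upto)
  X[idx, 1] <- init[1] + v * tt[idx] * u[1]
  X[idx, 2] <- init[2] + v * tt[idx] * u[2]
  switch_time <- NA_real_
  if (has_switch && !is.na(i0) && i0 < n) {
    switch_time <- tt[i0]
    if (spec$behavior == "divert") {
      d <- heading_unit(spec$divert_heading)
      rest <- (i0 + 1):n
      X[rest, 1] <- X[i0, 1] + v * (tt[rest] - tt[i0]) * d[1]
      X[rest, 2] <- X[i0, 2] + v * (tt[rest] - tt[i0]) * d[2]
    } else {
      dir_prev <- u
      for (i in i0:(n - 1L)) {
        dx <- participant_xy[i, 1] - X[i, 1]
        dy <- participant_xy[i, 2] - X[i, 2]
        nd <- sqrt(dx * dx + dy * dy)
        if (nd > 1e-9) {
          dir_prev <- c(dx / nd, dy / nd)
        }
        step <- v * (tt[i + 1L] - tt[i])
        X[i + 1L, 1] <- X[i, 1] + step * dir_prev[1]
        X[i + 1L, 2] <- X[i, 2] + step * dir_prev[2]
      }
    }
  }
  attr(X, "mode_switch_time") <- switch_time
  X
}

#' Simulate a threat's path through an epoch
#'
#' @param spec A `scenario_spec`.
#' @param participant_path Function of time since threat appearance returning
#'   the participant head position `c(x, y)`; used for pursuit after chase
#'   onset. Defaults to a participant standing at the fruit bush.
#' @param dt Time step, seconds.
#' @param t_max Duration to simulate, seconds since appearance.
#' @return Data frame with columns `t`, `x`, `y` (t measured from threat
#'   appearance) and attribute `mode_switch_time` giving the realized
#'   chase/divert switch timestamp.
#' @export
simulate_threat_path <- function(spec, participant_path = NULL, dt = 1 / 90,
                                 t_max = NULL) {
  stopifnot(dt > 0)
  if (is.null(t_max)) t_max <- spec$nominal_approach_time + 5
  tt <- seq(0, t_max, by = dt)
  if (is.null(participant_path)) {
    fp <- spec$fruit_position_2d
    participant_path <- function(t) fp
  }
  P <- t(vapply(tt, participant_path, numeric(2)))
  X <- threat_path_on_grid(spec, tt, P)
  out <- data.frame(t = tt, x = X[, 1], y = X[, 2])
  attr(out, "mode_switch_time") <- attr(X, "mode_switch_time")
  out
}

#' Simulate one full epoch
#'
#' Runs the encounter: the participant picks fruit at the bush until their
#' initiation delay after threat appearance, then escapes per policy; the
#' threat follows its scenario schedule. The epoch terminates by threat
#' contact, shelter entry (contact instead if the threat blocks the door), or
#' timeout, in line with the three possible outcomes. The appearance delay is
#' drawn uniformly from the scenario's appearance-delay law (1-11 s).
#'
#' @param spec A `scenario_spec`.
#' @param policy An [agent_policy()].
#' @param dt Nominal sampling interval, seconds, in (0, 0.1]. Default 1/90 s
#'   (VR frame rate).
#' @param seed Optional integer seed.
#' @param max_duration Epoch duration cap, seconds; default
#'   `max(12.5, appearance + approach time + 8)` capped at 40 s.
#' @param condition_flags List with logicals `force_shield`,
#'   `hands_up_signaled`, `medusa` (all default `FALSE`). With an active
#'   force shield, threat contact does not kill. A hands-up policy in a
#'   signaled epoch halts the threat. Medusa epochs kill on sustained gaze
#'   at the threat (see [medusa_force()]).
#' @param timestamp_jitter Fractional jitter of sample intervals (e.g. 0.1
#'   for +/-10%), emulating irregular tracker timing.
#' @param contact_radius Participant-threat contact distance, metres.
#' @param door_block_radius Threat-shelter distance below which shelter entry
#'   is converted to contact, metres.
#' @param shelter_radius Radius of the shelter entry region, metres.
#' @return List with elements `recording` (data frame: `t`, `head_x`,
#'   `head_y`, `head_fx`, `head_fy`, `pelvis_x`, `pelvis_y`, `pelvis_fx`,
#'   `pelvis_fy`, `threat_x`, `threat_y`; threat columns `NA` before
#'   appearance) and `event_log` (list of event times, condition flags and
#'   the outcome).
#' @export
simulate_epoch <- function(spec, policy, dt = 1 / 90, seed = NULL,
                           max_duration = NULL,
                           condition_flags = list(),
                           timestamp_jitter = 0,
                           contact_radius = 0.4,
                           door_block_radius = 1.0,
                           shelter_radius = 0.5) {
  stopifnot(dt > 0, dt <= 0.1, timestamp_jitter >= 0, timestamp_jitter < 1)
  flags <- utils::modifyList(
    list(force_shield = FALSE, hands_up_signaled = FALSE, medusa = FALSE),
    condition_flags)
  if (policy$hands_up && !flags$hands_up_signaled && policy$escape_target == "none" &&
      is.infinite(first_finite(policy$initiation_delay))) {
    # a hands-up-only policy in an unsignaled epoch has no action available
    stop("config error: policy relies on hands_up but the epoch does not signal it")
  }
  if (!is.null(seed)) set.seed(seed)

  t_app <- stats::runif(1, spec$appearance_delay_law[1],
                        spec$appearance_delay_law[2])
  delay <- if (is.function(policy$initiation_delay)) {
    policy$initiation_delay(1)
  } else policy$initiation_delay
  if (policy$escape_target == "none") delay <- Inf

  if (is.null(max_duration)) {
    max_duration <- min(40, max(spec$min_epoch_duration,
                                t_app + spec$nominal_approach_time + 8))
  }

  n <- ceiling(max_duration / dt) + 1L
  dts <- rep(dt, n - 1L)
  if (timestamp_jitter > 0) {
    dts <- dts * (1 + timestamp_jitter * stats::runif(n - 1L, -1, 1))
  }
  tt <- c(0, cumsum(dts))

  fruit <- spec$fruit_position_2d
  shelter <- spec$shelter_position_2d

  # hands-up halts the threat instead of escape
  hands_up_active <- flags$hands_up_signaled && policy$hands_up
  hands_up_time <- NA_real_
  if (hands_up_active) {
    hands_up_time <- t_app + if (is.finite(delay)) delay else 1
    delay <- Inf
  }

  # escape interruption when a chasing threat diverts
  t0 <- t_app + delay
  abort_time <- Inf
  if (policy$interrupt_on_divert && spec$behavior == "divert" &&
      spec$threat$is_chasing && is.finite(delay)) {
    t_div <- t_app + spec$divert_onset_time + 0.3  # 0.3 s reaction time
    if (t0 >= t_div) {
      delay <- Inf
      t0 <- Inf
    } else {
      abort_time <- t_div
    }
  }

  # participant head positions (noise added later)
  P <- matrix(rep(fruit, each = n), n, 2)
  escaping <- is.finite(t0) && policy$escape_speed > 0
  esc_dir <- c(0, -1)
  if (escaping) {
    if (policy$escape_target == "shelter") {
      esc_dir <- shelter - fruit
      d_goal <- sqrt(sum(esc_dir^2))
      esc_dir <- esc_dir / d_goal
    } else { # flee: straight away from the threat's initial position
      esc_dir <- fruit - spec$initial_threat_position
      esc_dir <- esc_dir / sqrt(sum(esc_dir^2))
      d_goal <- Inf
    }
    s <- pmin(pmax(tt - t0, 0) * policy$escape_speed,
              policy$escape_speed * max(abort_time - t0, 0))
    s <- pmin(s, d_goal)
    P[, 1] <- fruit[1] + s * esc_dir[1]
    P[, 2] <- fruit[2] + s * esc_dir[2]
  }

  # threat positions (NA before appearance)
  idx_app <- match(TRUE, tt >= t_app)
  TH <- matrix(NA_real_, n, 2)
  mode_switch <- NA_real_
  if (!is.na(idx_app)) {
    sub <- idx_app:n
    Xi <- threat_path_on_grid(spec, tt[sub] - t_app, P[sub, , drop = FALSE])
    ms <- attr(Xi, "mode_switch_time")
    if (!is.na(ms)) mode_switch <- ms + t_app
    if (hands_up_active) {
      rel_halt <- hands_up_time - t_app
      ih <- match(TRUE, (tt[sub] - t_app) >= rel_halt)
      if (!is.na(ih) && ih < length(sub)) {
        Xi[(ih + 1L):nrow(Xi), 1] <- Xi[ih, 1]
        Xi[(ih + 1L):nrow(Xi), 2] <- Xi[ih, 2]
      }
    }
    TH[sub, ] <- Xi
  }

  # termination: first terminal event wins
  d_threat <- sqrt((P[, 1] - TH[, 1])^2 + (P[, 2] - TH[, 2])^2)
  d_shelter <- sqrt((P[, 1] - shelter[1])^2 + (P[, 2] - shelter[2])^2)
  contact_idx <- if (flags$force_shield) NA_integer_ else
    match(TRUE, !is.na(d_threat) & d_threat <= contact_radius)
  entry_idx <- if (escaping && policy$escape_target == "shelter")
    match(TRUE, d_shelter <= shelter_radius & tt > t0) else NA_integer_

  end_idx <- n
  outcome <- "survived"
  contact_time <- NA_real_
  shelter_entry_time <- NA_real_
  if (!is.na(entry_idx) && (is.na(contact_idx) || entry_idx <= contact_idx)) {
    th_shelter <- sqrt((TH[entry_idx, 1] - shelter[1])^2 +
                         (TH[entry_idx, 2] - shelter[2])^2)
    if (!is.na(th_shelter) && th_shelter <= door_block_radius) {
      outcome <- "virtual_death"       # door blocked: counts as contact
      contact_time <- tt[entry_idx]
    } else {
      outcome <- "escape_to_shelter"
      shelter_entry_time <- tt[entry_idx]
    }
    end_idx <- entry_idx
  } else if (!is.na(contact_idx)) {
    outcome <- "virtual_death"
    contact_time <- tt[contact_idx]
    end_idx <- contact_idx
  }

  keep <- seq_len(end_idx)
  tt <- tt[keep]
  P <- P[keep, , drop = FALSE]
  TH <- TH[keep, , drop = FALSE]
  nk <- end_idx

  # orientation: facing the bush before appearance; afterwards the base
  # heading sits at acos(body_orientation) from the participant-to-threat
  # direction, so the mean orientation cosine equals the policy parameter.
  base_deg <- rep(0, nk)
  seen <- !is.na(TH[, 1])
  if (any(seen)) {
    th_deg <- atan2(TH[seen, 1] - P[seen, 1], TH[seen, 2] - P[seen, 2]) *
      180 / pi
    base_deg[seen] <- th_deg + acos(policy$body_orientation) * 180 / pi
  }
  # head scanning: one sinusoidal yaw oscillator whose mean absolute angular
  # speed equals the requested deg/s rate (rate = 4 * amplitude * frequency);
  # the amplitude steps up during the 1.5 s post-appearance burst window
  f_scan <- 2
  ph <- stats::runif(1, 0, 2 * pi)
  burst_win <- tt >= t_app & tt < t_app + 1.5
  rate <- policy$head_scan_base + policy$head_scan_burst * burst_win
  yaw <- base_deg + (rate / (4 * f_scan)) * sin(2 * pi * f_scan * tt + ph)
  head_f <- cbind(sin(yaw * pi / 180), cos(yaw * pi / 180))
  pelvis_f <- cbind(sin(base_deg * pi / 180), cos(base_deg * pi / 180))

  head_xy <- P + matrix(stats::rnorm(2 * nk, 0, policy$pos_noise_sd), nk, 2)
  pelvis_xy <- P + matrix(stats::rnorm(2 * nk, 0, policy$pos_noise_sd), nk, 2)

  recording <- data.frame(
    t = tt,
    head_x = head_xy[, 1], head_y = head_xy[, 2],
    head_fx = head_f[, 1], head_fy = head_f[, 2],
    pelvis_x = pelvis_xy[, 1], pelvis_y = pelvis_xy[, 2],
    pelvis_fx = pelvis_f[, 1], pelvis_fy = pelvis_f[, 2],
    threat_x = TH[, 1], threat_y = TH[, 2]
  )

  # fruit picks: a point process at the policy rate with a 1 s minimum
  # inter-pick gap, while the participant is at the bush
  pick_end <- min(if (is.finite(t0)) t0 else Inf, tt[nk])
  picks <- numeric(0)
  r <- min(policy$fruit_pick_rate, 0.99)
  if (r > 0 && pick_end > 0.5) {
    excess <- max(1 / r - 1, 1e-6)
    t_pick <- 0.5
    while (TRUE) {
      t_pick <- t_pick + 1 + stats::rexp(1, 1 / excess)
      if (t_pick > pick_end) break
      picks <- c(picks, t_pick)
    }
  }

  vocalized <- stats::runif(1) < policy$vocalize_probability

  event_log <- list(
    threat_appearance_time = t_app,
    fruit_pick_times = picks,
    shelter_entry_time = shelter_entry_time,
    contact_time = contact_time,
    magical_force_time = NA_real_,
    epoch_end_time = tt[nk],
    force_shield = flags$force_shield,
    hands_up_signaled = flags$hands_up_signaled,
    hands_up_time = hands_up_time,
    medusa = flags$medusa,
    outcome = outcome,
    vocalized = vocalized,
    mode_switch_time = mode_switch,
    escape_start_commanded = if (is.finite(t0)) t0 else NA_real_
  )

  if (flags$medusa) {
    mf <- medusa_force(recording, event_log)
    if (mf$triggered) {
      keep2 <- recording$t <= mf$time
      recording <- recording[keep2, , drop = FALSE]
      event_log$magical_force_time <- mf$time
      event_log$epoch_end_time <- mf$time
      event_log$outcome <- "virtual_death"
      event_log$shelter_entry_time <- NA_real_
      event_log$contact_time <- NA_real_
      event_log$fruit_pick_times <-
        picks[picks <= mf$time]
    }
  }

  list(recording = recording, event_log = event_log)
}

first_finite <- function(x) if (is.function(x)) 0 else x[1]

#' Medusa trigger: sustained gaze at the threat
#'
#' Finds the first time after threat appearance at which the cosine between
#' the head forward vector and the participant-to-threat direction stays at
#' or above `cos_threshold` for at least `min_dwell` seconds. The trigger
#' fires at the end of the dwell. The threshold comparison is inclusive.
#'
#' @param recording Trajectory recording data frame.
#' @param event_log Epoch event log (supplies the appearance time).
#' @param cos_threshold Cosine threshold; default `cos(30 deg)`.
#' @param min_dwell Minimum sustained dwell, seconds.
#' @return List with `triggered` (logical) and `time` (seconds, `NA` when
#'   never triggered).
#' @export
medusa_force <- function(recording, event_log,
                         cos_threshold = cos(30 * pi / 180),
                         min_dwell = 0.1) {
  t_app <- event_log$threat_appearance_time
  ok <- !is.na(recording$threat_x) & recording$t >= t_app
  if (!any(ok)) return(list(triggered = FALSE, time = NA_real_))
  dx <- recording$threat_x - recording$head_x
  dy <- recording$threat_y - recording$head_y
  nd <- sqrt(dx^2 + dy^2)
  cosv <- (recording$head_fx * dx + recording$head_fy * dy) / nd
  hit <- ok & !is.na(cosv) & nd > 1e-9 & cosv >= cos_threshold
  # first run of consecutive hits spanning >= min_dwell
  run_start <- NA_real_
  for (i in seq_along(hit)) {
    if (hit[i]) {
      if (is.na(run_start)) run_start <- recording$t[i]
      if (recording$t[i] - run_start >= min_dwell) {
        return(list(triggered = TRUE, time = run_start + min_dwell))
      }
    } else {
      run_start <- NA_real_
    }
  }
  list(triggered = FALSE, time = NA_real_)
}
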