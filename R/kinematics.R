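# Scenario kinematics: threat placement realizing a prescribed time-to-impact,
# and the attack/divert behavior schedule.
#
# Coordinate frame: 2-D horizontal plane. The forward axis (y) is the
# direction the participant naturally faces; the lateral axis (x) is
# perpendicular. Along the forward axis the shelter side is negative and the
# fruit side positive, so the default geometry is shelter at y = -2.5 m and
# fruit bush at y = +2.5 m. Angles are measured about the vertical axis
# relative to the forward axis, in degrees; a heading h maps to the unit
# vector (sin h, cos h).

#' Kinematic parameters of an encounter epoch
#'
#' Bundles the one-dimensional constants that the constant-velocity placement
#' equations operate on: positions of shelter and fruit bush on the escape
#' axis, the assumed participant escape speed, and the prescribed
#' time-to-impact. Speeds are signed: the participant runs toward the shelter
#' (negative direction), so the default `participant_speed` is -2 m/s.
#'
#' The estimated escape time `T_esc = (shelter - fruit) / participant_speed`
#' (2.5 s with defaults) is always derived, never stored.
#'
#' @param shelter_position Position of the shelter (safe house) on the escape
#'   axis, metres. Default -2.5.
#' @param fruit_position Position of the fruit bush (expected participant
#'   position at threat appearance), metres. Default +2.5.
#' @param participant_speed Assumed participant escape speed, m/s, signed
#'   toward the shelter. Default -2.
#' @param plan_time Prescribed time-to-impact (the time available to plan and
#'   initiate escape), seconds, > 0.
#' @return An object of class `kinematic_params`.
#' @export
kinematic_params <- function(shelter_position = -2.5, fruit_position = 2.5,
                             participant_speed = -2, plan_time = 1.5) {
  stopifnot(is.finite(shelter_position), is.finite(fruit_position),
            is.finite(participant_speed), is.finite(plan_time))
  if (abs(shelter_position - fruit_position) <= 0) {
    stop("shelter and fruit positions must differ")
  }
  if (plan_time <= 0) stop("plan_time must be > 0")
  structure(
    list(shelter_position = shelter_position,
         fruit_position = fruit_position,
         participant_speed = participant_speed,
         plan_time = plan_time),
    class = "kinematic_params"
  )
}

#' Escape time implied by kinematic parameters
#'
#' Time the participant needs to run from the fruit bush to the shelter at
#' the assumed speed: `(shelter - fruit) / participant_speed`.
#'
#' @param params A [kinematic_params()] object.
#' @return Escape time in seconds.
#' @export
escape_time <- function(params) {
  if (params$participant_speed == 0) stop("participant_speed must be nonzero")
  (params$shelter_position - params$fruit_position) / params$participant_speed
}

#' Describe a threat
#'
#' @param name Label, e.g. `"panther"`, `"rock"`.
#' @param speed Threat speed, m/s, signed toward the participant (negative
#'   along the forward axis).
#' @param is_chasing Does the threat pursue the participant once the chase
#'   starts? `FALSE` for the ballistic rock.
#' @param is_faster_than_participant Optional flag; if `NULL` it is derived
#'   by comparing `|speed|` against the 2 m/s default participant speed when
#'   the threat is used.
#' @return An object of class `threat_spec`.
#' @export
threat_spec <- function(name, speed, is_chasing = TRUE,
                        is_faster_than_participant = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.finite(speed))
  if (identical(name, "rock") && is_chasing) {
    stop("the rock is ballistic: is_chasing must be FALSE")
  }
  if (is.null(is_faster_than_participant)) {
    is_faster_than_participant <- NA
  }
  structure(
    list(name = name, speed = speed, is_chasing = isTRUE(is_chasing),
         is_faster_than_participant = as.logical(is_faster_than_participant)),
    class = "threat_spec"
  )
}

#' Default threat roster
#'
#' Seven threats spanning fast chasing animals, slow chasing animals, and the
#' ballistic rock. Per-threat speeds are not part of the published design and
#' are free configuration; these defaults order the chasing threats from
#' elephant (fastest) to spider (slowest) and straddle the assumed 2 m/s
#' participant speed.
#'
#' @return Named list of [threat_spec()] objects.
#' @export
default_threats <- function() {
  list(
    elephant = threat_spec("elephant", -6.0),
    bear     = threat_spec("bear", -5.0),
    human    = threat_spec("human", -4.0),
    dog      = threat_spec("dog", -3.5),
    rock     = threat_spec("rock", -4.0, is_chasing = FALSE),
    snake    = threat_spec("snake", -1.2),
    spider   = threat_spec("spider", -0.6)
  )
}

#' Initial placement of a threat faster than the participant
#'
#' For a chasing threat faster than the participant, time-to-impact is the
#' initiation delay that leads to simultaneous arrival of threat and
#' participant at the shelter. Solving the constant-velocity equations for
#' the initial threat position gives
#' `S_T = S_esc - V_T * ((S_esc - S_P) / V_P + T_Plan)`.
#'
#' @param params A [kinematic_params()] object (supplies `S_esc`, `S_P`,
#'   `V_P`, `T_Plan`).
#' @param threat A [threat_spec()] (supplies `V_T`).
#' @return Signed initial threat position on the escape axis, metres.
#' @export
fast_threat_initial_position <- function(params, threat) {
  v_t <- threat$speed
  v_p <- params$participant_speed
  if (v_t != 0 && abs(v_t) <= abs(v_p)) {
    stop("fast-placement-invalid: |threat speed| must exceed |participant speed|")
  }
  if (v_t != 0 && sign(v_t) != sign(v_p)) {
    stop("fast-placement-invalid: threat and participant must move toward the shelter side")
  }
  params$shelter_position -
    v_t * ((params$shelter_position - params$fruit_position) / v_p +
             params$plan_time)
}

#' Initial placement of a slow or non-chasing threat
#'
#' For threats no faster than the participant, and for the ballistic rock,
#' time-to-impact is simply the threat's travel time to the fruit-picking
#' position: `S_T = S_P - V_T * T_Plan`.
#'
#' @inheritParams fast_threat_initial_position
#' @return Signed initial threat position on the escape axis, metres.
#' @export
slow_threat_initial_position <- function(params, threat) {
  params$fruit_position - threat$speed * params$plan_time
}

#' Route placement to the fast or slow rule
#'
#' Fast rule iff the threat chases and is strictly faster than the
#' participant; the boundary `|V_T| = |V_P|` and all non-chasing threats use
#' the slow rule.
#'
#' @inheritParams fast_threat_initial_position
#' @return Signed initial threat position, metres.
#' @export
threat_initial_position <- function(params, threat) {
  fast <- threat$is_chasing &&
    abs(threat$speed) > abs(params$participant_speed)
  if (fast) fast_threat_initial_position(params, threat)
  else slow_threat_initial_position(params, threat)
}

#' Nominal approach time of a threat
#'
#' Path length from the initial threat position to the fruit-picking position
#' divided by the threat's speed magnitude. Angled approaches preserve total
#' path length, so the approach time is independent of approach angle.
#'
#' @param path_length Total path length from initial position to the fruit
#'   position, metres (sum of segment lengths for angled approaches).
#' @param speed Threat speed, m/s (sign ignored).
#' @return Approach time in seconds.
#' @export
nominal_approach_time <- function(path_length, speed) {
  if (abs(speed) == 0) stop("undefined-time: threat speed is zero")
  if (path_length < 0) stop("path length must be nonnegative")
  path_length / abs(speed)
}

#' Behavior schedule of a threat
#'
#' In attack epochs a chasing threat starts pursuing the participant after
#' 75% of its nominal approach time. In divert epochs the threat changes its
#' target heading after 20% of the approach time; the new heading depends on
#' the approach angle: a left approach (-45 deg) diverts right (+90 deg), a
#' right approach (+45 deg) diverts left (-90 deg), and a center approach
#' (0 deg) diverts left (-110 deg) or right (+110 deg) with equal
#' probability. The ballistic rock cannot change heading; its divert variant
#' instead offsets the initial rolling direction by +5 or -5 degrees (equal
#' probability) so that it misses the participant.
#'
#' Uses the current RNG state for the random choices.
#'
#' @param behavior `"attack"` or `"divert"`.
#' @param approach_angle Approach angle in degrees, one of -45, 0, +45.
#' @param approach_time Nominal approach time `T`, seconds.
#' @param is_chasing Whether the threat is a chasing threat (`FALSE` for the
#'   rock).
#' @return List with `chase_onset_time`, `divert_onset_time`,
#'   `divert_heading` (degrees) and `rock_offset_deg`; inactive entries are
#'   `NA`.
#' @export
behavior_schedule <- function(behavior, approach_angle, approach_time,
                              is_chasing = TRUE) {
  if (!behavior %in% c("attack", "divert")) {
    stop("unknown behavior label: ", behavior)
  }
  if (!approach_angle %in% c(-45, 0, 45)) {
    stop("approach_angle must be one of -45, 0, 45")
  }
  out <- list(chase_onset_time = NA_real_, divert_onset_time = NA_real_,
              divert_heading = NA_real_, rock_offset_deg = NA_real_)
  if (behavior == "attack") {
    if (is_chasing) out$chase_onset_time <- 0.75 * approach_time
    return(out)
  }
  # divert
  if (!is_chasing) {
    out$rock_offset_deg <- sample(c(-5, 5), 1L)
    return(out)
  }
  out$divert_onset_time <- 0.20 * approach_time
  out$divert_heading <- switch(as.character(approach_angle),
    "-45" = 90,
    "45"  = -90,
    "0"   = sample(c(-110, 110), 1L)
  )
  out
}

#' Default time-to-impact condition map
#'
#' @return Named numeric vector mapping `short` and `long` to seconds.
#' @export
default_tti_map <- function() c(short = 1.5, long = 5)

heading_unit <- function(deg) {
  r <- deg * pi / 180
  c(sin(r), cos(r))
}

#' Generate the full geometry and schedule of one encounter epoch
#'
#' Places the threat by the fast or slow rule so that the scenario realizes
#' the prescribed time-to-impact, chooses (or accepts) an approach angle, and
#' attaches the behavior schedule. The threat approaches the fruit-picking
#' position along a straight ray at the approach angle; angled approaches
#' have the same total path length as the straight one, so the nominal
#' approach time does not depend on the angle.
#'
#' @param threat A [threat_spec()].
#' @param behavior `"attack"` or `"divert"`.
#' @param tti_condition `"short"` or `"long"` (or any name in `tti_map`).
#' @param approach_angle Degrees in \{-45, 0, +45\}; drawn uniformly when
#'   `NULL`.
#' @param params A [kinematic_params()]; its `plan_time` is overridden by the
#'   mapped condition value.
#' @param tti_map Named map from condition labels to seconds; defaults to
#'   `c(short = 1.5, long = 5)`.
#' @param seed Optional integer seed making the scenario reproducible.
#' @return An object of class `scenario_spec`.
#' @export
generate_epoch_scenario <- function(threat, behavior,
                                    tti_condition = c("short", "long"),
                                    approach_angle = NULL,
                                    params = kinematic_params(),
                                    tti_map = default_tti_map(),
                                    seed = NULL) {
  tti_condition <- match.arg(tti_condition, names(tti_map))
  if (!is.null(seed)) set.seed(seed)
  t_plan <- unname(tti_map[[tti_condition]])
  params <- kinematic_params(params$shelter_position, params$fruit_position,
                             params$participant_speed, plan_time = t_plan)
  if (is.null(approach_angle)) approach_angle <- sample(c(-45, 0, 45), 1L)

  s_t <- threat_initial_position(params, threat)
  path_length <- abs(s_t - params$fruit_position)
  t_approach <- nominal_approach_time(path_length, threat$speed)

  fruit_2d <- c(0, params$fruit_position)
  shelter_2d <- c(0, params$shelter_position)
  init_2d <- fruit_2d + path_length * heading_unit(approach_angle)

  sched <- behavior_schedule(behavior, approach_angle, t_approach,
                             is_chasing = threat$is_chasing)

  structure(
    list(
      threat = threat,
      behavior = behavior,
      tti_condition = tti_condition,
      tti_seconds = t_plan,
      approach_angle = approach_angle,
      initial_threat_position = init_2d,
      fruit_position_2d = fruit_2d,
      shelter_position_2d = shelter_2d,
      nominal_approach_time = t_approach,
      chase_onset_time = sched$chase_onset_time,
      divert_onset_time = sched$divert_onset_time,
      divert_heading = sched$divert_heading,
      rock_offset_deg = sched$rock_offset_deg,
      appearance_delay_law = c(1, 11),
      min_epoch_duration = 12.5,
      participant_speed = params$participant_speed,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "scenario_spec"
  )
}

#' Recover the time-to-impact realized by a scenario
#'
#' Closed-form inversion of the placement geometry. For a chasing threat
#' faster than the participant, time-to-impact is the initiation delay that
#' makes participant and threat arrive at the shelter simultaneously: the
#' threat's travel time to the shelter (via the fruit position) minus the
#' participant's escape time. For slow or non-chasing threats it is the
#' threat's travel time from its initial placement to the fruit position.
#'
#' @param spec A `scenario_spec` from [generate_epoch_scenario()].
#' @param params A [kinematic_params()] supplying the assumed participant
#'   speed (its `plan_time` is ignored).
#' @return Time-to-impact in seconds.
#' @export
verify_time_to_impact <- function(spec, params = kinematic_params()) {
  d_fruit <- sqrt(sum((spec$initial_threat_position -
                         spec$fruit_position_2d)^2))
  v_t <- abs(spec$threat$speed)
  fast <- spec$threat$is_chasing && v_t > abs(params$participant_speed)
  if (!fast) return(d_fruit / v_t)
  d_escape <- sqrt(sum((spec$fruit_position_2d - spec$shelter_position_2d)^2))
  (d_fruit + d_escape) / v_t - d_escape / abs(params$participant_speed)
}
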