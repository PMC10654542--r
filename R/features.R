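# Epoch-level behavioral summary statistics extracted from a trajectory
# recording and its event log: outcomes, escape initiation, distances,
# speeds, orientation cosines, visual scanning, and foraging rates. Time
# averages over irregular samples use the trapezium rule throughout.

#' Time average of an irregularly sampled signal (trapezium rule)
#'
#' Trapezoidal integral of the piecewise-linear interpolant over the window,
#' divided by the window length. Values at the window edges are linearly
#' interpolated; if the samples do not span the whole window, the window is
#' clipped to the sampled range and the clipped length is used.
#'
#' @param times Strictly increasing sample times, seconds.
#' @param values Sample values.
#' @param window Numeric length-2 `c(start, end)`.
#' @return Mean value over the window, or `NA` if fewer than two samples
#'   intersect it.
#' @export
time_average_trapezium <- function(times, values, window) {
  stopifnot(length(times) == length(values), length(window) == 2L,
            window[2] > window[1])
  ok <- !is.na(values) & !is.na(times)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 2L || any(diff(times) <= 0)) {
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
    return(NA_real_)
  }
  a <- max(window[1], times[1])
  b <- min(window[2], times[length(times)])
  if (b <= a) return(NA_real_)
  inside <- times > a & times < b
  if (sum(inside) + 2L < 2L) return(NA_real_)
  va <- stats::approx(times, values, xout = a)$y
  vb <- stats::approx(times, values, xout = b)$y
  tt <- c(a, times[inside], b)
  vv <- c(va, values[inside], vb)
  integ <- sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
  integ / (b - a)
}

#' Classify the terminal outcome of an epoch
#'
#' Threat contact or the magical force give `virtual_death`; shelter entry
#' gives `escape_to_shelter`; otherwise the participant `survived` until
#' timeout.
#'
#' @param event_log Epoch event log.
#' @return One of `"virtual_death"`, `"escape_to_shelter"`, `"survived"`.
#' @export
classify_outcome <- function(event_log) {
  death <- !is.na(event_log$contact_time) ||
    !is.na(event_log$magical_force_time)
  entry <- !is.na(event_log$shelter_entry_time)
  if (death && entry) stop("malformed-log: multiple terminal events")
  if (death) return("virtual_death")
  if (entry) return("escape_to_shelter")
  "survived"
}

#' Detect escape initiation
#'
#' First time after the anchor (threat appearance, or a reference time for
#' no-threat epochs) at which the head tracker's horizontal distance from
#' the fruit-picking position exceeds `radius` while radial velocity stays
#' outward for at least `min_outward` seconds.
#'
#' @param recording Trajectory recording.
#' @param anchor_time Time from which to search, seconds.
#' @param fruit_position Fruit-picking position `c(x, y)`.
#' @param radius Departure radius, metres.
#' @param min_outward Required sustained outward motion, seconds.
#' @return List with `initiated` (logical) and `time` (seconds or `NA`).
#' @export
detect_escape_initiation <- function(recording, anchor_time, fruit_position,
                                     radius = 0.5, min_outward = 0.3) {
  t <- recording$t
  d <- sqrt((recording$head_x - fruit_position[1])^2 +
              (recording$head_y - fruit_position[2])^2)
  n <- length(t)
  if (n < 2L) return(list(initiated = FALSE, time = NA_real_))
  outward <- c(diff(d) / diff(t) > 0, FALSE)
  cand <- d > radius & outward & t >= anchor_time
  i <- 1L
  while (i <= n) {
    if (cand[i]) {
      j <- i
      while (j < n && cand[j + 1L]) j <- j + 1L
      if (t[j] - t[i] >= min_outward) {
        return(list(initiated = TRUE, time = t[i]))
      }
      i <- j + 1L
    }
    i <- i + 1L
  }
  list(initiated = FALSE, time = NA_real_)
}

#' Interrupted escape
#'
#' An initiated escape that did not end in shelter entry. `NA` when no
#' escape was initiated.
#'
#' @param initiated Logical: escape initiated.
#' @param outcome Epoch outcome label.
#' @return Logical flag or `NA`.
#' @export
interrupted_escape <- function(initiated, outcome) {
  if (!isTRUE(initiated)) return(NA)
  outcome != "escape_to_shelter"
}

#' Minimum distances to threat and shelter
#'
#' Minima over samples of the Euclidean head-tracker distance to the threat
#' and to the shelter position.
#'
#' @param recording Trajectory recording.
#' @param shelter_position Shelter position `c(x, y)`.
#' @return List with `min_dist_threat` (`NA` when the threat never appears)
#'   and `min_dist_shelter`.
#' @export
min_distances <- function(recording, shelter_position) {
  d_sh <- sqrt((recording$head_x - shelter_position[1])^2 +
                 (recording$head_y - shelter_position[2])^2)
  dt_ok <- !is.na(recording$threat_x)
  d_th <- if (any(dt_ok)) {
    min(sqrt((recording$head_x[dt_ok] - recording$threat_x[dt_ok])^2 +
               (recording$head_y[dt_ok] - recording$threat_y[dt_ok])^2))
  } else NA_real_
  list(min_dist_threat = d_th, min_dist_shelter = min(d_sh))
}

#' Peak and mean speed during escape
#'
#' Speeds from central finite differences of the head position, smoothed by
#' a moving average over `smooth_window` seconds; the peak is the maximum
#' smoothed speed in the escape window and the mean is the trapezium-rule
#' time average over it.
#'
#' @param recording Trajectory recording.
#' @param initiation_time Escape initiation time, seconds (`NA` gives
#'   missing results).
#' @param end_time End of the escape window: shelter entry or epoch end,
#'   whichever is earlier.
#' @param smooth_window Moving-average window, seconds.
#' @return List with `peak` and `mean` speed, m/s (both `NA` when escape was
#'   not initiated or the window holds fewer than two samples).
#' @export
escape_speed_stats <- function(recording, initiation_time, end_time,
                               smooth_window = 0.1) {
  if (is.na(initiation_time) || is.na(end_time) ||
      end_time <= initiation_time) {
    return(list(peak = NA_real_, mean = NA_real_))
  }
  t <- recording$t
  n <- length(t)
  if (n < 3L) return(list(peak = NA_real_, mean = NA_real_))
  v <- rep(NA_real_, n)
  idx <- 2:(n - 1L)
  v[idx] <- sqrt((recording$head_x[idx + 1L] - recording$head_x[idx - 1L])^2 +
                   (recording$head_y[idx + 1L] - recording$head_y[idx - 1L])^2) /
    (t[idx + 1L] - t[idx - 1L])
  v[1] <- v[2]; v[n] <- v[n - 1L]
  k <- max(1L, round(smooth_window / stats::median(diff(t))))
  if (k > 1L) {
    vs <- stats::filter(v, rep(1 / k, k), sides = 2)
    v <- ifelse(is.na(vs), v, as.numeric(vs))
  }
  win <- t >= initiation_time & t <= end_time
  if (sum(win) < 2L) return(list(peak = NA_real_, mean = NA_real_))
  list(peak = max(v[win], na.rm = TRUE),
       mean = time_average_trapezium(t, v, c(initiation_time, end_time)))
}

tracker_forward <- function(recording, tracker) {
  switch(tracker,
    pelvis = cbind(recording$pelvis_fx, recording$pelvis_fy),
    head   = cbind(recording$head_fx, recording$head_fy),
    gaze   = if (all(c("gaze_fx", "gaze_fy") %in% names(recording))) {
      cbind(recording$gaze_fx, recording$gaze_fy)
    } else cbind(recording$head_fx, recording$head_fy),
    stop("unknown tracker: ", tracker)
  )
}

#' Mean orientation cosine toward the threat
#'
#' Per-sample cosine of the angle between the tracker's horizontal forward
#' vector and the unit vector from the participant to the threat (1 toward,
#' -1 away), time-averaged over the window by the trapezium rule. Samples
#' with a degenerate forward vector or absent threat are skipped.
#'
#' @param recording Trajectory recording.
#' @param tracker `"pelvis"`, `"head"`, or `"gaze"` (gaze falls back to the
#'   head channel when no gaze columns are present).
#' @param window `c(start, end)` in seconds.
#' @return Mean cosine in `[-1, 1]`, or `NA`.
#' @export
orientation_cosine <- function(recording, tracker = c("pelvis", "head", "gaze"),
                               window) {
  tracker <- match.arg(tracker)
  fw <- tracker_forward(recording, tracker)
  dx <- recording$threat_x - recording$head_x
  dy <- recording$threat_y - recording$head_y
  nd <- sqrt(dx^2 + dy^2)
  nf <- sqrt(fw[, 1]^2 + fw[, 2]^2)
  ok <- !is.na(nd) & nd > 1e-9 & nf > 1e-9
  if (!any(ok)) return(NA_real_)
  cosv <- (fw[ok, 1] * dx[ok] + fw[ok, 2] * dy[ok]) / (nd[ok] * nf[ok])
  out <- time_average_trapezium(recording$t[ok], cosv, window)
  if (!is.na(out)) out <- max(-1, min(1, out))
  out
}

#' Visual scanning rate
#'
#' Cumulative angle (degrees) swept by the tracker's forward vector between
#' consecutive samples inside the window, divided by the window duration
#' (clipped to the sampled range).
#'
#' @inheritParams orientation_cosine
#' @return Scanning rate in deg/s, or `NA` with fewer than two samples.
#' @export
visual_scanning_rate <- function(recording, tracker = c("head", "pelvis", "gaze"),
                                 window) {
  tracker <- match.arg(tracker)
  fw <- tracker_forward(recording, tracker)
  t <- recording$t
  sel <- which(t >= window[1] & t <= window[2])
  if (length(sel) < 2L) return(NA_real_)
  f <- fw[sel, , drop = FALSE]
  dots <- f[-nrow(f), 1] * f[-1, 1] + f[-nrow(f), 2] * f[-1, 2]
  nrm <- sqrt(f[, 1]^2 + f[, 2]^2)
  dots <- dots / (nrm[-length(nrm)] * nrm[-1])
  ang <- acos(pmin(1, pmax(-1, dots))) * 180 / pi
  dur <- min(window[2], t[sel[length(sel)]]) - max(window[1], t[sel[1]])
  if (dur <= 0) return(NA_real_)
  sum(ang) / dur
}

#' Fruit picking rate over a window
#'
#' @param pick_times Vector of pick timestamps, seconds.
#' @param window `c(start, end)`; picks in the half-open interval
#'   `[start, end)` are counted.
#' @return Picks per second.
#' @export
fruit_picking_rate <- function(pick_times, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  sum(pick_times >= window[1] & pick_times < window[2]) /
    (window[2] - window[1])
}

#' Feature-extraction configuration
#'
#' @param initiation_radius Escape-initiation departure radius, metres.
#' @param min_outward Sustained outward motion required for initiation,
#'   seconds.
#' @param speed_smooth Speed moving-average window, seconds.
#' @param appear_window Length of the post-appearance window, seconds
#'   (1.5 s, matching the shorter time-to-impact).
#' @param min_epoch_duration Minimum epoch duration used for the foraging
#'   window, seconds.
#' @param scan_tracker Tracker for visual scanning (`"head"` or `"gaze"`).
#' @return List of feature parameters.
#' @export
feature_config <- function(initiation_radius = 0.5, min_outward = 0.3,
                           speed_smooth = 0.1, appear_window = 1.5,
                           min_epoch_duration = 12.5,
                           scan_tracker = "head") {
  list(initiation_radius = initiation_radius, min_outward = min_outward,
       speed_smooth = speed_smooth, appear_window = appear_window,
       min_epoch_duration = min_epoch_duration, scan_tracker = scan_tracker)
}

#' Summarize one epoch
#'
#' Computes the full set of epoch-level summary statistics. Windowed
#' measures use two windows: 0-1.5 s after threat appearance, and the escape
#' window from initiation until shelter entry or epoch end, whichever is
#' earlier. For no-threat epochs the appearance anchor is replaced by a
#' reference time drawn uniformly from the appearance-delay law under the
#' scenario seed. Escape-dependent measures are missing when no escape was
#' initiated.
#'
#' @param recording Trajectory recording.
#' @param event_log Epoch event log.
#' @param scenario The `scenario_spec` (supplies geometry and seed).
#' @param config See [feature_config()].
#' @return One-row data frame (class `epoch_summary`).
#' @export
summarize_epoch <- function(recording, event_log, scenario,
                            config = feature_config()) {
  outcome <- classify_outcome(event_log)
  t_end <- event_log$epoch_end_time
  fruit <- scenario$fruit_position_2d
  shelter <- scenario$shelter_position_2d

  t_app <- event_log$threat_appearance_time
  ref_used <- NA_real_
  if (is.na(t_app)) {
    sd_seed <- if (!is.na(scenario$seed)) derive_seed(scenario$seed, 777L)
               else 777L
    set.seed(sd_seed)
    ref_used <- stats::runif(1, scenario$appearance_delay_law[1],
                             scenario$appearance_delay_law[2])
    t_app <- ref_used
  }

  init <- detect_escape_initiation(recording, t_app, fruit,
                                   radius = config$initiation_radius,
                                   min_outward = config$min_outward)
  esc_end <- min(c(event_log$shelter_entry_time, t_end), na.rm = TRUE)
  interrupted <- interrupted_escape(init$initiated, outcome)
  dists <- min_distances(recording, shelter)

  win_app <- c(t_app, t_app + config$appear_window)
  sp <- escape_speed_stats(recording, if (init$initiated) init$time else
                             NA_real_, esc_end,
                           smooth_window = config$speed_smooth)
  win_esc <- if (init$initiated) c(init$time, esc_end) else NULL
  esc_val <- function(f) if (is.null(win_esc) ||
                             win_esc[2] <= win_esc[1]) NA_real_ else f(win_esc)

  data.frame(
    outcome = outcome,
    initiated_escape = init$initiated,
    escape_initiation_time = if (init$initiated) init$time - t_app
                             else NA_real_,
    interrupted_escape = interrupted,
    min_dist_shelter = dists$min_dist_shelter,
    min_dist_threat = dists$min_dist_threat,
    peak_speed = sp$peak,
    mean_speed = sp$mean,
    body_orient_appear = orientation_cosine(recording, "pelvis", win_app),
    body_orient_escape = esc_val(function(w)
      orientation_cosine(recording, "pelvis", w)),
    head_orient_appear = orientation_cosine(recording, "head", win_app),
    head_orient_escape = esc_val(function(w)
      orientation_cosine(recording, "head", w)),
    fruit_rate_appear = fruit_picking_rate(event_log$fruit_pick_times,
                                           win_app),
    fruit_rate_escape = esc_val(function(w)
      fruit_picking_rate(event_log$fruit_pick_times, w)),
    scan_appear = visual_scanning_rate(recording, config$scan_tracker,
                                       win_app),
    scan_escape = esc_val(function(w)
      visual_scanning_rate(recording, config$scan_tracker, w)),
    fruit_rate_to_min_duration =
      if (config$min_epoch_duration > t_app) {
        fruit_picking_rate(event_log$fruit_pick_times,
                           c(t_app, config$min_epoch_duration))
      } else NA_real_,
    magical_force_death = !is.na(event_log$magical_force_time),
    reference_time_used = ref_used,
    stringsAsFactors = FALSE
  )
}

#' Summarize a whole cohort
#'
#' Applies [summarize_epoch()] to every epoch of an `escape_cohort` and
#' binds the results with subject and design-cell labels, ready for the
#' inferential stage.
#'
#' @param cohort An `escape_cohort` from [generate_cohort()].
#' @param config See [feature_config()].
#' @return Data frame, one row per epoch.
#' @export
summarize_cohort <- function(cohort, config = feature_config()) {
  rows <- lapply(cohort$epochs, function(ep) {
    s <- summarize_epoch(ep$recording, ep$event_log, ep$scenario, config)
    cbind(data.frame(subject = ep$subject, threat = ep$threat, tti = ep$tti,
                     behavior = ep$behavior, stringsAsFactors = FALSE), s)
  })
  do.call(rbind, rows)
}
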