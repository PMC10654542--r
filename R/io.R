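# Formats, configuration and the pipeline driver. CSV files are UTF-8,
# comma-separated with "." decimals and missing values as empty cells; JSON
# numbers are plain decimals with missing values as null.

scenario_to_list <- function(spec) {
  s <- unclass(spec)
  s$threat <- unclass(s$threat)
  s
}

list_to_scenario <- function(x) {
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  ifp <- x$threat$is_faster_than_participant
  if (is.null(ifp) || length(ifp) == 0L) ifp <- NA
  thr <- threat_spec(x$threat$name, as.numeric(x$threat$speed),
                     is_chasing = isTRUE(x$threat$is_chasing),
                     is_faster_than_participant = ifp)
  structure(
    list(threat = thr, behavior = x$behavior,
         tti_condition = x$tti_condition, tti_seconds = num(x$tti_seconds),
         approach_angle = num(x$approach_angle),
         initial_threat_position = as.numeric(x$initial_threat_position),
         fruit_position_2d = as.numeric(x$fruit_position_2d),
         shelter_position_2d = as.numeric(x$shelter_position_2d),
         nominal_approach_time = num(x$nominal_approach_time),
         chase_onset_time = num(x$chase_onset_time),
         divert_onset_time = num(x$divert_onset_time),
         divert_heading = num(x$divert_heading),
         rock_offset_deg = num(x$rock_offset_deg),
         appearance_delay_law = as.numeric(x$appearance_delay_law),
         min_epoch_duration = num(x$min_epoch_duration),
         participant_speed = num(x$participant_speed),
         seed = if (is.null(x$seed) || is.na(x$seed)) NA_integer_
                else as.integer(x$seed)),
    class = "scenario_spec")
}

#' Write scenarios to JSON
#'
#' A single `scenario_spec` is written as one JSON object; a list of them as
#' a JSON array.
#'
#' @param spec A `scenario_spec` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path) {
  payload <- if (inherits(spec, "scenario_spec")) scenario_to_list(spec)
             else lapply(spec, scenario_to_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read scenarios from JSON
#'
#' @param path JSON file written by [write_scenario()].
#' @return A `scenario_spec` or list of them.
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!is.null(x$threat)) list_to_scenario(x)
  else lapply(x, list_to_scenario)
}

#' Write a trajectory recording as tidy CSV
#'
#' Columns `t, head_x, head_y, head_fx, head_fy, pelvis_x, pelvis_y,
#' pelvis_fx, pelvis_fy, threat_x, threat_y`; samples before threat
#' appearance have empty threat fields.
#'
#' @param recording Recording data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  utils::write.csv(recording, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory recording CSV
#'
#' @param path CSV file written by [write_recording()].
#' @return Recording data frame (empty threat fields become `NA`).
#' @export
read_recording <- function(path) {
  out <- utils::read.csv(path, colClasses = "numeric")
  required <- c("t", "head_x", "head_y", "head_fx", "head_fy")
  miss <- setdiff(required, names(out))
  if (length(miss)) {
    stop("parse error in ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  }
  out
}

#' Write an event log as JSON
#'
#' @param event_log Event-log list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(event_log, path) {
  jsonlite::write_json(event_log, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an event log from JSON
#'
#' @param path JSON file written by [write_event_log()].
#' @return Event-log list (`null` becomes `NA`).
#' @export
read_event_log <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scalars <- c("threat_appearance_time", "shelter_entry_time",
               "contact_time", "magical_force_time", "epoch_end_time",
               "hands_up_time", "mode_switch_time",
               "escape_start_commanded")
  for (nm in scalars) {
    x[[nm]] <- if (is.null(x[[nm]])) NA_real_ else as.numeric(x[[nm]])
  }
  x$fruit_pick_times <- if (is.null(x$fruit_pick_times)) numeric(0)
                        else as.numeric(x$fruit_pick_times)
  x
}

#' Write epoch summaries as CSV
#'
#' One row per epoch, stable column names, missing values as empty cells.
#'
#' @param summaries Summary data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read epoch summaries from CSV
#'
#' @param path CSV file written by [write_summaries()].
#' @return Summary data frame.
#' @export
read_summaries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("initiated_escape", "interrupted_escape",
                         "magical_force_death"), names(d))) {
    d[[nm]] <- as.logical(d[[nm]])
  }
  d
}

#' Pipeline configuration
#'
#' Bundles the geometry constants, condition maps, feature thresholds and
#' simulation sizes driving [run_pipeline()]. Defaults follow the standard
#' arena (fruit bush at +2.5 m, shelter at -2.5 m, assumed participant
#' escape speed 2 m/s) and desk-scale cohort sizes.
#'
#' @param fruit_position,shelter_position Positions on the escape axis, m.
#' @param participant_speed Assumed participant speed magnitude, m/s.
#' @param tti_map Named condition map, seconds.
#' @param n_subjects Cohort size for the simulation stage.
#' @param dt Sampling interval, seconds.
#' @param features [feature_config()] list.
#' @param n_clips Synthetic audio set size for the detection stage.
#' @param cv_reps Monte Carlo cross-validation repetitions.
#' @param max_miss Grid-search miss constraint.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fruit_position = 2.5, shelter_position = -2.5,
                            participant_speed = 2,
                            tti_map = default_tti_map(),
                            n_subjects = 8L, dt = 1 / 60,
                            features = feature_config(),
                            n_clips = 120L, cv_reps = 50L,
                            max_miss = 0.05) {
  stopifnot(participant_speed > 0, n_subjects >= 2, dt > 0,
            n_clips > 0, cv_reps > 0)
  structure(
    list(fruit_position = fruit_position,
         shelter_position = shelter_position,
         participant_speed = participant_speed, tti_map = tti_map,
         n_subjects = as.integer(n_subjects), dt = dt, features = features,
         n_clips = as.integer(n_clips), cv_reps = as.integer(cv_reps),
         max_miss = max_miss),
    class = "pipeline_config")
}

# FNV-1a hash of the JSON serialization; recorded in every pipeline output
# so reruns can be matched to their configuration.
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' generate -> simulate -> extract -> detect -> analyze, fully reproducible
#' under `seed` (one global seed fans out to per-stage child seeds). Writes
#' epoch summaries, the contrast table, the detector calibration and a JSON
#' report (including the configuration hash) into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return List with the report (invisibly also written to
#'   `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = tempfile("escapesim_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- generate_cohort(config$n_subjects,
                            seed = derive_seed(seed, 1L), dt = config$dt)
  summaries <- summarize_cohort(cohort, config$features)
  write_summaries(summaries, file.path(out_dir, "summaries.csv"))

  clips <- synth_audio(config$n_clips, seed = derive_seed(seed, 2L))
  th <- grid_search_calibrate(clips, max_miss = config$max_miss)
  cv <- monte_carlo_cv(clips, reps = config$cv_reps,
                       max_miss = config$max_miss,
                       seed = derive_seed(seed, 3L))

  contrasts <- analyze_hypotheses(summaries)
  utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE, na = "")

  report <- list(
    config_hash = config_hash(config),
    seed = seed,
    stages = list(
      simulate = list(n_subjects = config$n_subjects,
                      n_epochs = length(cohort$epochs), dt = config$dt),
      detect = list(
        n_clips = config$n_clips,
        volume_threshold = th$volume_threshold,
        time_threshold = th$time_threshold,
        in_sample_miss = attr(th, "miss_rate"),
        in_sample_false_alarm = attr(th, "false_alarm_rate"),
        cv_mean_miss = cv$mean_miss_rate,
        cv_mean_false_alarm = cv$mean_false_alarm_rate,
        cv_reps = config$cv_reps),
      analyze = list(n_hypotheses = nrow(contrasts),
                     n_holm_significant = sum(contrasts$p_holm < 0.05,
                                              na.rm = TRUE))
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list(out_dir = out_dir, report = report,
                 summaries = summaries, contrasts = contrasts))
}

#' Read a hypothesis-contrast specification from JSON
#'
#' The editable counterpart of [default_hypotheses()]: a JSON array of
#' objects with fields `hypothesis`, `response`, `family`, `filter_a`,
#' `filter_b` and optional `description`.
#'
#' @param path JSON file.
#' @return Hypothesis data frame usable by [analyze_hypotheses()].
#' @export
read_hypotheses <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("hypothesis", "response", "family", "filter_a", "filter_b")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("parse error in ", path, ": missing fields ",
         paste(miss, collapse = ", "))
  }
  if (!"description" %in% names(d)) d$description <- ""
  as.data.frame(d, stringsAsFactors = FALSE)
}
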