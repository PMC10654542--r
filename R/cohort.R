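# Synthetic cohort generation: balanced factorial epochs per subject with
# subject-level random intercepts realized as policy-parameter offsets, plus
# questionnaire scores linked to behavior. Built for parameter-recovery
# testing of the inferential stage.

#' Deterministic child seed derivation
#'
#' Fans one global seed out to per-stage / per-epoch child seeds by a
#' linear-congruential scheme; results stay below 2^31 - 1.
#'
#' @param seed Parent integer seed.
#' @param k Nonnegative counter.
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, k) {
  h <- ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k)) %%
    2147483629
  as.integer(h)
}

#' Full factorial epoch design
#'
#' The 7 x 2 x 2 design (threat x time-to-impact x threat behavior) as a
#' data frame, one row per cell per repetition.
#'
#' @param threats Named list of [threat_spec()]s; default [default_threats()].
#' @param tti_levels Time-to-impact condition labels.
#' @param behaviors Threat behavior labels.
#' @param epochs_per_cell Repetitions of each cell per subject.
#' @return Data frame with columns `threat`, `tti`, `behavior`.
#' @export
default_design <- function(threats = default_threats(),
                           tti_levels = c("short", "long"),
                           behaviors = c("attack", "divert"),
                           epochs_per_cell = 1L) {
  g <- expand.grid(threat = names(threats), tti = tti_levels,
                   behavior = behaviors, rep = seq_len(epochs_per_cell),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rep <- NULL
  g
}

#' Condition effects injected into a synthetic cohort
#'
#' Per-condition means, between-subject SDs and residual noise for the
#' policy parameters, plus the coefficients linking questionnaire scores and
#' sex to behavior. Defaults echo the magnitudes reported for the first
#' experiment: escape initiated around 1.3 s after appearance under short
#' time-to-impact versus 2.9 s under long; mean escape speed near 1.9 m/s
#' for fast threats and 1.4 m/s for slow ones; body orientation during
#' escape more toward the threat for slow (+0.2) than fast (-0.3) threats;
#' visual scanning bursts lower for the human threat.
#'
#' @param ... Named overrides of any default component.
#' @return List of effect parameters (class `effect_spec`).
#' @export
default_effect_spec <- function(...) {
  spec <- list(
    initiation_delay_mean = c(short = 1.3, long = 2.9),
    rock_long_extra_delay = 1.9,      # the ballistic rock is watched longest
    initiation_delay_subject_sd = 0.5,
    initiation_delay_noise_sd = 0.35,
    escape_prob = c(attack_short = 0.97, attack_long = 0.95,
                    divert_short = 0.75, divert_long = 0.5),
    escape_speed_mean = c(fast = 1.9, slow = 1.4),
    escape_speed_long_shift = -0.25,
    escape_speed_subject_sd = 0.15,
    escape_speed_noise_sd = 0.1,
    orientation_mean = c(fast = -0.3, slow = 0.2),
    orientation_subject_sd = 0.15,
    orientation_noise_sd = 0.1,
    scan_base = 25,
    scan_burst_mean = c(human = 57, other = 70),
    scan_subject_sd = 8,
    scan_noise_sd = 6,
    fruit_pick_rate = 0.8,
    vocalize_probability = 0.2,
    # subject-level links: delay offset = qcoef . (scores, sex female)
    questionnaire_names = c("fearfulness", "spider_fear", "snake_fear",
                            "sensation_seeking", "trait_anxiety"),
    delay_q_coef = c(fearfulness = -0.3, spider_fear = -0.25,
                     sex_female = -0.3),
    orientation_q_coef = c(sensation_seeking = 0.08, fearfulness = -0.06,
                           sex_female = -0.06)
  )
  utils::modifyList(spec, list(...))
}

subject_policy_offsets <- function(eff) {
  q <- stats::rnorm(length(eff$questionnaire_names))
  names(q) <- eff$questionnaire_names
  sex <- if (stats::runif(1) < 0.5) "F" else "M"
  lin <- function(coefs) {
    s <- 0
    for (nm in names(coefs)) {
      s <- s + coefs[[nm]] * if (nm == "sex_female") as.numeric(sex == "F")
                             else q[[nm]]
    }
    s
  }
  list(
    scores = q, sex = sex,
    delay_offset = lin(eff$delay_q_coef) +
      stats::rnorm(1, 0, eff$initiation_delay_subject_sd),
    speed_offset = stats::rnorm(1, 0, eff$escape_speed_subject_sd),
    orient_offset = lin(eff$orientation_q_coef) +
      stats::rnorm(1, 0, eff$orientation_subject_sd),
    scan_offset = stats::rnorm(1, 0, eff$scan_subject_sd)
  )
}

#' Generate a synthetic cohort of encounter epochs
#'
#' Simulates a balanced factorial dataset: for each subject and design cell,
#' a scenario is generated, a condition-dependent policy is drawn around the
#' effect-spec means with subject-level offsets (random intercepts), and the
#' epoch is simulated. Fully reproducible under `seed`.
#'
#' @param n_subjects Number of subjects, > 0.
#' @param design Data frame with columns `threat`, `tti`, `behavior` (one
#'   row per epoch per subject); see [default_design()].
#' @param effect_spec See [default_effect_spec()].
#' @param seed Integer seed.
#' @param threats Named list of [threat_spec()]s referenced by the design.
#' @param dt Sampling interval for the simulated recordings, seconds.
#' @param timestamp_jitter Fractional sample-interval jitter (default 10%,
#'   exercising irregular-sampling code paths downstream).
#' @return Object of class `escape_cohort`: list with `subjects` (data frame
#'   of sex and questionnaire scores) and `epochs` (list of per-epoch
#'   records: subject, cell labels, `scenario`, `recording`, `event_log`).
#' @export
generate_cohort <- function(n_subjects, design = default_design(),
                            effect_spec = default_effect_spec(),
                            seed = 1L, threats = default_threats(),
                            dt = 1 / 90, timestamp_jitter = 0.1) {
  if (n_subjects <= 0) stop("n_subjects must be positive")
  stopifnot(all(c("threat", "tti", "behavior") %in% names(design)))
  eff <- effect_spec
  subjects <- vector("list", n_subjects)
  epochs <- vector("list", n_subjects * nrow(design))
  ep_i <- 0L
  for (s in seq_len(n_subjects)) {
    set.seed(derive_seed(seed, 1000L + s))
    off <- subject_policy_offsets(eff)
    subjects[[s]] <- data.frame(subject = sprintf("S%03d", s), sex = off$sex,
                                t(off$scores))
    for (r in seq_len(nrow(design))) {
      ep_i <- ep_i + 1L
      cell <- design[r, ]
      threat <- threats[[cell$threat]]
      if (is.null(threat)) stop("unknown threat in design: ", cell$threat)
      ep_seed <- derive_seed(seed, 100000L + s * 1000L + r)
      set.seed(ep_seed)
      scenario <- generate_epoch_scenario(threat, cell$behavior, cell$tti,
                                          seed = ep_seed)
      fastcls <- if (abs(threat$speed) > 2) "fast" else "slow"

      p_esc <- eff$escape_prob[[paste(cell$behavior, cell$tti, sep = "_")]]
      will_escape <- stats::runif(1) < p_esc
      delay_mu <- eff$initiation_delay_mean[[cell$tti]] +
        if (threat$name == "rock" && cell$tti == "long")
          eff$rock_long_extra_delay else 0
      delay <- max(0.2, delay_mu + off$delay_offset +
                     stats::rnorm(1, 0, eff$initiation_delay_noise_sd))
      speed <- max(0.5, eff$escape_speed_mean[[fastcls]] +
                     (cell$tti == "long") * eff$escape_speed_long_shift +
                     off$speed_offset +
                     stats::rnorm(1, 0, eff$escape_speed_noise_sd))
      orient <- max(-1, min(1, eff$orientation_mean[[fastcls]] +
                              off$orient_offset +
                              stats::rnorm(1, 0, eff$orientation_noise_sd)))
      burst_mu <- if (threat$name == "human") eff$scan_burst_mean[["human"]]
                  else eff$scan_burst_mean[["other"]]
      burst <- max(0, burst_mu + off$scan_offset +
                     stats::rnorm(1, 0, eff$scan_noise_sd))

      policy <- agent_policy(
        initiation_delay = if (will_escape) delay else Inf,
        escape_speed = speed,
        escape_target = if (will_escape) "shelter" else "none",
        body_orientation = orient,
        head_scan_base = eff$scan_base,
        head_scan_burst = burst,
        fruit_pick_rate = eff$fruit_pick_rate,
        vocalize_probability = eff$vocalize_probability
      )
      sim <- simulate_epoch(scenario, policy, dt = dt,
                            seed = derive_seed(ep_seed, 7L),
                            timestamp_jitter = timestamp_jitter)
      epochs[[ep_i]] <- list(
        subject = sprintf("S%03d", s),
        threat = cell$threat, tti = cell$tti, behavior = cell$behavior,
        scenario = scenario, recording = sim$recording,
        event_log = sim$event_log
      )
    }
  }
  structure(list(subjects = do.call(rbind, subjects), epochs = epochs),
            class = "escape_cohort")
}
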