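# escapesim

Simulation and analysis of human escape decisions in immersive
virtual-reality threat encounters.

## The scientific problem

In naturalistic escape experiments a participant forages at a fruit bush
while a threat (animal or ballistic object) can emerge from cover and
approach; a shelter sits 5 m behind the foraging position. The key
experimental variable is **time-to-impact** `T_Plan`: the maximum delay
after threat appearance such that an escape at the assumed participant
speed *just barely* avoids contact — a quantitative formalization of
"defensive distance" / "predatory imminence". Encounter geometry is built
by inverting the constant-velocity equations of motion on the escape axis
(shelter `S_esc = -2.5` m, bush `S_P = +2.5` m, participant speed
`V_P = -2` m/s):

* threat faster than the participant (chasing):
  `S_T = S_esc - V_T ((S_esc - S_P)/V_P + T_Plan)`
  (simultaneous arrival at the shelter if escape starts at exactly
  `T_Plan`);
* threat no faster, or ballistic:
  `S_T = S_P - V_T T_Plan`
  (arrival at the bush after exactly `T_Plan`).

`escapesim` implements the complete analysis pipeline for this paradigm:

1. **kinematics** — scenario generation realizing a prescribed
   time-to-impact, plus the attack/divert behavior schedule (chase after
   75% of the approach, divert after 20%, rock ±5°);
2. **simulate** — an epoch simulator (90 Hz pose streams, event logs,
   three terminal outcomes) and a factorial cohort generator with
   subject-level random intercepts, for parameter-recovery testing;
3. **features** — the epoch-level summary statistics: outcomes, escape
   initiation, minimum distances, escape speeds, body/head orientation
   cosines, visual scanning, foraging rates (trapezium-rule time averages
   over irregular samples);
4. **vocalization** — amplitude/duration threshold detection of voiced
   events, constrained grid-search calibration (miss rate ≤ 5%, then
   fewest false alarms), Monte Carlo cross-validation, WAV I/O;
5. **stats** — `DV ~ threat * tti * behavior + (1 | subject)` mixed
   models (lme4), estimated marginal means, Wald contrasts,
   Holm–Bonferroni correction, questionnaire predictor screening;
6. **io/cli** — JSON/CSV round-trip formats, a seeded end-to-end
   pipeline driver, and a command-line surface
   (`inst/cli/escapesim.R`).

## Worked example

```r
library(escapesim)

s <- generate_epoch_scenario(default_threats()$dog, "attack", "short",
                             seed = 42)
verify_time_to_impact(s)
#> [1] 1.5

sim <- simulate_epoch(s, agent_policy(initiation_delay = 1.2,
                                      escape_speed = 2), seed = 42)
su  <- summarize_epoch(sim$recording, sim$event_log, s)
```

which prints, for this seed:

```
initial threat position: -6.364 8.864
nominal approach time : 2.571 s
chase onset           : 1.929 s
verified time-to-impact: 1.5 s
escape_initiation_time  1.452
mean_speed              2.008
peak_speed              2.148
body_orient_escape     -0.200
scan_appear            73.030
min_dist_threat         1.015
outcome: escape_to_shelter
```

Reading this: the dog (3.5 m/s) was placed 9 m up a -45° approach ray so
that the short condition's 1.5 s time-to-impact is realized exactly; it
would start chasing at 75% of its 2.57 s approach. The simulated
participant initiated escape ~1.45 s after appearance (commanded delay
1.2 s plus the 0.5 m departure-radius crossing), ran at ~2 m/s with body
oriented slightly away from the threat (cosine -0.2, the policy value),
scanned ~73°/s in the 1.5 s after appearance, and reached the shelter
with ~1 m to spare.

A full seeded pipeline run (cohort → summaries → detector calibration →
contrast table with Holm-adjusted p-values):

```r
res <- run_pipeline(pipeline_config(n_subjects = 8), seed = 1)
res$contrasts
```

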