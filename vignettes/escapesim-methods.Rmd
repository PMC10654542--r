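---
title: "Models and methods behind escapesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind escapesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

escapesim studies a minimal but complete model of human escape decisions
under naturalistic threat: a forager picks fruit at a bush, a threat appears
from cover and approaches, and the forager must decide whether and when to
run to a shelter. The package provides the full analysis pipeline for such
experiments — scenario generation, trajectory simulation, behavioral feature
extraction, vocalization detection, and factorial mixed-model inference —
so that every analysis step can be validated on synthetic data with known
ground truth before it touches real motion-capture recordings.

# Scenario kinematics and time-to-impact

The central experimental variable is **time-to-impact** `T_Plan`: the
maximum delay after threat appearance such that a participant escaping at
the assumed speed just barely avoids contact. It formalizes the classical
notions of defensive distance and predatory imminence as a single number in
seconds. The arena is one-dimensional at heart: the shelter sits at
`S_esc = -2.5` m and the fruit bush at `S_P = +2.5` m on the escape axis
(5 m escape distance), with assumed participant speed `V_P = -2` m/s.

Threat placement inverts the constant-velocity equations of motion:

* **Threat faster than the participant** (chasing): place it so that threat
  and participant would arrive at the shelter simultaneously if the escape
  started exactly `T_Plan` after appearance:
  `S_T = S_esc - V_T ((S_esc - S_P)/V_P + T_Plan)`.
* **Threat no faster than the participant, or ballistic**: place it so that
  it reaches the fruit-picking position exactly `T_Plan` after appearance:
  `S_T = S_P - V_T T_Plan`.

The boundary case `|V_T| = |V_P|` is routed to the second rule, which stays
well-defined where the first becomes degenerate. `verify_time_to_impact()`
inverts the generated geometry in closed form; the test suite requires the
round trip `generate -> verify` to be exact to 1e-9 s across a grid of
speeds, and checks both placements against an independent discrete-time
forward simulation of both movers.

Approach direction is drawn from {-45°, 0°, +45°}; the threat is placed at
the 1-D distance along that ray, so the total path length — and therefore
the nominal approach time — is independent of the angle. In attack epochs a
chasing threat switches from the straight bush-bound approach to pursuit
after **75%** of its nominal approach time; in divert epochs it changes to
an off-axis heading after **20%** (left approach diverts right +90°, right
diverts left -90°, center picks ±110° at random). The ballistic rock never
turns: its divert variant offsets the initial rolling direction by ±5° so
it misses the forager but must still be watched to judge the trajectory.

# The epoch simulator

`simulate_epoch()` plays out one encounter at the VR frame rate
(dt = 1/90 s by default, optionally with ±10% timestamp jitter to exercise
irregular-sampling code paths). The threat follows its schedule; pursuit is
per-step **pure pursuit** of the participant's current head position — the
simplest model consistent with "the threat chases the participant"; whether
a real threat re-targets continuously is unknowable from the data, so this
is a modeling choice, not a claim.

The participant follows an `agent_policy()`: picking fruit (a point process
at the policy rate with a 1 s minimum inter-pick gap) until an initiation
delay after appearance, then running at a constant escape speed toward the
shelter. Orientation is controlled directly in cosine units: the body
forward vector is held at `acos(w)` from the participant-to-threat
direction, so the epoch-level mean orientation cosine equals the policy
parameter `w` by construction. Head scanning is a sinusoidal yaw oscillator
whose mean absolute angular velocity equals the requested deg/s rate
(rate = 4 × amplitude × frequency), with an amplitude step-up during the
1.5 s post-appearance burst window.

Epochs terminate in exactly one of three outcomes: **virtual death** (any
sample with participant-threat distance at or below the 0.4 m contact
radius, or shelter entry while the threat is within the 1.0 m door-blocking
radius), **escape to shelter** (head inside the 0.5 m shelter disc), or
**survived** (timeout). The contact and door radii are not published
(contact used "a set of simple volumes" in the original environment) and
are configurable; defaults were chosen once as plausible body-scale values
and never tuned against test outcomes.

Non-natural elements mirror the perturbation conditions: an active **force
shield** makes contact non-lethal; a **hands-up** policy in a signaled
epoch halts the threat at the moment the gesture is made; **Medusa** epochs
end in virtual death when the head-orientation cosine toward the threat
stays at or above cos 30° for 0.1 s (inclusive threshold; both constants
are unpublished design gaps, documented here and configurable).

## What the synthetic cohort does and does not emulate

`generate_cohort()` produces balanced factorial datasets with
subject-level random intercepts realized as policy-parameter offsets and
questionnaire scores linked to behavior through explicit coefficients. The
default effect sizes echo the first experiment's reported magnitudes:
initiation around 1.3 s (short) vs 2.9 s (long time-to-impact), escape
speeds near 1.9 m/s (fast threats) vs 1.4 m/s (slow), body orientation
+0.2 (slow) vs -0.3 (fast), scanning bursts lower for the human threat,
and a late-watched rock under long time-to-impact. These are *stated-world*
constants: they define what a green test establishes — that injected
effects of realistic size are recovered by the pipeline — not that real
humans behave this way. The generator does not emulate within-epoch speed
variability, 3-D posture, hand trackers, eye physiology, or acoustic
coupling between vocal events and motion; conclusions about those channels
cannot be drawn from green tests here.

# Feature extraction

All time averages over irregular samples use the trapezium rule with linear
interpolation at window edges (`time_average_trapezium()`); windows are
half-open `[start, end)` and clipped to the sampled range. Two windows
matter: 0–1.5 s after threat appearance (the length of the shorter
time-to-impact) and the escape window from initiation until shelter entry
or epoch end, whichever is earlier. For no-threat epochs the anchor is a
reference time drawn uniformly from the 1–11 s appearance-delay law under
the epoch seed, mirroring how the original environment pre-registered a
random reference point.

Escape initiation is detected as the first time the head tracker leaves a
0.5 m radius around the fruit-picking position with radial velocity outward
sustained for 0.3 s. Both thresholds are unpublished; the defaults are
documented and configurable, and the detector's sustain rule is what keeps
brief postural excursions from counting as escapes. Speeds come from
central finite differences smoothed over 0.1 s (raw 90 Hz differences are
noise-dominated for peak statistics). Orientation cosines use horizontal
projections only, because the analyzed angles are about the vertical axis.
Visual scanning is the cumulative angle between consecutive forward
vectors per unit time — the full angle, not yaw-only, since forehead
movement is not restricted to one axis; the gaze variant is the same
computation on the gaze channel when present. When no escape is initiated,
exactly the escape-dependent fields are missing; this missingness contract
is property-tested.

One ambiguity deserves a note: whether escape-window orientation measures
should start at threat appearance or at escape initiation is not decidable
from the published description. escapesim uses initiation-to-end and
exposes the window in `feature_config()`.

# Vocalization detection

The detector is deliberately primitive, matching the validated original: a
clip is voiced if the time its rectified amplitude spends strictly above a
volume threshold strictly exceeds a time threshold. Rectification (|x|) is
a choice — microphone polarity is arbitrary — and both comparisons are
strict ("above", "exceeds"). Calibration is a constrained grid search:
among tuples with in-sample miss rate ≤ 5%, take the one with fewest false
alarms; ties go to the highest volume, then the highest time threshold
(the most conservative detector; any deterministic rule would do, this one
is documented). The default grids are 20 log-spaced volume points spanning
the data's amplitude range and 0.01–0.2 s in 0.01 s steps — the original
grid is unpublished. Monte Carlo cross-validation holds out exactly 1/k of
clips per repetition without stratification. Synthetic clips are Gaussian
noise, with voiced clips adding an amplitude-modulated tone burst whose
peak is five times the noise SD; at that separation the calibration is
feasible by construction.

# Inference

Every epoch statistic is analyzed with the factorial mixed model
`DV ~ threat * tti * behavior + (1 | subject)` — full interactions, one
random intercept per subject; Gaussian for continuous responses, logistic
(Laplace approximation) for binary ones. On convergence failure the fit
retries all available optimizers and, for binary models, finally drops the
integration over random effects (nAGQ = 0). Estimated marginal means are
computed by hand on top of lme4: model predictions per design cell with
random effects at zero, with the full EMM covariance propagated by the
delta method into Wald contrasts. The balanced-design identity EMM = raw
cell mean is property-tested, which pins the implementation without
requiring the reference EMM package (not available in this environment).
Degrees of freedom use the normal approximation; acceptance therefore
targets effect recovery, not p-value equality with any particular
reference implementation.

Holm–Bonferroni adjustment is the textbook step-down (sort, multiply by
`m - i + 1`, running maximum, cap at 1) applied across the whole
replication hypothesis family at once. The eleven shipped hypotheses are
equal-weight group contrasts on the EMM grid; the original contrast weights
are unpublished, so the definitions live in an editable JSON file and in
`default_hypotheses()`.

Questionnaire screening retains scores with bivariate r² > 0.10 against a
subject-level outcome, caps the set at the three strongest, and always
appends sex; the joint explanatory power is an ordinary multiple-regression
R² on subject-level data.

# Numerical and testing choices

* Placement round trips must be exact to 1e-9 s; placements are also
  checked against a 1 ms-step forward-simulation oracle with the final
  crossing interpolated inside the last step (naive one-sided stepping
  cannot resolve 2 mm at 6 m/s).
* The trapezium oracle integrates the piecewise-linear interpolant on a
  dense grid that includes the original knots, making the comparison exact
  rather than O(h²)-limited.
* Parameter-recovery acceptance runs 100 seeded replicates of 30-subject
  cohorts; to stay within the test-time budget these simulate at
  dt = 1/60 s instead of 1/90 s (the scanning and averaging features are
  sampling-robust by their own property tests) and use a 2-threat
  sub-design of the full factorial.
* One global seed fans out to stage and epoch child seeds through a
  linear-congruential scheme kept below 2³¹, so every pipeline stage is
  independently reproducible.

# Known limitations

The simulator's pure-pursuit threat slightly shortcuts the via-bush path
once chasing begins, so at the exact feasibility boundary an angled attack
is marginally harsher than the 1-D placement promises; the boundary
property is therefore stated (and tested) on the straight approach. Escape
speed is constant within an epoch, unlike real participants. Binary mixed
models on very small cohorts are close to separation and rely on the
optimizer fallback chain; the pipeline smoke tests restrict the hypothesis
battery to continuous responses at such sizes. None of the human-cohort
percentages reported for the original experiments are reproducible from
synthetic data, and the package makes no attempt to fake them.
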