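Package: escapesim
Title: Simulation and Analysis of Escape Decisions in Virtual Threat Encounters
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying human escape behavior in immersive
    virtual-reality threat encounters. Generates encounter scenarios whose
    geometry realizes a prescribed time-to-impact, simulates participant and
    threat trajectories together with epoch event logs, extracts epoch-level
    behavioral summary statistics from motion-tracking time series (escape
    initiation, speeds, orientation cosines, visual scanning, foraging
    rates), detects vocalization events in audio by amplitude-duration
    thresholding with constrained grid-search calibration and Monte Carlo
    cross-validation, and fits factorial mixed-effects models with
    estimated-marginal-mean contrasts and Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
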