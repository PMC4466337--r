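Package: optorc
Title: Reverse-Correlation and Linear-Nonlinear Models of Two-State
    Navigation Behavior
Version: 0.1.0
Authors@R:
    person("optorc", "developers", email = "optorc@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying sensory-driven switching between two
    behavioral states (runs and turns) under binary white-noise
    optogenetic stimulation.  Provides generators for Bernoulli, step and
    pulse-train light sequences; a ground-truth stochastic simulator of
    larval populations whose run-to-turn and turn-to-run hazards are
    linear-nonlinear (LN) functionals of the stimulus; event extraction
    and crawling-speed analysis; event-triggered-average estimation of
    linear filters by reverse correlation; static-nonlinearity fitting;
    LN prediction of transition-probability dynamics for arbitrary
    stimulus waveforms; and the associated significance machinery
    (two-proportion z-tests against baseline, per-lag t-tests against a
    control).  All file formats are plain-text CSV/JSON, and a small
    command-line interface wires the stages into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
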