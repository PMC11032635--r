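Package: midpointr
Title: Conflict-Task Diffusion Models and the Midpoint Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of sequential-sampling models of conflict
    tasks (Eriksen flanker, Stroop, Simon). Implements the time-dependent drift
    rates of the dual-stage two-phase model (DSTP), the shrinking-spotlight
    model (SSP, including a biased-neutral extension), and the diffusion model
    of conflict (DMC, including a concave controlled-process extension);
    deterministic threshold-crossing predictions; Euler-Maruyama first-passage
    Monte Carlo; and midpoint-assumption analytics for the congruent / neutral /
    incongruent design: the ratio R = (RT_N - RT_C) / (RT_I - RT_N), the
    symmetry gap, a packaged 52-study literature table, study-table aggregation,
    and the subject-level paired midpoint t-test. A command-line interface
    covers prediction, simulation, synthetic-experiment generation and table /
    trial analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
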