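Package: compasswalk
Title: Powered Compass-Gait Walking Model and Treadmill Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for the powered simple (compass-gait)
    walking model with a hip torque spring, push-off and gravitational impulses.
    Finds periodic gaits as fixed points of the post-collision Poincare map,
    sweeps hip-spring stiffness at fixed walking speed, and computes the gait
    observables used in human studies: margin of stability, propulsive force and
    maximum hip flexion torque. A companion pipeline analyses treadmill
    motion-capture trials (ground-reaction-force gait events, zero-lag
    filtering, step geometry, hip quasi-stiffness, double-support regression and
    a per-speed correlation battery), and a synthetic-trial generator produces
    model-driven motion-capture data with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
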