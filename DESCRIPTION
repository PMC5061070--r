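Package: wristsim
Title: Virtual Muscle-Driven Wrist Joint Motion Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a two-degree-of-freedom tendon-driven wrist joint
    actuated by six cable "muscles" (FCR, FCU, ECRL, ECRB, ECU, APL) and
    implements four closed-loop control strategies for muscle-activated
    joint motion simulators: position control with moment-arm-ratio
    excursion distribution, per-muscle force control, hybrid control with
    per-muscle force bounds, and cascade control in which joint-torque
    PID loops feed a quadratic-programming distribution of torque onto
    nonnegative muscle forces under a total-force (impedance) constraint.
    Includes trajectory generation for planar and complex wrist motions
    (flexion-extension, radioulnar deviation, dart thrower's motion,
    circumduction), Ziegler-Nichols gain tuning, co-contraction sweeps,
    and kinematic-error and repeatability metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
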