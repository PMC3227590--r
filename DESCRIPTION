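Package: graspecon
Title: Closed-Loop Prosthetic Grasping: Simulation, Segmentation, Scoring and
    Vibrotactile Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study grip-force economy in closed-loop prosthetic
    grasping. Simulates grasp-and-lift trials with a gated-ramp force
    controller, injected timing uncertainty and lossy force/position sensing;
    automatically segments trajectories into reach, force-ramp, lift and
    replace phases; detects drop, slip and failed-lift errors from
    force-kinematic rules; computes per-trial performance measures and a
    per-subject normalised compound grasp score; models a spatially encoded
    vibrotactile force display on an eight-motor forearm array; and implements
    adaptive-staircase two-interval forced-choice psychophysics with
    maximum-likelihood cumulative-Gaussian fits, just-noticeable-difference
    profiles and discriminable-level counts. Includes generators for the
    block/condition structures of three feedback-manipulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
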