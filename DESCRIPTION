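Package: perchgrip
Title: Mechanics of Bird Perching: Claw-Asperity Engagement, Stick-Slip
    Friction and Grasp Stability
Version: 0.1.0
Authors@R:
    person("Perchgrip", "Developers", email = "perchgrip@example.org",
           role = c("aut", "cre"))
Description: Models of how birds grasp complex perches: traced-surface
    simulation of claw-tip engagement with rough surface profiles
    (including a Hertzian penetration correction to the minimum asperity
    slope), stick-slip friction statistics with Monte Carlo load-sharing
    and drag-distance simulations, a planar rigid-body grasp-stability
    model solved as a linear program over contact friction cones with
    directional safety margins, and tau-theory analysis of landing
    approaches. Includes parametric generators for rough surfaces, drag
    traces, claw profiles and landing trials with embedded ground truth,
    so every estimator ships with a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
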