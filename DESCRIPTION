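Package: inertialdelay
Title: Scaling of Inertial Delays in Quadrupedal Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minimum-time ('bang-bang') simulations of two corrective-movement
    tasks in terrestrial mammals - repositioning a swing limb (distributed-mass
    pendulum) and recovering upright posture after a push (point-mass inverted
    pendulum) - parameterized across seven orders of magnitude of body mass by
    published allometric scaling relationships for limb inertial properties and
    muscle architecture. Provides closed-form linearized models, an adaptive
    Runge-Kutta integrator with event detection, switch-time shooting for the
    posture task, log-log power-law regression of inertial delay against body
    mass, Monte Carlo propagation of scaling-parameter uncertainty to confidence
    intervals, and comparisons of inertial delay against sensorimotor delay and
    available movement time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
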