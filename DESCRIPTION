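Package: plumenav
Title: Agent-Based Simulation of Binaral Odor Plume Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-sensor (binaral) agent navigating turbulent odor
    plumes in a 1 x 1 m flow arena. Implements discrete-time agent kinematics,
    first-order gas-sensor dynamics with baseline acquisition, a reactive
    wall-avoidance hierarchy, and two minimal chemotaxis controllers: an
    instantaneous left-right comparison (tropotaxis, Code A) and a temporal
    gradient strategy falling back on the binaral comparison (klinotaxis,
    Code B). Plume inputs can be HDF5 concentration movies, their time
    averages, or movies from a bundled Gaussian-puff generator with lateral
    meander and a complexity preset. Includes trajectory metrics (linearity,
    total turning angle, wall hugging, nose/body path ratio), batch sweep
    runners over start angles with hierarchical seeding, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
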