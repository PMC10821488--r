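Package: wheelmotion
Title: Detection of Active Versus Attendant-Pushed Wheelchair Propulsion from
    Wheel- and Frame-Mounted Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs manual-wheelchair kinematics (forward speed,
    acceleration, roll/pitch/yaw angular rates, 2D path) from 50 Hz
    wheel-hub and frame-mounted 6-axis inertial sensors, segments movement
    into propulsion bouts, builds a fixed 56-predictor aggregate feature
    set per bout, and classifies each bout as self-propelled (active) or
    attendant-pushed (passive) using cross-validated model selection over
    five classifier families. Includes a physics-based synthetic trial
    simulator that renders ground-truth trajectories into raw sensor
    streams, so the whole chain can be validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml,
    e1071,
    randomForest,
    xgboost
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
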