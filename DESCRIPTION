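Package: fluidintake
Title: Hierarchical Fluid-Intake Monitoring from a Wrist-Worn Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects drinking activities, spots the sip gesture within them,
    and estimates the ingested amount in grams from a single wrist-worn
    six-channel inertial sensor (tri-axial accelerometer and gyroscope at
    128 Hz). The pipeline combines moving-average smoothing, sliding-window
    statistical features over eleven signal axes, machine-learning window
    classifiers with rule-based label post-processing (fragment revision and
    a minimum-duration threshold), five-class drinking-gesture spotting, and
    container-dependent or container-independent regression of intake amount
    from sip-gesture features. A synthetic wrist-IMU cohort generator
    emulating a scripted activity protocol makes every stage testable
    end-to-end, with leave-one-subject-out evaluation utilities and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    randomForest,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
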