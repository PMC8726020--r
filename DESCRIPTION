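Package: imubalance
Title: Automatic Balance-Activity Detection and Assessment from Lumbar
    Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects sit-to-stand, 360-degree turning, and stand-to-sit
    motion intervals in six-channel lumbar inertial-sensor recordings
    (tri-axial accelerometer and gyroscope at 40 Hz) with a convolutional
    LSTM window classifier followed by rule-based interval postprocessing,
    extracts balance features (anterior-posterior acceleration peak count,
    average turning speed) from the detected intervals, and classifies
    individuals as normal versus deviating-from-healthy in the sense of the
    Tinetti POMA-B grading items using one-class SVM, LDA, or k-NN, under
    leave-one-subject-out cross-validation with McNemar agreement
    statistics.  Includes a seeded synthetic-recording generator emulating
    the balance tasks for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    zoo,
    pracma,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
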