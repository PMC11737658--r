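Package: domesync
Title: Session Logs, Display-Timing Synchronization and Dome Projection
    Geometry for Virtual-Reality Neuroscience Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for behavioral virtual-reality experiments that are
    projected into a hemispherical dome and synchronized with neural
    recordings. Provides a plain-text timed session-log dialect (writer,
    streaming parser, trajectory / state-interval / performance extraction),
    conversion of game-thread event times to on-screen display times from
    per-frame flip timestamps with a fixed rendering-pipeline and projector
    delay, photodiode-based verification of display timing with residual
    statistics, conversions between engine Cartesian coordinates, angular
    dome coordinates and fisheye image coordinates (directly and through a
    five-camera rig), warp-mesh loading and application, per-frame receptive
    field mapping stimulus schedules (moving bar, flashed Gaussian blobs,
    sparse noise), and a synthetic session simulator with configurable frame
    skips, pauses, clock offsets and photodiode noise so that the whole
    pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite
Config/testthat/edition: 3
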