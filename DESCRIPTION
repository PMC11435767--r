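Package: strokewave
Title: Rowing Stroke Segmentation from Hull Acceleration via the
    Undecimated Wavelet Transform
Version: 0.1.0
Authors@R:
    person("Strokewave", "Developers", email = "strokewave@example.org",
           role = c("aut", "cre"))
Description: Detects per-stroke rowing events (cycle start, drive start,
    drive end) from a single hull-mounted accelerometer using a 9-level
    biorthogonal 4.4 undecimated (stationary) wavelet transform, with
    peak searches on the level-3 and level-2 approximation coefficients.
    Includes the oarlock-force reference procedure (gate-force summation,
    per-stroke peak detection, positive-to-negative zero-crossing drive
    end, and a threshold-crossing drive-time surrogate), an agreement
    statistics battery (intraclass correlation with F test and confidence
    interval, Bland-Altman limits of agreement, ordinary least squares
    regression), and a seeded generator of paired synthetic
    acceleration/force sessions with known ground-truth events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
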