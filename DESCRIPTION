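Package: fnrp
Title: Free Navigation Reference Point Planning for Secondary Zygoma Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Navigation planning toolkit for secondary reduction of dislocated
    zygoma fractures. Estimates the dislocated-to-reduced rigid transform by
    landmark fitting and iterative closest point (ICP) matching of bone-surface
    point clouds, converts intraoperatively chosen surface marks into free
    navigation reference points (FNRPs), back-calculates planned screw-hole
    positions onto the dislocated bone through the inverse transform, simulates
    the probing procedure, and evaluates drilling deviations and global
    reduction errors (geometric-centre displacement plus per-axis rotation).
    Includes STL mesh input/output, plain-text point, landmark and transform
    formats, and a synthetic skull-plus-zygoma phantom generator with known
    ground-truth dislocation for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
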