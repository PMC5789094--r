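Package: nanocal
Title: Traceable Distance Calibration of DNA Origami Nanorulers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration toolchain for intermark distance measurements on
    DNA origami nanorulers imaged by DNA-PAINT single-molecule localization
    microscopy. Provides a Monte-Carlo simulator of binding-site blinking
    kinetics with simultaneous-emitter merging, density-based structure
    picking, projected two-mark distance fitting by a one-dimensional
    Gaussian mixture, stage-micrometre pixel-size calibration, propagation
    of a full GUM-style measurement uncertainty budget with expanded
    uncertainty, two-color channel registration with correlation-density
    evaluation, and drift/resolution benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: stats, utils, graphics, grDevices, tiff, yaml
Suggests: testthat (>= 3.0.0), mclust, optparse, jsonlite, withr, knitr
Config/testthat/edition: 3
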