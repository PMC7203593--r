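Package: spinewise
Title: Lumbar Spine Multi-Body Modelling and Stepwise-Reduction Ligament Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static multi-body modelling of lumbar motion segments with
    nonlinear intervertebral-disk, ligament, facet-contact and muscle-cable
    force elements. Implements backward stepwise-reduction calibration, which
    extracts disk torque-angle and ligament force-strain characteristics from
    range-of-motion tables measured while passive structures are removed one at
    a time, and forward validation protocols for range of motion and
    intradiscal pressure, including outlier counting against experimental
    ranges. Ships a synthetic-data generator so the complete
    calibrate-then-validate loop runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
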