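Package: dropmetry
Title: Vision-Based Droplet Morphometry for Microfluidic Droplet Generators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures water-in-oil droplets in raster images of a
    microfluidic outlet channel and tracks droplet-generator performance
    over time. Implements the full still-image pipeline: colour-band
    extraction, fixed-threshold binarization, from-scratch binary
    morphology (erosion, dilation, opening), size-based noise filtering,
    Moore-neighbour boundary tracing with Jacob's stopping criterion,
    area- and perimeter-based diameter estimation with
    pixel-to-millimetre calibration against a known channel width, and
    quadratic time-trend fitting of the mean droplet diameter. Includes a
    ground-truthed synthetic scene generator for end-to-end validation,
    experiment-protocol arithmetic (sampling schedules, PWM voltage
    quantization), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
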