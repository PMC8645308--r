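Package: texturality
Title: Predicting Perceived Texturality of Images from Summary Texture Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes Portilla-Simoncelli texture statistics of grayscale
    images via a complex steerable pyramid, collapses them into
    class-by-spatial-frequency summary variables, screens the variables
    against behavioral texture/non-texture judgments with logistic
    correlations, and classifies images as texture or non-texture with a
    small-feature radial-basis-function support vector machine. Includes
    generators for synthetic texture and non-texture stimuli and a
    simulated observer, so that every stage of the pipeline is testable
    without behavioral data, plus a command-line interface tying the
    stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
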