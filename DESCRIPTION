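Package: lfiaQuant
Title: Channel-Optimized Colorimetric Readout for Lateral Flow Immunoassays
Version: 0.3.1
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of lateral flow immunoassay (LFIA) strips from
    colour-camera images. Implements spectral selection of the Bayer colour
    channel that is most sensitive to the labelling particle (colloidal gold,
    iron oxide), extraction of native-site channel planes from an RGGB colour
    filter array, test-line densitometry via the background-to-test-line
    intensity ratio I(b)/I(t), calibration-curve fitting with linear-range and
    limit-of-detection estimation, and Bonferroni-corrected comparison of
    channel readout methods. A synthetic strip-image simulator with known
    ground-truth concentration response makes the full pipeline testable
    without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    yaml,
    jsonlite
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'lfiaQuant-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'spectral.R'
    'simulate.R'
    'readout.R'
    'quantify.R'
    'pipeline.R'
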