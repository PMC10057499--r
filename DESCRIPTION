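Package: thermovasc
Title: Virtual-Wave Analysis of Dynamic Infrared Thermography for Vascular Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cold-stress dynamic infrared image sequences of the
    breast. A time-lapse of calibrated skin-temperature images recorded after
    fan cooling is converted, per pixel, from diffusive heat-propagation
    signals into virtual wave signals by a regularized ill-posed inversion
    (the virtual wave transform), then separated into physically distinct
    components by an uncentered principal-component factorization over images
    followed by independent-component unmixing of the time matrix with the
    inverse rotation applied to the images, so the matrix product (the data
    reconstruction) is preserved. Components are classified by polarity into
    passive thermal reflections from constant-temperature vessel boundaries
    and active vasoconstriction responses, vessel depths are estimated from
    virtual arrival times, and vasoconstriction-deficit maps are produced. A
    one-dimensional heat-diffusion phantom generator with known vessel ground
    truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
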