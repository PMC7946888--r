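Package: mprheo
Title: Multiplane Microscopy Particle Tracking and Optical-Tweezers
    Microrheology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional passive microrheology with optical
    tweezers using multiplane (simultaneous multi-focal-plane) microscopy.
    Simulates the Brownian dynamics of an optically trapped bead (exact
    Ornstein-Uhlenbeck updates), renders synthetic tiled multiplane camera
    frames of a bead with defocus-dependent blur, localises the bead in 3D
    from such frames using an image-sharpness weighting scheme with in-situ
    self-calibration, and extracts trap stiffness, trap-volume width, and
    relative fluid viscosity from the resulting trajectories via normalised
    mean-squared-displacement and position-autocorrelation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    withr
Config/testthat/edition: 3
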