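Package: pwbeam
Title: Multi-Angle Plane-Wave Ultrasound Beamforming with Adaptive Signal Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstruction of multi-angle plane-wave ultrasound images from
    raw channel data. Implements coherent plane-wave compounding (CPWC),
    minimum-variance (Capon) beamforming in the receive-channel and
    transmit-angle dimensions with subarray, temporal and forward-backward
    covariance averaging and diagonal loading, delay-multiply-and-sum (DMAS)
    coherence imaging via p-th-root magnitude scaling, and an adaptive
    pixel-wise coherence order (ADMAS) driven by generalized-coherence-factor
    and angular-variance maps. Includes image-quality metrics (lateral FWHM,
    contrast ratio, contrast-to-noise ratio, generalized CNR), a synthetic
    plane-wave RF simulator for point, speckle and cyst phantoms, and
    PICMUS-style HDF5 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rhdf5,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
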