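Package: transmitscope
Title: Deconvolution Imaging Analysis of Genetically Encoded
    Transmitter Sensor Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for wide-field fluorescence movies of
    genetically encoded neurotransmitter sensors (iAChSnFR, GRAB,
    dLight and related probes). Provides a forward simulator of sensor
    movies with known ground truth (quantal release, vesicle-pool
    depletion and refill, exponential spatial transmitter spread,
    sensor kinetics, point-spread-function blur, photon and read
    noise, photobleaching and drift), preprocessing (rigid sub-pixel
    drift registration, photobleaching correction, denoising, delta
    F over F computation), point-spread-function estimation from
    fluorescent bead images plus diffraction-limit arithmetic,
    Richardson-Lucy deconvolution with quality diagnostics, detection
    of isolated release sites and single-exponential fitting of the
    transmitter spread length constant, and estimation of readily
    releasable pool size, refill rate, release probability and quantal
    size from prolonged stimulus trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
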