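Package: hemipa
Title: Virtual Dense Hemispherical Arrays for Sparse Photoacoustic Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for artifact reduction in 3D photoacoustic tomography with
    sparse hemispherical (golden-ratio / Fibonacci lattice) transducer arrays.
    The array is decomposed into three families of spiral chains at Fibonacci
    index intervals (34, 21, 13); virtual sensors are placed between
    chain-adjacent real sensors, their signals are estimated either by linear
    interpolation or by a per-direction convolutional regression network, and
    artifact-reduced initial-pressure volumes are reconstructed by inverse
    filtering of the transducer response followed by universal back-projection.
    Includes a complete N-wave forward simulator (spherical and cylindrical
    absorbers, transducer bandwidth limitation, calibrated noise) so every
    stage can be exercised without measured data, plus volume signal-to-noise
    and signal-correlation evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
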