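Package: llsheet
Title: Design and Simulation of Lattice Light-Sheet Illumination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scalar-diffraction simulation and design toolkit for
    light-sheet microscopy illumination. Synthesizes rear-pupil fields for
    Gaussian, sinc, Bessel, multi-Bessel lattice, axially confined
    lattice, harmonic-balanced lattice and cosine-sinc light sheets;
    models spatial-light-modulator phase pattern generation (grayscale
    and binary, with sidelobe cropping) followed by annular-mask
    filtering; computes excitation and overall point-spread and transfer
    functions as a function of propagation distance; and scores practical
    axial resolution with a variable-pitch stripe phantom imaged under a
    realistic camera noise model, Richardson-Lucy deconvolution and
    Fourier-shell-correlation-guided stopping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    tibble,
    ggplot2,
    rlang,
    generics,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
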