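Package: flickspec
Title: Flicker Spectroscopy and FTIR Analysis of Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring membrane mechanics and structure from two
    complementary experiments. The flicker-spectroscopy chain extracts
    equatorial contours of giant unilamellar vesicles or red blood cells from
    video frames, decomposes them into Fourier modes, estimates the thermal
    fluctuation spectrum of the mode amplitudes, and fits planar-membrane
    models to recover the bending modulus, reduced tension and (for red
    blood cells) the skeleton confinement strength. The FTIR chain builds
    melting curves from the CH2 symmetric stretching band position, locates
    the main phase transition temperature from the derivative maximum,
    computes the thermal-expansivity proxy beta, and quantifies probe
    partitioning from a two-Gaussian decomposition of the carbonyl
    stretching band of membrane-solubilized tungsten hexacarbonyl. A
    synthetic-data module generates contour sequences, rendered microscopy
    frames and infrared spectra with the statistical structure the analysis
    assumes, so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
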