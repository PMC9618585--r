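Package: tuberspec
Title: NIR Hyperspectral Classification of Potato Processing Aptitude
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric pipeline for classifying potato tubers by industrial
    processing aptitude (cooking versus frying as crisps) from near-infrared
    hyperspectral images of fresh-cut slices. Provides ENVI hypercube input and
    output, white/dark reflectance calibration, slice segmentation, spectral
    pre-processing chains (Savitzky-Golay smoothing and derivatives, standard
    normal variate, multiplicative scatter correction, mean centering), PCA and
    SIMPLS-based PLS-DA with venetian-blinds cross-validation at mean-spectrum
    and pixel level, forward interval PLS wavelength selection, pixel-wise
    classification maps, and a synthetic line-scan image generator that emulates
    the measurement so the whole pipeline runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
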