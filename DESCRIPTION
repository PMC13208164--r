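Package: lakeshade
Title: UV-Vis Spectral Reduction and Photochemical Sunscreen Modelling of
    Prebiotic Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing raw UV-Vis spectrometer counts to relative
    absorbance and molar attenuation coefficients via Beer-Lambert
    regression, and for simulating a layered stagnant-lake photochemical
    system in which dissolved ferrocyanide and nitroprusside attenuate
    ultraviolet flux and so act as sunscreens for photosensitive prebiotic
    compounds. Includes a synthetic spectrometer-data generator with known
    ground truth (inverse-square source geometry, Poisson counting noise,
    Gaussian-band attenuation curves), signal-to-noise masking and
    replicate aggregation, per-wavelength calibration regressions with
    uncertainty propagation, additive spectral combination of mixtures,
    and a depth-layered kinetic model of ferrocyanide photo-oxidation and
    photo-aquation with band-wise flux attenuation, survival times and
    shadow-slope extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
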