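Package: eemdom
Title: Fluorescence EEM Preprocessing and Nonnegative PARAFAC for
    Algae-Derived Dissolved Organic Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for excitation-emission matrix (EEM) fluorescence
    spectroscopy of dissolved organic matter (DOM): blank subtraction,
    absorbance-based inner-filter correction, Raman-area normalization to
    Raman Units, Rayleigh/Raman scatter excision with Whittaker-smoothing
    interpolation, nonnegative PARAFAC decomposition by alternating least
    squares with expectation-maximization handling of masked cells,
    split-half validation with Tucker congruence, Coble-peak classification
    of fluorophores, and fluorescence-intensity contribution accounting.
    Includes a synthetic EEM generator emulating microalgae culture
    experiments so that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
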