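Package: eem2d
Title: Triangular Two-Dimensional Fluorescence Spectra: Conversion, Display
    and Slicing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for accelerated two-dimensional fluorescence spectroscopy
    based on the triangular acquisition scheme, in which each emission scan
    starts just above the current excitation wavelength so the physically
    empty region below the Rayleigh line is never measured.  The package
    parses plain-text fluorometer group exports (raw and corrected
    channels), converts triangular scan sets into rectangular
    excitation-emission matrices (EEMs) by zero-filling the unmeasured
    upper triangle, subtracts buffer baselines and difference spectra,
    computes percent-of-scale contour levels, annotates Rayleigh
    (first-order), second-order and water-Raman scatter ridges, extracts
    one-dimensional emission and excitation slices with
    nearest-existing-wavelength semantics, plans rectangular, triangular
    and trapezoidal acquisitions and quantifies the up-to-two-fold time
    saving, and simulates realistic EEMs (Gaussian fluorophores plus
    scatter ridges and noise) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
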