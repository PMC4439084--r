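Package: wmrs
Title: Wavelength-Modulated Raman Spectroscopy for Label-Free Single-Cell
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wavelength-modulated Raman spectroscopy (WMRS) of
    single cells: a synthetic acquisition simulator in which Raman bands
    translate with excitation wavelength over a static autofluorescence
    background, extraction of the fluorescence-suppressed modulated Raman
    spectrum of each cell as the first principal component across
    modulation steps, zero-crossing peak localisation, per-wavenumber
    two-sample t-test significance maps between cell subsets, and
    leave-one-out cross-validated nearest-neighbour classification in
    principal-component space with confusion matrices and pairwise
    sensitivity/specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
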