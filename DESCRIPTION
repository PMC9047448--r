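Package: msicelltyper
Title: Single-Cell MALDI-MSI Cell Typing with PCA/LDA Recognition Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds single-cell spectral libraries from MALDI mass spectrometry
    imaging (MSI) data and fits PCA/LDA recognition models that classify
    breast-cancer cell lines and receptor subtypes, with a standard-deviation
    based outlier rule. Provides centroid-spectrum preprocessing (rms
    normalization, mass-range restriction, fixed-width binning), ROI mean
    spectra, stratified cross-validation and holdout evaluation, pixel-wise
    offline and streaming tissue classification with area percentages,
    cross-instrument lipid-ratio comparison by one-way ANOVA, and a synthetic
    MSI data generator (cell and tissue images in processed-mode imzML or CSV)
    so the whole pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
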