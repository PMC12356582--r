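Package: patox
Title: Suspect Screening, Molecular Networking and Occurrence Statistics for
    Pyrrolizidine Alkaloids in Honey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale workflow for investigating pyrrolizidine alkaloids
    (PAs) and their N-oxides (PANOs) in honey by liquid chromatography coupled
    to high-resolution mass spectrometry. The package builds an in-silico
    MSP spectral library from literature fragmentation tables, derives the
    regulated 35-compound panel and a class-diagnostic ion list, simulates
    ground-truthed honey cohorts and data-dependent acquisition runs, runs a
    suspect-screening filter cascade with class-coverage filtering and
    fragmentation-coverage scoring, performs molecular networking of MS/MS
    spectra, implements matrix-matched calibration, validation metrics and
    lower-bound panel sums, and computes occurrence statistics (prevalence,
    analyte frequency, co-occurrence, one-way ANOVA, Pearson correlation and
    Ward hierarchical clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
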