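Package: pyroDOM
Title: Molecular Characterization of Pyrogenic Dissolved Organic Matter
    from FTICR-MS Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for ultrahigh-resolution mass
    spectrometry characterization of dissolved organic matter (DOM)
    across a wildfire burn-severity gradient. Filters centroided
    negative-mode peak lists (m/z window, 13C isotopologue removal),
    internally recalibrates mass axes against auto-detected CH2
    homologous series, aligns peaks across samples at sub-ppm
    tolerance, assigns CHONSP molecular formulas by bounded exhaustive
    enumeration within 0.5 ppm, computes per-formula descriptors
    (nominal oxidation state of carbon, aromaticity index, Van Krevelen
    compound classes), detects C4H2 Kendrick mass defect homologous
    series retained across burn-severity conditions, and compares
    conditions via unique-formula sets and one-sided pairwise Welch
    tests. Ships a seeded synthetic DOM spectrum generator with planted
    aromaticity effects so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
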