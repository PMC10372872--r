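Package: metims
Title: Native Ion Mobility Mass Spectrometry of Metalloprotein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for characterizing metal-protein complexes by
    native mass spectrometry, developed around Cu(I)/Zn(II)-metallothionein-3.
    Simulates isotopic fine-structure patterns for arbitrary elemental
    compositions, assigns metal and disulfide stoichiometries by fitting
    theoretical charge-state envelopes to observed spectra, calibrates
    traveling-wave ion-mobility drift times against reference collision cross
    sections, builds collision-induced unfolding fingerprints and conformer
    ratios, extracts E50 gas-phase stability midpoints from survival-yield
    curves, and annotates native top-down b/y fragment ions with metal adducts
    for domain-level metal localization. Includes a synthetic-data generator
    that emulates the experimental observables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
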