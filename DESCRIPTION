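Package: simslipid
Title: Single-Cell ToF-SIMS Lipidomics: Abundance Profiling and
    Isotope-Label Turnover Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-of-flight secondary ion mass
    spectrometry (ToF-SIMS) hyperspectral images of cultured cells on
    conductive substrates. Provides a lipid shorthand parser and
    monoisotopic ion m/z calculus with adducts, neutral losses and
    stable-isotope labels; continuous-mode imzML read/write of 0.05-Da
    binned datacubes; marker-ion region-of-interest segmentation with
    substrate-interference removal and total-ion-current normalization;
    ranked abundance profiling with lipid-class summaries; PCA-guided
    discriminant peak selection followed by per-peak Mann-Whitney tests
    for labeled-precursor turnover calls; and a seeded synthetic
    datacube generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    EBImage,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
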