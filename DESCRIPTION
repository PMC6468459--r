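Package: glycotrait
Title: MALDI-TOF N-Glycomics Profiling, Derived Glycan Traits, and
    Glyco-Gene Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for composition-level MALDI-TOF
    N-glycomics under linkage-specific sialic acid derivatization (ethyl
    esterification of alpha2,6-linked N-acetylneuraminic acid, lactonization
    of alpha2,3-linked).  Provides a sodiated monoisotopic mass engine with
    isotopic pattern computation and composition enumeration, spectrum
    preprocessing (Savitzky-Golay smoothing, tophat baseline removal, peak
    picking, cubic internal recalibration), isotopic-pattern-corrected
    targeted extraction with spectrum- and analyte-level quality control,
    derived glycan trait calculation from normalized profiles, and the
    statistical layer used to associate traits with group labels and
    glyco-gene expression (Mann-Whitney with Bonferroni correction, PCA,
    per-gene t-tests, trait-gene regression).  A synthetic-data module
    generates cohorts of glycan profiles with prescribed trait structure,
    renders them as realistic spectra, and emits matched gene-expression
    matrices so that every stage is testable end to end.
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
    pracma,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
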