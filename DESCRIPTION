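Package: protquant
Title: Label-Free Differential Expression and PRM Absolute Quantitation
    for FFPE Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative proteomics of
    formalin-fixed paraffin-embedded (FFPE) breast lesions. Covers
    label-free quantitation (LFQ) preprocessing (detection filtering,
    summed-intensity normalization, per-sample minimum-based imputation,
    NSAF spectral-count normalization), per-protein differential
    expression with the Benjamini-Krieger two-stage adaptive FDR
    procedure, and absolute quantitation by parallel reaction monitoring
    (PRM): 1/x^2-weighted response-curve fitting with calibration-level
    acceptance, LOD/LOQ determination, and SIS-normalized concentration
    estimation. Includes a synthetic-data generator reproducing the
    statistical structure the analysis assumes (log-normal abundances,
    group effects, loading variation, intensity-dependent dropout,
    seven-point calibration series), so the full pipeline is testable
    without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    tools,
    yaml,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
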