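Package: etsdyn
Title: Dynamic Heterogeneity in DNA Site Discrimination by ETS Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for comparing sequence-specific DNA complexes of
    ETS-family transcription-factor DNA-binding domains. Implements the circular
    permutation electrophoresis bend model (a point-kink reptation description of
    relative mobility versus flexure displacement) with weighted Levenberg-Marquardt
    fitting, delta-method confidence bands, and nested-model F tests; replicate
    statistics for gel quantitation (Welch t tests with Benjamini-Hochberg false
    discovery rate control); dynamic light scattering size-distribution analysis
    (Stokes-Einstein conversion and log-normal fits summarized by geometric mean and
    geometric standard deviation); capillary footprint quantitation (peak integration,
    control-peak normalization, protection fractions, change flags, DNase I
    hypersensitivity calls); binding-motif information content and
    discrimination-energetics comparisons; and a seeded synthetic-data generator that
    emulates every input so the full pipeline is testable without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
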