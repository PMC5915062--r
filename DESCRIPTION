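Package: lcmProteomics
Title: Spectral-Count Differential Proteomics for Laser-Capture
    Microdissected Tissue
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free differential protein abundance analysis for
    spectral-count data from laser-capture microdissected (LCM) tissue.
    Implements pseudocount log2 fold-changes, per-protein two-group tests,
    presence/absence "all-or-nothing" exclusivity selection, Bonferroni and
    Benjamini-Hochberg multiple-testing regimes, gene-set over-representation
    scoring with a permutation-derived significance threshold, Ward
    hierarchical clustering of abundance profiles, cell-line contrast
    filtering, stable-isotope-dilution PRM absolute quantification with
    calibration-curve QC (LOD/LOQ/CV), and proteome-versus-transcriptome
    comparison. Ships a seeded synthetic-study generator with planted ground
    truth so the full pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
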