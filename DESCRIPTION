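Package: immunax
Title: Immunoregulatory Ligand-Receptor Axis Discovery from Single-Cell Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for discovering therapeutically targetable
    immunoregulatory axes (such as NECTIN2-TIGIT) from annotated single-cell
    RNA-seq count data of tumors. Implements plate-based (CEL-Seq2 style)
    quality control with spike-in calibrated liveness thresholds, gene-signature
    module scoring (cytotoxicity, dysfunction), permutation-null ligand-receptor
    interaction inference over a curated pair database, correlation-based target
    prioritization against effector-subset dysfunction scores, and per-sample
    cellular composition comparisons between treatment timepoints. Ships a
    negative-binomial synthetic data generator with planted ligand-receptor and
    dysfunction structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
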