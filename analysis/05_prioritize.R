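#!/usr/bin/env Rscript
# Target nomination: overlay of (i) membrane/secreted localization, (ii)
# significant ligand-receptor interaction with an effector subset, and (iii)
# significant positive correlation of per-sample partner expression with the
# effector's dysfunction score.

library(immunax)

seed <- 2026
cm <- read_counts("results/qc/matrix.mtx", "results/qc/genes.tsv",
                  "results/qc/cells.tsv")
nm <- normalize_cp10k_log1p(cm)
db <- read_lr_database("results/cohort/lr_pairs.tsv")
loc <- read_localization("results/cohort/localization.tsv")
ints <- readr::read_tsv("results/interactions/interactions.tsv",
                        show_col_types = FALSE)
scores <- readr::read_tsv("results/scores/module_scores.tsv",
                          show_col_types = FALSE)
scores <- scores[scores$signature == "dysfunction", ]

effectors <- c("CD8_T", "CD4_T_DUSP4")
partners <- unique(ints$source)

targets <- prioritize_targets(nm, cm$cells, scores, ints, db, loc,
                              partners, effectors,
                              genes = unique(unlist(db$ligand)))

dir.create("results/targets", recursive = TRUE, showWarnings = FALSE)
flat <- targets
flat$interaction_support <- vapply(flat$interaction_support, paste, "",
                                   collapse = ";")
readr::write_tsv(flat, "results/targets/targets.tsv")

# heatmap-style matrix of Pearson r per gene x (partner, effector)
wide <- tidyr::pivot_wider(
  targets[, c("gene", "population_x", "effector_y", "pearson_r")],
  names_from = c("population_x", "effector_y"), values_from = "pearson_r")
readr::write_tsv(wide, "results/targets/correlation_matrix.tsv")

called <- targets[targets$call, ]
cat(sprintf("%d rows called; top nominations:\n", nrow(called)))
print(as.data.frame(called[1:min(5, nrow(called)),
                           c("population_x", "gene", "effector_y",
                             "pearson_r", "corr_p")]), row.names = FALSE)
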