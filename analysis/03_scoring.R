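#!/usr/bin/env Rscript
# Normalization and signature scoring: log1p CP10K, cytotoxicity and
# dysfunction module scores per cell, and checkpoint receptor-ratio
# summaries (TIGIT/CD226, CD96/CD226 analogues) per population and sample.

library(immunax)

seed <- 2026
cm <- read_counts("results/qc/matrix.mtx", "results/qc/genes.tsv",
                  "results/qc/cells.tsv")
nm <- normalize_cp10k_log1p(cm)
sigs <- default_signatures()

scores <- dplyr::bind_rows(
  module_score(nm, sigs$cytotoxicity, name = "cytotoxicity", seed = seed),
  module_score(nm, sigs$dysfunction, name = "dysfunction", seed = seed))

dir.create("results/scores", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(scores, "results/scores/module_scores.tsv")

ratios <- receptor_ratio(nm, cm$cells, "TIGIT", "CD226",
                         group_by = c("population", "timepoint"))
readr::write_tsv(ratios, "results/scores/tigit_cd226_ratio.tsv")

by_pop <- dplyr::summarise(
  dplyr::group_by(dplyr::inner_join(scores, cm$cells, by = "cell_id"),
                  population, signature),
  mean_score = mean(score), .groups = "drop")
readr::write_tsv(by_pop, "results/scores/scores_by_population.tsv")

dys <- by_pop[by_pop$signature == "dysfunction", ]
cat("mean dysfunction score by population (top 4):\n")
print(as.data.frame(dys[order(-dys$mean_score), ][1:4, ]), row.names = FALSE)
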