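#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 24 plate-based samples (10 pre-, 14
# post-chemotherapy), twelve labeled populations, ERCC-style spike-ins and
# empty wells, one planted NECTIN2-TIGIT axis among 50 decoy pairs.
# Writes the raw artifacts under results/cohort/.

library(immunax)

seed <- 2026
sim <- simulate_cohort(sim_config(seed = seed))

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
write_counts(sim$matrix, "results/cohort")
readr::write_tsv(
  tibble::tibble(pair_id = sim$lr$pair_id,
                 ligand = vapply(sim$lr$ligand, paste, "", collapse = "+"),
                 receptor = vapply(sim$lr$receptor, paste, "", collapse = "+"),
                 annotation = sim$lr$annotation),
  "results/cohort/lr_pairs.tsv")
readr::write_tsv(sim$localization, "results/cohort/localization.tsv")
readr::write_tsv(sim$truth, "results/cohort/truth.tsv")

cat(sprintf("cohort: %d genes x %d wells across %d samples (%d empty wells)\n",
            nrow(sim$matrix$counts), ncol(sim$matrix$counts),
            length(unique(sim$matrix$cells$sample_id)),
            sum(sim$matrix$cells$sort_gate == "empty_well")))
cat(sprintf("planted axis: %s (%s) -> %s (%s)\n",
            sim$truth$ligand, sim$truth$source,
            sim$truth$receptor, sim$truth$target))
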