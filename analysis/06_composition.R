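#!/usr/bin/env Rscript
# Cellular composition: per-sample fractions over unbiased-sorted cells,
# pre/post-chemotherapy Mann-Whitney comparisons, lymphoid/myeloid ratio.

library(immunax)

cells <- readr::read_tsv("results/qc/cells.tsv", show_col_types = FALSE)

ct_all <- compose_fractions(cells, "all_cells")
ct_imm <- compose_fractions(cells, "immune_cells")

dir.create("results/composition", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(ct_all, "results/composition/fractions_all.tsv")
readr::write_tsv(ct_imm, "results/composition/fractions_immune.tsv")

cmp <- dplyr::bind_rows(lapply(unique(ct_all$population), function(p) {
  r <- compare_pre_post(ct_all, p)
  tibble::tibble(population = p, U = r$U, p_value = r$p_value,
                 median_pre = r$median_pre, median_post = r$median_post)
}))
readr::write_tsv(cmp, "results/composition/pre_post_tests.tsv")

lm_ratio <- lymphoid_myeloid_ratio(ct_imm)
readr::write_tsv(lm_ratio, "results/composition/lymphoid_myeloid_ratio.tsv")

cat("pre/post composition shifts (fraction of all unbiased cells):\n")
print(as.data.frame(cmp[order(cmp$p_value), ][1:4, ]), row.names = FALSE)
cat(sprintf("median lymphoid/myeloid ratio pre %.2f vs post %.2f\n",
            median(lm_ratio$ratio[lm_ratio$timepoint == "pre"], na.rm = TRUE),
            median(lm_ratio$ratio[lm_ratio$timepoint == "post"], na.rm = TRUE)))
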