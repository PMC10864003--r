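# immunax

Discovery of therapeutically targetable immunoregulatory ligand–receptor
axes — the kind of analysis that nominates NECTIN2–TIGIT as an immune
checkpoint in a pediatric solid tumor — from annotated plate-based
single-cell RNA-seq count data.

Tumor-infiltrating T and NK cells are suppressed by their neighbors. Given a
gene×cell count matrix with population labels, a curated ligand–receptor
pair database, and a membrane/secreted localization table, `immunax` runs
the full chain:

1. **QC** — plate-wise liveness thresholds calibrated on deliberately empty
   wells (floor 500 transcripts), protein-coding/genomic read-ratio purity
   filter (GPratio < 20 removed), mitochondrial-dominance removal,
   1,000–150,000 nuclear-transcript and 500-gene bounds, pseudogene and
   low-expression gene filters — with a per-rule audit that sums exactly.
2. **Scoring** — log1p CP10K normalization; binned-control module scores
   (score of a cell = mean expression of signature genes − mean of
   expression-matched control genes) for cytotoxicity and
   dysfunction/exhaustion panels; checkpoint receptor ratios (TIGIT/CD226);
   percent-killing utilities.
3. **Interaction inference** — CellPhoneDB-style statistic per (source
   population X, target population Y, pair): `score = mean(ligand in X) ·
   mean(receptor in Y)` (multi-subunit complexes by the limiting subunit),
   with a label-permutation null (within samples) and add-one p-values
   `p = (1 + #[null ≥ obs]) / (1 + B)`, gated on ≥10% expressing cells on
   both sides.
4. **Prioritization** — the overlay: gene B on partner X is called against
   effector Y when B is membrane/secreted, its per-sample mean expression in
   X correlates positively (Pearson, p < 0.05 across samples) with Y's
   per-sample dysfunction score, and B sits in at least one significant X→Y
   interaction.
5. **Composition** — per-sample fractions over unbiased-sorted cells,
   exact Mann–Whitney pre/post-treatment comparisons, lymphoid/myeloid
   ratios.

A negative-binomial synthetic-cohort generator (`simulate_cohort`) with
spike-ins, empty wells, a planted axis and decoy pairs makes every stage
testable end to end without any data download.

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on a
simulated 24-sample cohort (10 pre-, 14 post-chemotherapy, ~6,900 wells,
1,200 genes, one planted NECTIN2→TIGIT axis among 50 decoys) and write all
tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # cohort + LR database + localization + truth
Rscript analysis/02_qc.R          # QC audit and filtered matrix
Rscript analysis/03_scoring.R     # module scores, receptor ratios
Rscript analysis/04_interactions.R
Rscript analysis/05_prioritize.R  # the overlay -> targets.tsv
Rscript analysis/06_composition.R
```

Highlights of what they print:

```
mean dysfunction score by population (top 4):
  population   signature mean_score
       CD8_T dysfunction  0.8139132
 CD4_T_DUSP4 dysfunction  0.8032883
  CD4_T_TPT1 dysfunction  0.2364735
        Treg dysfunction  0.2130885

47 of 1020 (source, target, pair) tests significant

3 rows called; top nominations:
 population_x    gene  effector_y pearson_r       corr_p
   macrophage NECTIN2       CD8_T 0.9156536 3.571544e-10
   macrophage   LG006 CD4_T_DUSP4 0.6754237 2.927793e-04
   CD4_T_TPT1 NECTIN2 CD4_T_DUSP4 0.5039756 4.653802e-02

pre/post composition shifts (fraction of all unbiased cells):
 population   U      p_value median_pre median_post
 mesenchyme   0 8.693824e-05 0.11135464  0.46862444
      tumor 120 8.693824e-05 0.47411620  0.02670657
```

The dysfunction score peaks in the tumor-reactive subsets (CD8 and DUSP4-hi
CD4 T cells); the planted macrophage→CD8 NECTIN2–TIGIT axis is the top
nomination, with its per-sample expression explaining CD8 dysfunction at
r = 0.92; decoy calls are rare and weak; and the cohort shows the
characteristic post-chemotherapy collapse of tumor content (47% → 3% of
cells) with mesenchymal expansion (11% → 47%), both at the exact
Mann–Whitney p = 8.7e-5.

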