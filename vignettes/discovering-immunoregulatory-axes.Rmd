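---
title: "Discovering targetable immunoregulatory axes from annotated single-cell counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering targetable immunoregulatory axes from annotated single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunax)
```

## The problem

Tumor-infiltrating T and NK cells are frequently rendered dysfunctional by
inhibitory signals from surrounding cells — myeloid populations, tumor cells,
mesenchyme, regulatory T cells. Picking the right immune-checkpoint target for
a given tumor type means finding, among hundreds of curated ligand–receptor
pairs, the few whose ligand is (i) actually expressed by a partner population
in that tumor, (ii) engaged in a statistically credible interaction with an
effector subset, and (iii) quantitatively associated with how dysfunctional
that effector subset is, sample by sample. `immunax` implements that
discovery chain for plate-based (CEL-Seq2 style) single-cell count data with
annotated populations: quality control, normalization, signature scoring,
permutation-based interaction inference, and the final correlation overlay
that nominates axes such as NECTIN2–TIGIT. Clustering and population
annotation are treated as upstream inputs, not reimplemented.

## The pipeline, stage by stage

### Quality control

Plate-based data comes with two assets droplet data lacks: ERCC spike-ins in
every well and deliberately empty wells on every plate. The QC cascade uses
them in a fixed order; a cell is attributed to its first failing rule so the
audit adds up exactly.

1. **Empty wells** are flagged outright (they can never pass).
2. **Liveness**: per plate, a threshold separates live cells from debris and
   failed reactions. The empty wells give the background total-transcript
   distribution; the threshold is `mean + 3 sd` of the empty-well totals with
   a floor of 500 transcripts. The published procedure states only that the
   threshold is computed from the empty wells with a 500 floor; the 3-sd
   outlier bound is this package's choice and is exposed in
   `qc_config(liveness_sd_mult = )`. Plates without empty wells fall back to
   the floor.
3. **GPratio**: the ratio of protein-coding to genomic (intronic) raw counts
   must be at least 20. The source procedure names this ratio
   "genomic:protein-coding" yet removes cells with a ratio *below* 20, which
   under the literal reading would discard essentially every clean cell
   (clean cells carry perhaps 2% intronic reads, a literal ratio near 0.02).
   We therefore compute protein-coding over genomic and remove cells below
   20 — low protein-coding purity — and expose the direction as
   `gp_ratio_direction` for anyone who wants the literal reading. A zero
   genomic count gives an infinite ratio and passes.
4. **Mitochondrial dominance**: strictly more mitochondrial than nuclear
   transcripts removes the cell; equality passes.
5. Spike-in and mitochondrial genes then leave the dataset.
6. **Bounds**: fewer than 1000 nuclear transcripts, fewer than 500 detected
   genes, or more than 150,000 nuclear transcripts removes the cell; all
   comparisons are strict, exactly as printed in the source thresholds, so
   boundary values pass.
7. **Gene filter** (on passing cells only): pseudogenes are removed, and a
   gene is removed when fewer than 5 cells express it or fewer than 2 cells
   carry at least two transcripts of it. The second clause of the published
   rule ("less than two cells with less than two transcripts") is
   grammatically ambiguous; we read it as "fewer than two cells with at
   least two transcripts", which is the reading that makes the clause do
   work.

The cascade is idempotent, permutation-stable in the cell order, and `run_qc`
returns the per-rule audit. Cluster-level removals (erythroid or contaminated
clusters) require clustering, which is out of scope; `drop_populations()`
accepts caller-supplied labels instead. Ambient-RNA decontamination is
likewise an upstream concern: run it before `read_counts` if needed.

### Normalization and scoring

All scoring uses log1p counts-per-10k (`normalize_cp10k_log1p`), a simple,
exactly reproducible transform. The variance-stabilizing transform used
upstream for clustering in the source study serves clustering, which this
package does not perform.

`module_score` is the standard binned-control signature score: genes are
ranked by average normalized expression and cut into `n_bins = 24`
equal-frequency bins; each signature gene draws `n_ctrl = 100` control genes
from its own bin without replacement (the whole bin when smaller); the score
is the mean of the signature genes minus the mean over the pooled control
draws, per cell. Controls are drawn once per signature under a fixed seed, so
scores are deterministic and translation-invariant. Shipped signatures:

* `cytotoxicity`: GZMA, GZMB, PRF1, GNLY, NKG7, CST7, CCL5, IFNG — the
  effector program used for NK/T killing capacity.
* `dysfunction`: PDCD1, CTLA4, LAG3, HAVCR2, TIGIT, TOX, ENTPD1 — a
  canonical inhibitory-receptor/exhaustion panel. The study this pipeline
  descends from used a curated literature signature whose full list lives in
  supplementary material; this panel is a documented stand-in and every
  scoring function accepts any gene list.

`receptor_ratio` computes checkpoint-balance statistics (e.g. TIGIT/CD226)
as ratios of group means (all cells, zeros included), per population and
sample; whether such ratios should be averaged per cell first is not
specified anywhere we know of, and the group-mean convention is the one that
matches expression-ratio semantics. `percent_killing` converts normalized
luminescence from killing assays into percent killing,
`100 * (1 - treated/control)`.

### Interaction inference

The interaction statistic is deliberately the simplest fully specifiable
convention, the CellPhoneDB-style product of means: for a pair between
source population X and target population Y,

```
score = mean_expr(ligand complex in X) * mean_expr(receptor complex in Y)
```

with multi-subunit complexes reduced by the limiting subunit (minimum of the
subunit means; the expressed fraction requires every subunit detected in a
cell). The null shuffles population labels across cells — within each sample
when several samples are present, preserving per-sample composition — and
recomputes the score; with `B` permutations the p-value is the add-one
estimator `(1 + #[null >= observed]) / (1 + B)`, so p is never below
`1/(B+1)` and is exactly uniform on its attainable values under an
exchangeable null. A call additionally requires both sides expressed in at
least 10% of their population's cells, guarding against means driven by a
handful of cells. The mass-action/Hill-kinetics model used by CellChat in
the source study is intentionally not reproduced: the downstream overlay
needs only pairwise significance, and a permutation test is exactly
reproducible and calibrated by construction.

Numerical note: null scores are compared to the observed score with a
relative tolerance of 1e-9 so that permutations reproducing the observed
grouping count as ties regardless of floating-point summation order; without
it, p-values on small instances are anti-conservative.

### Target prioritization

The overlay asks, for every gene B expressed by partner population X and
effector subset Y: does B's per-sample mean expression in X correlate with
Y's per-sample mean dysfunction score? A target is called when

1. B is annotated membrane-expressed or secreted (therapeutic
   accessibility; unlisted genes count as `other` and are never called),
2. the Pearson correlation across common samples is significant at 0.05
   with r > 0 (the positive direction is the default for
   dysfunction-promoting partners; `direction = "negative"` serves
   cytotoxicity-suppression analyses), and
3. B sits on the ligand side of at least one significant X→Y interaction
   (`side = "either"` widens this; whether the source analysis required the
   ligand side specifically is not stated).

Correlations are computed across samples on population means (at least 5
cells per sample, at least 5 samples) because the per-tumor aggregation is
what bulk-cohort validation can confirm. P-values are used unadjusted at
0.05, matching the source procedure; Benjamini–Hochberg is available via
`p_adjust = "BH"`. Ranking puts called rows first by descending r, ties by
ascending p then gene name.

### Composition

`compose_fractions` counts only unbiased-sorted, QC-passing cells; samples
with fewer than 10 immune cells are excluded from immune-denominator
analyses. Pre/post-treatment comparisons use the two-sided Mann–Whitney
test, exact when both arms have at most 8 tie-free samples (cohorts of this
size demand exactness), normal approximation with tie correction otherwise.
The mixed-effects composition modeling of the source study is out of scope.

## The synthetic cohort

`simulate_cohort` generates the data every stage is tested on. What it
emulates, and its defaults, are the study conditions of the cohort the
pipeline descends from:

* 24 samples (10 pre-, 14 post-chemotherapy), one 384-well-style plate per
  sample, 8 empty wells per plate, 20 spike-in genes contributing ~200
  transcripts to every well.
* Twelve populations (tumor, mesenchyme, endothelium, three myeloid, six
  lymphoid) whose expected per-sample abundances reproduce the printed
  compositional shift: tumor ~47% of cells before treatment and ~3% after,
  mesenchyme ~11% before and ~49% after. Per-population frequencies in real
  cohorts vary widely; these are round numbers, not fitted values.
* Gene-wise negative-binomial counts: lognormal baseline means scaled to
  ~6,000 endogenous transcripts per cell, dispersion 0.4, per-cell
  library-size factors lognormal with sdlog 0.35, marker genes 8-fold
  enriched in their population, ~2% genomic-class and ~5% mitochondrial
  reads, low-expressed pseudogenes. Empty wells receive Poisson(0.5) total
  endogenous leakage plus full spike-ins, so the liveness threshold must
  separate them.
* One planted axis (default NECTIN2 on macrophages → TIGIT on CD8 T): both
  genes 8-fold co-expressed in their populations, and each sample's
  dysfunction-gene means in the target subset multiplied by
  `exp(0.5 z + 0.375 eps)` where `z` is the sample's standardized latent
  ligand abundance (which also scales the ligand in the source, sdlog 0.5)
  and `eps` is independent noise — a latent per-sample correlation of
  exactly `0.5 / sqrt(0.25 + 0.375^2) = 0.8`, attenuated to roughly 0.75 in
  realized data by finite cells per sample. Fifty decoy pairs have no
  planted structure.
* One RNG stream per generation stage, derived from the master seed, so
  output is byte-identical under a fixed seed.

What it does **not** emulate: doublets, batch effects beyond the plate
label, cell-cycle structure, ambient contamination gradients, or realistic
gene–gene correlation beyond the planted axis. Passing tests on this
generator therefore demonstrate that the statistics recover exactly the
structure they are defined to recover at realistic noise levels — not that
the pipeline is robust to every artifact of real plates.

## Benchmarks the package runs on itself

Three evaluation helpers re-run the pipeline at fixed problem sizes chosen
so each completes in about a minute on one core:

* `evaluate_permutation_calibration()`: seven exchangeable populations
  (identical means, no markers, no axes), 50 pairs scored between every
  ordered population pair with 999 permutations each (2,100 tests); the
  fraction of p < 0.05 must sit in the binomial band around the estimator's
  attainable mass (49/1000).
* `evaluate_recovery()`: twenty cohorts of 20 samples and 300 genes with
  the default planted axis among 50 decoys, interactions at 200
  permutations; reports how often the planted axis is called and ranked
  first by r among the pair genes of its source→effector overlay (and,
  separately, across all partner–effector overlays). QC is skipped in these
  runs — the generator emits clean cells and QC has its own constructed
  fixture (`make_qc_fixture`) with a hand-computable per-rule audit.
* `evaluate_null_calls()`: the same cohorts with no planted effects; the
  fraction of called rows stays an order of magnitude below the nominal
  alpha because the localization, direction and interaction gates compound.

The `analysis/` scripts run the same pipeline once at full size (1,200
genes, ~280 cells per sample, 1,000 permutations, QC included) and write
every table under `results/`.

## Known limitations

* Population labels are trusted as given; mislabeling propagates directly
  into interaction and overlay results.
* The product-of-means statistic shares CellPhoneDB's insensitivity to
  within-population heterogeneity; a bimodal ligand can score identically
  to a uniform one.
* Correlation across ~20 samples has limited power and the unadjusted 0.05
  gate is liberal by design (fidelity to the source procedure); use
  `p_adjust = "BH"` for conservative lists.
* The dysfunction signature is a stand-in panel; conclusions about specific
  genes that are also signature members (e.g. TIGIT) deserve a sensitivity
  check with the gene removed from the signature.
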