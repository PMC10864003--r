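#' Configuration for the plate-based QC cascade
#'
#' Thresholds follow the published filtering rules for CEL-Seq2 data: a
#' per-plate liveness threshold with a floor of 500 total transcripts,
#' removal of cells with a protein-coding/genomic read ratio (GPratio)
#' below 20, removal of cells dominated by mitochondrial transcripts,
#' nuclear-transcript bounds of 1000 to 150000 and a 500 detected-gene
#' minimum, and removal of pseudogenes and lowly expressed genes.
#'
#' @param liveness_min_transcripts floor of the per-plate liveness threshold
#'   (total transcripts, spike-ins included).
#' @param liveness_sd_mult empty-well outlier bound: threshold =
#'   `max(floor, mean(empty totals) + liveness_sd_mult * sd(empty totals))`.
#' @param gp_ratio_cutoff cells below this ratio are removed.
#' @param gp_ratio_direction `"protein_over_genomic"` (default) computes
#'   protein-coding / genomic; `"genomic_over_protein"` the reciprocal.
#' @param min_nuclear_transcripts,max_nuclear_transcripts inclusive bounds on
#'   nuclear (non-mitochondrial, non-spike-in) transcripts.
#' @param min_genes minimum detected genes per cell.
#' @param gene_min_cells_expressing gene kept only if at least this many
#'   passing cells express it.
#' @param gene_min_cells_ge2 gene kept only if at least this many passing
#'   cells have >= 2 transcripts of it.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(liveness_min_transcripts = 500, liveness_sd_mult = 3,
                      gp_ratio_cutoff = 20,
                      gp_ratio_direction = c("protein_over_genomic",
                                             "genomic_over_protein"),
                      min_nuclear_transcripts = 1000, min_genes = 500,
                      max_nuclear_transcripts = 150000,
                      gene_min_cells_expressing = 5, gene_min_cells_ge2 = 2) {
  gp_ratio_direction <- match.arg(gp_ratio_direction)
  assert_that(min_nuclear_transcripts < max_nuclear_transcripts,
              "min_nuclear_transcripts must be below max_nuclear_transcripts")
  assert_that(all(c(liveness_min_transcripts, gp_ratio_cutoff,
                    min_nuclear_transcripts, min_genes,
                    max_nuclear_transcripts) > 0),
              "QC thresholds must be positive")
  structure(list(liveness_min_transcripts = liveness_min_transcripts,
                 liveness_sd_mult = liveness_sd_mult,
                 gp_ratio_cutoff = gp_ratio_cutoff,
                 gp_ratio_direction = gp_ratio_direction,
                 min_nuclear_transcripts = min_nuclear_transcripts,
                 min_genes = min_genes,
                 max_nuclear_transcripts = max_nuclear_transcripts,
                 gene_min_cells_expressing = gene_min_cells_expressing,
                 gene_min_cells_ge2 = gene_min_cells_ge2),
            class = "qc_config")
}

class_colsums <- function(cm, classes, negate = FALSE) {
  sel <- cm$genes$class %in% classes
  if (negate) sel <- !sel
  if (!any(sel)) return(numeric(ncol(cm$counts)))
  Matrix::colSums(cm$counts[sel, , drop = FALSE])
}

# mark currently-passing cells failing `bad` with `reason`
fail_cells <- function(cells, bad, reason) {
  hit <- cells$qc_pass & bad
  cells$qc_pass[hit] <- FALSE
  cells$qc_reason[hit] <- reason
  cells
}

#' Per-plate liveness threshold on empty wells
#'
#' For each plate the deliberately empty wells give the background
#' (ambient + spike-in) transcript distribution; the liveness threshold is
#' `max(floor, mean + k * sd)` of the empty-well totals (sd taken as 0 for a
#' single empty well), with the configured floor. Plates without empty wells
#' fall back to the floor. Cells whose total transcripts (all genes,
#' spike-ins included) fall below their plate threshold are flagged with
#' reason `"liveness"`. Empty wells themselves are flagged `"empty_well"`.
#'
#' @param cm a [count_matrix()].
#' @param cfg a [qc_config()].
#' @return The updated cell table.
#' @export
liveness_filter <- function(cm, cfg = qc_config()) {
  cells <- cm$cells
  assert_that(nrow(cells) > 0, "count matrix has no cells")
  totals <- Matrix::colSums(cm$counts)
  cells <- fail_cells(cells, cells$sort_gate == "empty_well", "empty_well")
  thr <- vapply(split(seq_len(nrow(cells)), cells$plate_id), function(idx) {
    et <- totals[idx][cells$sort_gate[idx] == "empty_well"]
    if (length(et) == 0) return(cfg$liveness_min_transcripts)
    s <- if (length(et) > 1) sd(et) else 0
    max(cfg$liveness_min_transcripts, mean(et) + cfg$liveness_sd_mult * s)
  }, numeric(1))
  bad <- cells$sort_gate != "empty_well" & totals < thr[cells$plate_id]
  fail_cells(cells, bad, "liveness")
}

#' Protein-coding vs genomic read-ratio purity filter
#'
#' GPratio on raw counts; with the default direction a cell is removed when
#' protein-coding / genomic < cutoff (low protein-coding purity). A zero
#' denominator gives an infinite ratio, which passes.
#'
#' @inheritParams liveness_filter
#' @param cells cell table carrying QC state (defaults to `cm$cells`).
#' @return Updated cell table; failing cells get reason `"gp_ratio"`.
#' @export
gp_ratio_filter <- function(cm, cells = cm$cells, cfg = qc_config()) {
  pc <- class_colsums(cm, "protein_coding")
  gen <- class_colsums(cm, "genomic")
  ratio <- if (cfg$gp_ratio_direction == "protein_over_genomic") pc / gen else gen / pc
  ratio[is.nan(ratio)] <- Inf  # 0/0: no reads of either class, let bounds decide
  fail_cells(cells, ratio < cfg$gp_ratio_cutoff, "gp_ratio")
}

#' Mitochondrial-dominance filter
#'
#' Removes cells with strictly more mitochondrial-encoded transcripts than
#' nuclear (non-mitochondrial, non-spike-in) ones; equality passes.
#'
#' @inheritParams gp_ratio_filter
#' @return Updated cell table; failing cells get reason `"mito_dominant"`.
#' @export
mito_filter <- function(cm, cells = cm$cells) {
  mito <- class_colsums(cm, "mitochondrial")
  nuclear <- class_colsums(cm, c("mitochondrial", "spike_in"), negate = TRUE)
  fail_cells(cells, mito > nuclear, "mito_dominant")
}

#' Nuclear transcript and detected-gene bounds
#'
#' Removes cells with fewer than `min_nuclear_transcripts` nuclear
#' transcripts, fewer than `min_genes` detected genes, or more than
#' `max_nuclear_transcripts` nuclear transcripts (first matching reason:
#' `"low_transcripts"`, `"low_genes"`, `"high_transcripts"`). Boundary values
#' pass (comparisons are strict, as published). Nuclear totals and detected
#' genes are computed over non-mitochondrial, non-spike-in genes.
#'
#' @inheritParams gp_ratio_filter
#' @return Updated cell table.
#' @export
transcript_gene_bounds <- function(cm, cells = cm$cells, cfg = qc_config()) {
  sel <- !(cm$genes$class %in% c("mitochondrial", "spike_in"))
  sub <- cm$counts[sel, , drop = FALSE]
  nuclear <- Matrix::colSums(sub)
  ngene <- Matrix::colSums(sub > 0)
  cells <- fail_cells(cells, nuclear < cfg$min_nuclear_transcripts, "low_transcripts")
  cells <- fail_cells(cells, ngene < cfg$min_genes, "low_genes")
  fail_cells(cells, nuclear > cfg$max_nuclear_transcripts, "high_transcripts")
}

#' Gene-level filter
#'
#' Removes spike-in and mitochondrial genes unconditionally, pseudogenes, and
#' lowly expressed genes: a gene is removed when fewer than
#' `gene_min_cells_expressing` passing cells express it, or fewer than
#' `gene_min_cells_ge2` passing cells carry at least two transcripts of it.
#' Counts are evaluated on QC-passing cells only.
#'
#' @inheritParams gp_ratio_filter
#' @return List with `matrix` (gene-filtered [count_matrix()], all cells
#'   retained) and `gene_removals` (tibble `reason`, `n_removed`).
#' @export
gene_filter <- function(cm, cells = cm$cells, cfg = qc_config()) {
  pass_idx <- which(cells$qc_pass)
  sub <- cm$counts[, pass_idx, drop = FALSE]
  n_expr <- Matrix::rowSums(sub > 0)
  n_ge2 <- Matrix::rowSums(sub >= 2)
  cls <- cm$genes$class
  reason <- rep(NA_character_, nrow(cm$genes))
  reason[n_expr < cfg$gene_min_cells_expressing |
           n_ge2 < cfg$gene_min_cells_ge2] <- "low_expression"
  reason[cls == "pseudogene"] <- "pseudogene"
  reason[cls == "mitochondrial"] <- "mitochondrial"
  reason[cls == "spike_in"] <- "spike_in"
  keep <- is.na(reason)
  removals <- tibble::tibble(reason = c("spike_in", "mitochondrial",
                                        "pseudogene", "low_expression"))
  removals$n_removed <- vapply(removals$reason,
                               function(r) sum(reason == r, na.rm = TRUE), 0L,
                               USE.NAMES = FALSE)
  out <- count_matrix(cm$counts[keep, , drop = FALSE],
                      cm$genes[keep, , drop = FALSE], cells)
  list(matrix = out, gene_removals = removals)
}

#' Run the full QC cascade with a per-rule audit
#'
#' Applies, in fixed order: empty-well flagging and per-plate liveness,
#' GPratio, mitochondrial dominance, spike-in/mitochondrial gene removal,
#' nuclear transcript/gene bounds, then the gene-level filter (computed on
#' passing cells). Each removed cell is attributed to its first failing rule.
#'
#' @param cm a [count_matrix()].
#' @param cfg a [qc_config()].
#' @return List of class `qc_result`: `matrix` (passing cells and retained
#'   genes only), `cells` (full input cell table with `qc_pass`/`qc_reason`),
#'   and `report` (list with `cell_removals`, `gene_removals`, `n_cells_in`,
#'   `n_cells_out`, `n_genes_in`, `n_genes_out`).
#' @export
run_qc <- function(cm, cfg = qc_config()) {
  assert_that(is_count_matrix(cm), "cm must be a count_matrix")
  cells <- cm$cells
  cells$qc_pass <- TRUE
  cells$qc_reason <- ""
  cm2 <- cm; cm2$cells <- cells
  cells <- liveness_filter(cm2, cfg)
  cells <- gp_ratio_filter(cm, cells, cfg)
  cells <- mito_filter(cm, cells)
  # spike-in and mitochondrial transcripts leave the dataset here; the
  # remaining rules see nuclear genes only
  nuc <- !(cm$genes$class %in% c("mitochondrial", "spike_in"))
  cm_nuc <- count_matrix(cm$counts[nuc, , drop = FALSE],
                         cm$genes[nuc, , drop = FALSE], cells)
  cells <- transcript_gene_bounds(cm_nuc, cells, cfg)
  gf <- gene_filter(cm, cells, cfg)
  rules <- c("empty_well", "liveness", "gp_ratio", "mito_dominant",
             "low_transcripts", "low_genes", "high_transcripts")
  cell_removals <- tibble::tibble(
    rule = rules,
    n_removed = vapply(rules, function(r) sum(cells$qc_reason == r), 0L,
                       USE.NAMES = FALSE))
  keep_cells <- which(cells$qc_pass)
  out <- gf$matrix
  out <- count_matrix(out$counts[, keep_cells, drop = FALSE],
                      out$genes, cells[keep_cells, , drop = FALSE])
  report <- list(cell_removals = cell_removals,
                 gene_removals = gf$gene_removals,
                 n_cells_in = nrow(cells), n_cells_out = length(keep_cells),
                 n_genes_in = nrow(cm$genes), n_genes_out = nrow(out$genes))
  structure(list(matrix = out, cells = cells, report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<qc_result> cells %d -> %d, genes %d -> %d\n",
              r$n_cells_in, r$n_cells_out, r$n_genes_in, r$n_genes_out))
  print(r$cell_removals)
  invisible(x)
}

#' Drop caller-specified populations
#'
#' Convenience for label-driven exclusions decided upstream (for example a
#' contaminated or erythroid cluster identified by clustering, which this
#' pipeline does not perform): flags all cells of the given populations as
#' failing with reason `"dropped_population"` and removes them from the
#' matrix.
#'
#' @param cm a [count_matrix()].
#' @param labels population labels to drop.
#' @return A [count_matrix()] without those cells.
#' @export
drop_populations <- function(cm, labels) {
  cells <- fail_cells(cm$cells, cm$cells$population %in% labels,
                      "dropped_population")
  keep <- cells$qc_reason != "dropped_population"
  count_matrix(cm$counts[, keep, drop = FALSE], cm$genes, cells[keep, , drop = FALSE])
}
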