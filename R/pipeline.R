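#' Run the full discovery pipeline on a synthetic or supplied cohort
#'
#' Orchestrates simulate (or ingest) -> QC -> normalize -> dysfunction
#' scoring -> permutation interaction scoring -> target prioritization ->
#' composition, with one master seed and a manifest of per-stage counts.
#'
#' @param sim a [sim_config()], or a pre-built list with elements `matrix`,
#'   `lr`, `localization` (e.g. from [simulate_cohort()] or [read_counts()]
#'   plus [read_lr_database()]).
#' @param qc_cfg a [qc_config()], or `NULL` to skip QC (for data already
#'   filtered upstream).
#' @param int_cfg an [interaction_config()]; its seed defaults to the master
#'   seed.
#' @param partners partner population labels scored as interaction sources
#'   (default: every non-effector population with enough cells).
#' @param effectors effector subset labels (receiving side).
#' @param dysfunction_genes signature used for the dysfunction score.
#' @param seed master seed for scoring and permutations.
#' @param min_cells,min_samples aggregation thresholds for the per-sample
#'   correlation step.
#' @param ... passed to [overlay_targets()] via [prioritize_targets()].
#' @return List of class `pipeline_result`: `data` (simulated/supplied
#'   inputs), `qc` (qc_result or NULL), `nm`, `scores`, `interactions`,
#'   `targets`, `composition`, `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), qc_cfg = qc_config(),
                         int_cfg = NULL, partners = NULL,
                         effectors = c("CD8_T", "CD4_T_DUSP4"),
                         dysfunction_genes = default_signatures()$dysfunction,
                         seed = NULL, min_cells = 5, min_samples = 5, ...) {
  if (inherits(sim, "sim_config")) {
    seed <- seed %||% sim$seed
    data <- simulate_cohort(sim)
  } else {
    seed <- seed %||% 1
    data <- sim
  }
  if (is.null(int_cfg)) int_cfg <- interaction_config(seed = seed)

  if (!is.null(qc_cfg)) {
    qc <- run_qc(data$matrix, qc_cfg)
    cm <- qc$matrix
  } else {
    qc <- NULL
    cm <- data$matrix
    keep <- cm$cells$qc_pass
    cm <- count_matrix(cm$counts[, keep, drop = FALSE], cm$genes,
                       cm$cells[keep, , drop = FALSE])
  }
  nm <- normalize_cp10k_log1p(cm)
  cells <- cm$cells

  scores <- module_score(nm, dysfunction_genes, name = "dysfunction",
                         seed = seed)

  pop_n <- table(cells$population)
  if (is.null(partners)) {
    partners <- setdiff(names(pop_n)[pop_n >= int_cfg$min_cells],
                        c(effectors, "unassigned"))
  }
  interactions <- score_interactions(nm, cells, data$lr, int_cfg,
                                     sources = partners, targets = effectors)
  targets <- prioritize_targets(nm, cells, scores, interactions, data$lr,
                                data$localization, partners, effectors,
                                genes = unique(unlist(data$lr$ligand)),
                                min_cells = min_cells,
                                min_samples = min_samples, ...)
  composition <- compose_fractions(cells, "all_cells")

  manifest <- list(
    seed = seed,
    n_cells_in = nrow(data$matrix$cells),
    n_cells_analyzed = nrow(cells),
    n_genes_analyzed = nrow(cm$genes),
    n_pairs_tested = nrow(data$lr),
    n_interaction_rows = nrow(interactions),
    n_targets_called = sum(targets$call),
    qc = if (!is.null(qc)) qc$report else NULL)
  structure(list(data = data, qc = qc, nm = nm, scores = scores,
                 interactions = interactions, targets = targets,
                 composition = composition, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pipeline_result> seed %s: %d cells in, %d analyzed, %d genes, %d pairs, %d targets called\n",
              m$seed, m$n_cells_in, m$n_cells_analyzed, m$n_genes_analyzed,
              m$n_pairs_tested, m$n_targets_called))
  invisible(x)
}
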