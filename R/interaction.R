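#' Configuration for ligand-receptor interaction scoring
#'
#' @param min_expressing_fraction both sides of a pair must be expressed in
#'   at least this fraction of their population's cells for a call.
#' @param n_permutations label permutations for the null (>= 100).
#' @param aggregation interaction statistic; `"product_of_means"` only.
#' @param complex_rule multi-subunit convention; `"min_subunit"` only
#'   (limiting-subunit: complex mean = min over subunit means).
#' @param min_cells minimum cells per named population.
#' @param alpha significance level on the permutation p-value.
#' @param seed RNG seed for the permutations.
#' @return A list of class `interaction_config`.
#' @export
interaction_config <- function(min_expressing_fraction = 0.10,
                               n_permutations = 1000,
                               aggregation = "product_of_means",
                               complex_rule = "min_subunit",
                               min_cells = 10, alpha = 0.05, seed = 1) {
  assert_that(min_expressing_fraction > 0 && min_expressing_fraction < 1,
              "min_expressing_fraction must be in (0, 1)")
  assert_that(n_permutations >= 100, "n_permutations must be >= 100")
  aggregation <- match.arg(aggregation)
  complex_rule <- match.arg(complex_rule)
  structure(list(min_expressing_fraction = min_expressing_fraction,
                 n_permutations = n_permutations, aggregation = aggregation,
                 complex_rule = complex_rule, min_cells = min_cells,
                 alpha = alpha, seed = seed),
            class = "interaction_config")
}

#' Complex expression summary within a population
#'
#' Limiting-subunit convention: the complex mean is the minimum over subunit
#' population means; the expressing fraction is the fraction of cells with
#' every subunit detected. A complex with any subunit absent from the matrix
#' is unexpressed (mean 0, fraction 0).
#'
#' @param nm normalized matrix.
#' @param cell_idx column indices (or names) of the population's cells.
#' @param complex character vector of subunit gene symbols.
#' @return List with `mean` and `expressing_fraction`.
#' @export
complex_expression <- function(nm, cell_idx, complex) {
  assert_that(length(cell_idx) > 0, "empty population")
  if (!all(complex %in% rownames(nm))) {
    return(list(mean = 0, expressing_fraction = 0))
  }
  sub <- nm[complex, cell_idx, drop = FALSE]
  m <- min(Matrix::rowMeans(sub))
  frac <- mean(Matrix::colSums(sub > 0) == length(complex))
  list(mean = m, expressing_fraction = frac)
}

# permute labels, within sample blocks when >1 sample is present
permute_within <- function(n, blocks) {
  idx <- seq_len(n)
  if (is.null(blocks) || length(unique(blocks)) <= 1) return(sample(idx))
  for (b in split(seq_len(n), blocks)) idx[b] <- b[sample.int(length(b))]
  idx
}

#' Permutation-null ligand-receptor interaction scoring
#'
#' For every (source population, target population, pair), the interaction
#' score is ligand mean in the source times receptor mean in the target
#' (complex means per the limiting-subunit rule), on normalized expression.
#' The null distribution is built by shuffling population labels across all
#' cells jointly (within each sample when several samples are present,
#' preserving sample composition) and recomputing the score; the p-value uses
#' the add-one estimator `p = (1 + #[null >= observed]) / (1 + B)`, so
#' `p >= 1/(B+1)` always. A pair whose ligand or receptor is absent from the
#' matrix scores 0 with p = 1. A call is significant when p < alpha and both
#' expressed fractions reach the configured threshold.
#'
#' @param nm normalized matrix.
#' @param cells cell table matching `colnames(nm)`.
#' @param db an [lr_database()].
#' @param cfg an [interaction_config()].
#' @param sources,targets population labels to score as sender / receiver.
#' @return Tibble of class `interaction_result`: `source`, `target`,
#'   `pair_id`, `ligand_mean`, `receptor_mean`, `score`, `p_value`,
#'   `expr_frac_ligand`, `expr_frac_receptor`, `significant`.
#' @export
score_interactions <- function(nm, cells, db, cfg = interaction_config(),
                               sources, targets) {
  cells <- cells[match(colnames(nm), cells$cell_id), ]
  pops <- unique(c(sources, targets))
  missing_pop <- setdiff(pops, unique(cells$population))
  assert_that(length(missing_pop) == 0,
              paste("unknown population:", paste(missing_pop, collapse = ", ")))
  pop_cells <- lapply(setNames(pops, pops),
                      function(p) which(cells$population == p))
  small <- pops[vapply(pop_cells, length, 0L) < cfg$min_cells]
  assert_that(length(small) == 0,
              paste("populations below min_cells:", paste(small, collapse = ", ")))

  subunits <- unique(unlist(c(db$ligand, db$receptor)))
  present <- intersect(subunits, rownames(nm))
  expr <- as.matrix(nm[present, , drop = FALSE])

  # observed complex summaries: population means and expressed fractions of
  # every involved gene in one pass, then complex reduction per pair
  obs_mean <- vapply(pops, function(p) rowMeans(expr[, pop_cells[[p]], drop = FALSE]),
                     numeric(length(present)))
  obs_frac <- vapply(pops, function(p) rowMeans(expr[, pop_cells[[p]], drop = FALSE] > 0),
                     numeric(length(present)))
  rownames(obs_mean) <- rownames(obs_frac) <- present
  obs_summary <- function(pop, complex) {
    if (!all(complex %in% present)) return(c(0, 0))
    if (length(complex) == 1) {
      c(obs_mean[complex, pop], obs_frac[complex, pop])
    } else {
      sub <- expr[complex, pop_cells[[pop]], drop = FALSE]
      c(min(obs_mean[complex, pop]), mean(colSums(sub > 0) == length(complex)))
    }
  }
  grid <- expand.grid(source = sources, target = targets,
                      pair = seq_len(nrow(db)), stringsAsFactors = FALSE)
  lig <- mapply(function(s, k) unname(obs_summary(s, db$ligand[[k]])),
                grid$source, grid$pair, USE.NAMES = FALSE)
  rec <- mapply(function(t, k) unname(obs_summary(t, db$receptor[[k]])),
                grid$target, grid$pair, USE.NAMES = FALSE)
  res <- tibble::tibble(
    source = grid$source, target = grid$target,
    pair_id = db$pair_id[grid$pair],
    ligand_mean = lig[1, ], receptor_mean = rec[1, ],
    expr_frac_ligand = lig[2, ], expr_frac_receptor = rec[2, ])
  res$score <- res$ligand_mean * res$receptor_mean

  # null: permuted population means of all involved subunits, via sparse
  # indicator products so every permutation is one matrix multiply
  B <- cfg$n_permutations
  n <- ncol(nm)
  npop <- length(pops)
  pop_n <- vapply(pop_cells, length, 0L)
  pop_of <- match(cells$population, pops)  # NA for uninvolved populations
  blocks <- if (!is.null(cells$sample_id)) cells$sample_id else NULL
  exceed <- numeric(nrow(res))
  # null means of every pair's complex within one population: pairs x perms
  complex_mat <- function(M, complexes) {
    t(vapply(complexes, function(cx) {
      if (!all(cx %in% present)) return(numeric(ncol(M)))
      if (length(cx) == 1) M[cx, ] else
        do.call(pmin, lapply(cx, function(g) M[g, ]))
    }, numeric(ncol(M))))
  }
  with_stage_seed(cfg$seed, "interaction_null", {
    chunk <- 200L
    done <- 0L
    while (done < B) {
      b <- min(chunk, B - done)
      # indicator: cells x (perm, pop) with 1/n_pop weights -> group means
      trip <- lapply(seq_len(b), function(k) {
        perm <- permute_within(n, blocks)
        po <- pop_of[perm]  # population of each cell after shuffling
        keep <- which(!is.na(po))
        list(i = keep, j = (k - 1L) * npop + po[keep], x = 1 / pop_n[po[keep]])
      })
      ind <- Matrix::sparseMatrix(
        i = unlist(lapply(trip, `[[`, "i")),
        j = unlist(lapply(trip, `[[`, "j")),
        x = unlist(lapply(trip, `[[`, "x")),
        dims = c(n, b * npop))
      means <- as.matrix(expr %*% ind)  # present genes x (perm, pop)
      rownames(means) <- present
      by_pop <- lapply(seq_len(npop), function(si) {
        means[, (seq_len(b) - 1L) * npop + si, drop = FALSE]
      })
      lig_mat <- lapply(by_pop, complex_mat, complexes = db$ligand)
      rec_mat <- lapply(by_pop, complex_mat, complexes = db$receptor)
      pair_k <- match(res$pair_id, db$pair_id)
      grp <- split(seq_len(nrow(res)),
                   list(match(res$source, pops), match(res$target, pops)))
      for (g in grp) {
        if (length(g) == 0) next
        si <- match(res$source[g[1]], pops); ti <- match(res$target[g[1]], pops)
        null_sc <- lig_mat[[si]][pair_k[g], , drop = FALSE] *
          rec_mat[[ti]][pair_k[g], , drop = FALSE]
        # tolerance so permutations reproducing the observed grouping count
        # as ties despite floating-point summation order
        thr <- res$score[g] - 1e-9 * (1 + abs(res$score[g]))
        exceed[g] <- exceed[g] + rowSums(null_sc >= thr)
      }
      done <- done + b
    }
  })
  res$p_value <- (1 + exceed) / (1 + B)
  # absent ligand or receptor: score 0 by convention, p fixed at 1
  absent <- res$score == 0 &
    (res$expr_frac_ligand == 0 | res$expr_frac_receptor == 0)
  res$p_value[absent] <- 1
  res$significant <- res$p_value < cfg$alpha &
    res$expr_frac_ligand >= cfg$min_expressing_fraction &
    res$expr_frac_receptor >= cfg$min_expressing_fraction
  res <- res[, c("source", "target", "pair_id", "ligand_mean",
                 "receptor_mean", "score", "p_value", "expr_frac_ligand",
                 "expr_frac_receptor", "significant")]
  class(res) <- c("interaction_result", class(res))
  res
}

#' Keep the strongest source per (pair, target)
#'
#' Collapses an interaction table to one row per (pair, target): the row with
#' the maximal score among sources (ties broken by source label), mirroring
#' "highest probability per interaction" summaries.
#'
#' @param res an `interaction_result` tibble.
#' @return The collapsed tibble.
#' @export
merge_max_probability <- function(res) {
  assert_that(nrow(res) > 0, "empty interaction result")
  res <- dplyr::arrange(res, .data$pair_id, .data$target,
                        dplyr::desc(.data$score), .data$source)
  out <- dplyr::slice_head(dplyr::group_by(res, .data$pair_id, .data$target),
                           n = 1)
  dplyr::ungroup(out)
}
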