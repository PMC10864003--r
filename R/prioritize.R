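#' Per-sample mean expression of a population
#'
#' Mean normalized expression per (sample, gene) over the cells of one
#' population. Samples contributing fewer than `min_cells` cells of the
#' population are excluded (and reported via the `excluded_samples`
#' attribute); the population must survive in at least `min_samples` samples.
#'
#' @param nm normalized matrix.
#' @param cells cell table matching `colnames(nm)`.
#' @param population population label.
#' @param min_cells minimum cells per sample.
#' @param min_samples minimum retained samples.
#' @return genes x samples numeric matrix.
#' @export
per_sample_means <- function(nm, cells, population, min_cells = 5,
                             min_samples = 5) {
  cells <- cells[match(colnames(nm), cells$cell_id), ]
  idx <- which(cells$population == population)
  assert_that(length(idx) > 0, paste("population absent:", population))
  tab <- table(cells$sample_id[idx])
  ok_samples <- names(tab)[tab >= min_cells]
  assert_that(length(ok_samples) >= min_samples,
              sprintf("population %s present with >= %d cells in only %d samples (need %d)",
                      population, min_cells, length(ok_samples), min_samples))
  out <- vapply(ok_samples, function(s) {
    Matrix::rowMeans(nm[, idx[cells$sample_id[idx] == s], drop = FALSE])
  }, numeric(nrow(nm)))
  attr(out, "excluded_samples") <- setdiff(names(tab), ok_samples)
  out
}

#' Per-sample mean dysfunction score of an effector subset
#'
#' Averages per-cell signature scores (for example the dysfunction module
#' score) over the cells of one population within each sample, excluding
#' samples with fewer than `min_cells` such cells.
#'
#' @param scores tibble from [module_score()] (`cell_id`, `score`).
#' @param cells cell table.
#' @param subset effector population label.
#' @param min_cells minimum cells per sample.
#' @return Named numeric vector (sample -> mean score).
#' @export
dysfunction_by_sample <- function(scores, cells, subset, min_cells = 5) {
  d <- dplyr::inner_join(scores, cells[, c("cell_id", "sample_id", "population")],
                         by = "cell_id")
  d <- d[d$population == subset, ]
  assert_that(nrow(d) > 0, paste("population absent:", subset))
  agg <- dplyr::summarise(dplyr::group_by(d, .data$sample_id),
                          n = dplyr::n(), score = mean(.data$score),
                          .groups = "drop")
  agg <- agg[agg$n >= min_cells, ]
  setNames(agg$score, agg$sample_id)
}

#' Overlay interaction support, localization and dysfunction correlation
#'
#' The target-nomination step: for every gene B expressed by partner
#' population X, correlate its per-sample mean expression in X with the
#' per-sample dysfunction score of effector subset Y across their common
#' samples, and call B a candidate axis when (i) it is annotated membrane or
#' secreted, (ii) the correlation is significant at `alpha` (positive under
#' the default direction), and (iii) B participates on the ligand side (by
#' default) of at least one significant X -> Y interaction.
#'
#' @param means genes x samples matrix from [per_sample_means()] for X.
#' @param dys named per-sample dysfunction scores for Y
#'   (see [dysfunction_by_sample()]).
#' @param interactions an `interaction_result` tibble.
#' @param db the [lr_database()] the interactions were scored against (used
#'   to resolve which genes belong to a pair's ligand or receptor complex).
#' @param loc localization tibble (see [read_localization()]); genes not
#'   listed count as `other`.
#' @param x,y labels of the partner population and effector subset (used to
#'   filter `interactions` and recorded in the output).
#' @param alpha significance level for the correlation.
#' @param direction `"positive"` requires r > 0 (dysfunction-promoting
#'   partners); `"negative"` requires r < 0 (e.g. cytotoxicity suppressors);
#'   `"both"` ignores the sign.
#' @param side which side of a pair B must occupy for interaction support.
#' @param p_adjust multiplicity correction applied to the correlation
#'   p-values before calling (`"none"` by default, matching unadjusted
#'   per-gene calls; `"BH"` available).
#' @param min_samples minimum common samples.
#' @return Tibble of class `target_table`: `population_x`, `gene`,
#'   `effector_y`, `pearson_r`, `corr_p`, `n_samples`, `localization`,
#'   `interaction_support` (list of pair ids), `call`.
#' @export
overlay_targets <- function(means, dys, interactions, db, loc, x, y,
                            alpha = 0.05, direction = c("positive", "negative", "both"),
                            side = c("ligand", "receptor", "either"),
                            p_adjust = "none", min_samples = 5) {
  direction <- match.arg(direction)
  side <- match.arg(side)
  common <- intersect(colnames(means), names(dys))
  assert_that(length(common) >= max(3, min_samples),
              sprintf("only %d common samples between X means and Y scores", length(common)))
  m <- means[, common, drop = FALSE]
  d <- dys[common]
  genes <- rownames(m)

  sig <- interactions[interactions$significant &
                        interactions$source == x & interactions$target == y, ]
  db_cols <- switch(side, ligand = "ligand", receptor = "receptor",
                    either = c("ligand", "receptor"))
  sig_k <- match(sig$pair_id, db$pair_id)
  support <- lapply(genes, function(g) {
    if (nrow(sig) == 0) return(character(0))
    hit <- vapply(seq_along(sig_k), function(i) {
      any(vapply(db_cols, function(cl) g %in% db[[cl]][[sig_k[i]]], logical(1)))
    }, logical(1))
    sig$pair_id[hit]
  })

  sdx <- apply(m, 1, sd)
  r <- rep(NA_real_, length(genes))
  p <- rep(NA_real_, length(genes))
  if (sd(d) > 0) {
    ok <- sdx > 0
    r[ok] <- as.numeric(cor(t(m[ok, , drop = FALSE]), d))
    df <- length(common) - 2
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  }
  p_called <- p.adjust(p, method = p_adjust)
  locl <- localization_class(loc, genes)
  dir_ok <- switch(direction, positive = r > 0, negative = r < 0,
                   both = rep(TRUE, length(r)))
  call <- locl %in% c("membrane", "secreted") &
    !is.na(p_called) & p_called < alpha &
    lengths(support) > 0 & !is.na(dir_ok) & dir_ok
  out <- tibble::tibble(
    population_x = x, gene = genes, effector_y = y,
    pearson_r = r, corr_p = p, n_samples = length(common),
    localization = locl, interaction_support = support, call = call)
  class(out) <- c("target_table", class(out))
  out
}

#' Rank nominated targets
#'
#' Called rows first, by descending Pearson r; ties broken by ascending
#' correlation p, then lexically by gene.
#'
#' @param tt a `target_table` tibble (rows may cover several X/Y pairs).
#' @return The reordered tibble.
#' @export
rank_targets <- function(tt) {
  ord <- order(!tt$call, -ifelse(is.na(tt$pearson_r), -Inf, tt$pearson_r),
               tt$corr_p, tt$gene)
  tt[ord, ]
}

#' Nominate targets across partner populations and effector subsets
#'
#' Convenience wrapper running [per_sample_means()], [dysfunction_by_sample()]
#' and [overlay_targets()] for every (partner X, effector Y) combination and
#' returning the pooled, ranked target table.
#'
#' @param nm normalized matrix.
#' @param cells cell table.
#' @param scores per-cell dysfunction scores (see [module_score()]).
#' @param interactions an `interaction_result` covering the X -> Y pairs.
#' @param loc localization tibble.
#' @param partners partner population labels (X).
#' @param effectors effector subset labels (Y).
#' @param genes optional restriction of the genes tested (default: all
#'   ligand-side genes of `interactions`' database won't be assumed — every
#'   gene in `nm` is tested).
#' @param ... passed to [overlay_targets()].
#' @inheritParams overlay_targets
#' @return A ranked `target_table`.
#' @export
prioritize_targets <- function(nm, cells, scores, interactions, db, loc,
                               partners, effectors, genes = NULL,
                               min_cells = 5, min_samples = 5, ...) {
  out <- list()
  for (x in partners) {
    means <- per_sample_means(nm, cells, x, min_cells = min_cells,
                              min_samples = min_samples)
    if (!is.null(genes)) means <- means[intersect(genes, rownames(means)), , drop = FALSE]
    for (y in effectors) {
      dys <- dysfunction_by_sample(scores, cells, y, min_cells = min_cells)
      out[[paste(x, y)]] <- overlay_targets(means, dys, interactions, db, loc,
                                            x = x, y = y,
                                            min_samples = min_samples, ...)
    }
  }
  rank_targets(dplyr::bind_rows(out))
}
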