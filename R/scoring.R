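#' Default gene signatures
#'
#' `cytotoxicity` is the effector program used to quantify NK/T killing
#' capacity (GZMA, GZMB, PRF1, GNLY, NKG7, CST7, CCL5, IFNG). `dysfunction`
#' is a canonical inhibitory-receptor/exhaustion marker panel (PDCD1, CTLA4,
#' LAG3, HAVCR2, TIGIT, TOX, ENTPD1) standing in for curated exhaustion
#' signatures from the literature; both are configurable wherever used.
#'
#' @return Named list of character vectors.
#' @export
default_signatures <- function() {
  list(cytotoxicity = c("GZMA", "GZMB", "PRF1", "GNLY", "NKG7",
                        "CST7", "CCL5", "IFNG"),
       dysfunction = c("PDCD1", "CTLA4", "LAG3", "HAVCR2",
                       "TIGIT", "TOX", "ENTPD1"))
}

#' Library-size normalization: log1p counts-per-10k
#'
#' Each cell's counts are scaled to 10,000 total and log(1 + x) transformed.
#' All-zero cells map to all-zero columns. This simple, exactly reproducible
#' transform is used for all scoring and correlation work.
#'
#' @param cm a [count_matrix()] (typically QC-passed).
#' @param scale_factor per-cell total after scaling (default 1e4).
#' @return A sparse genes x cells `dgCMatrix` with attribute
#'   `normalization = "cp10k_log1p"`; rownames are gene symbols when unique,
#'   else gene ids.
#' @export
normalize_cp10k_log1p <- function(cm, scale_factor = 1e4) {
  assert_that(is_count_matrix(cm), "cm must be a count_matrix")
  tot <- Matrix::colSums(cm$counts)
  sf <- ifelse(tot > 0, scale_factor / tot, 0)
  nm <- cm$counts %*% Matrix::Diagonal(x = sf)
  nm@x <- log1p(nm@x)
  nm <- as(nm, "CsparseMatrix")
  rn <- if (!anyDuplicated(cm$genes$symbol)) cm$genes$symbol else cm$genes$gene_id
  dimnames(nm) <- list(rn, cm$cells$cell_id)
  attr(nm, "normalization") <- "cp10k_log1p"
  nm
}

#' Per-cell gene-signature module score
#'
#' The standard binned-control scheme: genes are ranked by their average
#' normalized expression and split into `n_bins` equal-frequency bins; for
#' each signature gene, `n_ctrl` control genes are drawn from its bin without
#' replacement (the whole bin when it is smaller than `n_ctrl`). The score of
#' a cell is the mean expression of the signature genes minus the mean over
#' the pooled control draws. Deterministic under a fixed seed; controls are
#' drawn once per signature, not per cell.
#'
#' @param nm normalized matrix from [normalize_cp10k_log1p()].
#' @param genes character vector of signature genes (rownames of `nm`);
#'   symbols absent from the matrix are dropped with a warning.
#' @param name signature name recorded in the output.
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed RNG seed for the control draw.
#' @return Tibble with columns `cell_id`, `signature`, `score`.
#' @export
module_score <- function(nm, genes, name = "signature",
                         n_bins = 24, n_ctrl = 100, seed = 1) {
  present <- intersect(genes, rownames(nm))
  dropped <- setdiff(genes, present)
  if (length(dropped)) {
    warn(paste("signature genes absent from matrix:",
               paste(dropped, collapse = ", ")))
  }
  assert_that(length(present) > 0,
              "signature is empty after intersection with matrix genes")
  avg <- Matrix::rowMeans(nm)
  # equal-frequency bins on the expression rank (ties broken by row order)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk * n_bins / length(avg))
  sig_idx <- match(present, rownames(nm))
  ctrl_idx <- with_stage_seed(seed, "module_score_controls", {
    unlist(lapply(sig_idx, function(g) {
      members <- which(bin == bin[g])
      k <- min(n_ctrl, length(members))
      members[sample.int(length(members), k)]
    }))
  })
  score <- Matrix::colMeans(nm[sig_idx, , drop = FALSE]) -
    Matrix::colMeans(nm[ctrl_idx, , drop = FALSE])
  tibble::tibble(cell_id = colnames(nm), signature = name,
                 score = as.numeric(score))
}

#' Mean-expression ratio of two genes within groups
#'
#' Ratio of group-mean normalized expression of `numerator` over
#' `denominator`, with groups formed by the given cell-table columns (all
#' cells of the group enter the means, zeros included). A zero denominator
#' mean yields a missing ratio, not an error. Used for checkpoint-receptor
#' balance statistics such as TIGIT/CD226 in NK cells.
#'
#' @param nm normalized matrix.
#' @param cells cell table matching `colnames(nm)`.
#' @param numerator,denominator gene symbols (rownames of `nm`).
#' @param group_by cell-table columns defining the groups.
#' @return Tibble with the grouping columns, `n_cells`, `numerator_mean`,
#'   `denominator_mean`, `ratio`.
#' @export
receptor_ratio <- function(nm, cells, numerator, denominator,
                           group_by = c("population", "sample_id")) {
  for (g in c(numerator, denominator)) {
    assert_that(g %in% rownames(nm), paste("unknown gene:", g))
  }
  cells <- cells[match(colnames(nm), cells$cell_id), ]
  num <- as.numeric(nm[numerator, ])
  den <- as.numeric(nm[denominator, ])
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(cells[group_by], num = num, den = den),
                    dplyr::across(dplyr::all_of(group_by))),
    n_cells = dplyr::n(),
    numerator_mean = mean(num), denominator_mean = mean(den),
    ratio = ifelse(denominator_mean > 0, numerator_mean / denominator_mean,
                   NA_real_),
    .groups = "drop")
}

#' Pearson correlation of two score vectors
#'
#' Pairwise-complete Pearson correlation with the usual two-sided
#' t-distributed p-value. Constant input is flagged undefined rather than
#' raising an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `r`, `p_value`, `n`, `defined`.
#' @export
correlate_scores <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, sprintf("need at least 3 complete pairs, got %d", n))
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}

#' Percent killing from a luminescence readout
#'
#' `100 * (1 - treated / control)`: the percentage reduction of viable
#' (luciferase-expressing) tumor cells relative to the tumor-only control
#' mean.
#'
#' @param lum_treated luminescence of the treated condition (>= 0).
#' @param lum_control_mean mean luminescence of the tumor-only control (> 0).
#' @return Percent killing (may be negative if treated exceeds control).
#' @export
percent_killing <- function(lum_treated, lum_control_mean) {
  assert_that(all(lum_control_mean > 0), "control mean must be positive")
  assert_that(all(lum_treated >= 0), "treated luminescence must be non-negative")
  100 * (1 - lum_treated / lum_control_mean)
}
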