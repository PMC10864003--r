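#' Default population -> lineage map for the synthetic panel
#'
#' @return Named character vector mapping population labels to lineages
#'   (`tumor`, `mesenchyme`, `endothelium`, `myeloid`, `lymphoid`); immune
#'   cells are the union of myeloid and lymphoid.
#' @export
default_lineage_map <- function() {
  p <- default_populations()
  setNames(p$lineage, p$name)
}

#' Per-sample cellular composition
#'
#' Counts cells per (sample, population) and converts to fractions of the
#' chosen denominator. Only cells sorted with an unbiased gate and passing QC
#' are counted, so enrichment-sorted samples drop out. For immune-based
#' denominators (`immune_cells`, `myeloid`, `lymphoid`), samples with fewer
#' than `min_immune_cells` immune cells are excluded. The (sample,
#' population) grid is completed with zeros so absent populations appear
#' with fraction 0.
#'
#' @param cells cell table.
#' @param denominator one of `all_cells`, `immune_cells`, `myeloid`,
#'   `lymphoid`.
#' @param lineage_map named vector population -> lineage; see
#'   [default_lineage_map()].
#' @param min_immune_cells exclusion threshold for immune denominators.
#' @return Tibble with `sample_id`, `timepoint`, `population`, `n_cells`,
#'   `fraction`, `denominator`.
#' @export
compose_fractions <- function(cells,
                              denominator = c("all_cells", "immune_cells",
                                              "myeloid", "lymphoid"),
                              lineage_map = default_lineage_map(),
                              min_immune_cells = 10) {
  denominator <- match.arg(denominator)
  d <- cells[cells$sort_gate == "unbiased" & cells$qc_pass, ]
  assert_that(nrow(d) > 0, "no unbiased QC-passing cells")
  unmapped <- setdiff(unique(d$population), names(lineage_map))
  assert_that(length(unmapped) == 0,
              paste("populations missing from lineage map:",
                    paste(unmapped, collapse = ", ")))
  d$lineage <- unname(lineage_map[d$population])
  immune_n <- tapply(d$lineage %in% c("myeloid", "lymphoid"), d$sample_id, sum)
  if (denominator != "all_cells") {
    keep <- names(immune_n)[immune_n >= min_immune_cells]
    d <- d[d$sample_id %in% keep, ]
    d <- switch(denominator,
                immune_cells = d[d$lineage %in% c("myeloid", "lymphoid"), ],
                myeloid = d[d$lineage == "myeloid", ],
                lymphoid = d[d$lineage == "lymphoid", ])
  }
  assert_that(nrow(d) > 0,
              paste("denominator", denominator, "is empty in every sample"))
  tp <- dplyr::distinct(d[, c("sample_id", "timepoint")])
  grid <- tidyr::expand_grid(sample_id = unique(d$sample_id),
                             population = sort(unique(d$population)))
  counts <- dplyr::count(d, .data$sample_id, .data$population, name = "n_cells")
  out <- dplyr::left_join(grid, counts, by = c("sample_id", "population"))
  out$n_cells[is.na(out$n_cells)] <- 0L
  out <- dplyr::left_join(out, tp, by = "sample_id")
  out <- dplyr::mutate(dplyr::group_by(out, .data$sample_id),
                       fraction = .data$n_cells / sum(.data$n_cells))
  out <- dplyr::ungroup(out)
  out$denominator <- denominator
  out[, c("sample_id", "timepoint", "population", "n_cells", "fraction",
          "denominator")]
}

#' Pre- vs post-treatment comparison of a population's fraction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-sample fractions
#' between timepoints: exact when both arms have at most `exact_max` samples
#' and the fractions are tie-free, otherwise the normal approximation with
#' tie correction.
#'
#' @param ct composition tibble from [compose_fractions()].
#' @param population population label to compare.
#' @param exact_max largest per-arm size for the exact test.
#' @return List with `U` (statistic for the pre arm), `p_value`,
#'   `median_pre`, `median_post`, `n_pre`, `n_post`.
#' @export
compare_pre_post <- function(ct, population, exact_max = 8) {
  d <- ct[ct$population == population & ct$timepoint %in% c("pre", "post"), ]
  pre <- d$fraction[d$timepoint == "pre"]
  post <- d$fraction[d$timepoint == "post"]
  assert_that(length(pre) > 0 && length(post) > 0,
              "both timepoints need at least one sample")
  ties <- anyDuplicated(c(pre, post)) > 0
  exact <- max(length(pre), length(post)) <= exact_max && !ties
  wt <- suppressWarnings(wilcox.test(pre, post, exact = exact,
                                     correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       median_pre = stats::median(pre), median_post = stats::median(post),
       n_pre = length(pre), n_post = length(post))
}

#' Per-sample lymphoid/myeloid ratio
#'
#' Ratio of the lymphoid to the myeloid fraction of immune cells per sample;
#' samples without myeloid cells give a missing ratio.
#'
#' @param ct composition tibble computed with `denominator = "immune_cells"`.
#' @param lineage_map named vector population -> lineage.
#' @return Tibble with `sample_id`, `timepoint`, `lymphoid`, `myeloid`,
#'   `ratio`.
#' @export
lymphoid_myeloid_ratio <- function(ct, lineage_map = default_lineage_map()) {
  assert_that(all(ct$denominator == "immune_cells"),
              "composition must use the immune_cells denominator")
  unmapped <- setdiff(unique(ct$population), names(lineage_map))
  assert_that(length(unmapped) == 0,
              paste("populations missing from lineage map:",
                    paste(unmapped, collapse = ", ")))
  ct$lineage <- unname(lineage_map[ct$population])
  out <- dplyr::summarise(
    dplyr::group_by(ct, .data$sample_id, .data$timepoint),
    lymphoid = sum(.data$fraction[.data$lineage == "lymphoid"]),
    myeloid = sum(.data$fraction[.data$lineage == "myeloid"]),
    .groups = "drop")
  out$ratio <- ifelse(out$myeloid > 0, out$lymphoid / out$myeloid, NA_real_)
  out
}
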