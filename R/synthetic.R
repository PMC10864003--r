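#' Default population panel for the synthetic cohort
#'
#' Twelve labeled populations emulating a pre/post-chemotherapy solid-tumor
#' cohort: tumor, mesenchyme, endothelium, myeloid subsets and T/NK subsets.
#' Expected cells per sample differ by timepoint so that the cohort reproduces
#' the characteristic compositional shift after induction chemotherapy
#' (tumor fraction collapsing from roughly half of the sample to a few
#' percent, mesenchyme expanding to about half).
#'
#' @return Tibble with columns `name`, `lineage`, `mean_cells_pre`,
#'   `mean_cells_post` and list-column `markers`.
#' @export
default_populations <- function() {
  tibble::tribble(
    ~name,           ~lineage,      ~mean_cells_pre, ~mean_cells_post, ~markers,
    "tumor",         "tumor",       130, 8,   c("MYCN", "PHOX2B", "CHGB", "TH", "CDK4"),
    "mesenchyme",    "mesenchyme",  30, 135,  c("COL1A1", "COL3A1", "DCN", "LUM", "PDGFRB"),
    "endothelium",   "endothelium", 28, 28,   c("PECAM1", "VWF", "CDH5", "KDR", "CLDN5"),
    "macrophage",    "myeloid",     22, 26,   c("CD68", "CD163", "MRC1", "C1QA", "IL10"),
    "cDC",           "myeloid",     5, 6,     c("CLEC9A", "XCR1", "FLT3", "IDO1", "BATF3"),
    "monocyte",      "myeloid",     9, 11,    c("S100A8", "S100A9", "FCN1", "VCAN", "LYZ"),
    "B",             "lymphoid",    9, 10,    c("MS4A1", "CD79A", "CD79B", "IGHM", "CD19"),
    "NK",            "lymphoid",    13, 15,   c("GNLY", "NKG7", "KLRD1", "NCR1", "PRF1"),
    "CD8_T",         "lymphoid",    13, 15,   c("CD8A", "CD8B", "CD3D", "GZMK", "CCL5"),
    "CD4_T_DUSP4",   "lymphoid",    9, 10,    c("DUSP4", "CD4", "CD3E", "MKI67", "CXCL13"),
    "CD4_T_TPT1",    "lymphoid",    5, 6,     c("TPT1", "IL7R", "CCR7", "KLRB1", "RORA"),
    "Treg",          "lymphoid",    5, 6,     c("FOXP3", "IL2RA", "IKZF2", "BATF", "TNFRSF4")
  )
}

#' Define a planted ligand-receptor axis
#'
#' A ground-truth immunoregulatory axis the generator embeds in the data:
#' the ligand is over-expressed in the source population and the receptor in
#' the target effector subset (`coexpr_fold`), and each sample's dysfunction
#' marker expression in the target subset is shifted linearly (on the log
#' scale) in the sample-level ligand abundance of the source, so that the
#' per-sample ligand-mean vs dysfunction-score Pearson correlation is
#' recoverable downstream.
#'
#' @param ligand,receptor gene symbols.
#' @param source,target population labels (target is the effector subset).
#' @param coexpr_fold fold-change of ligand in source and receptor in target
#'   (> 1 for planted axes).
#' @param corr_slope slope (log scale per SD of sample-level ligand abundance)
#'   linking ligand abundance to the dysfunction shift.
#' @param corr_noise_sd sample-level Gaussian noise on the dysfunction shift;
#'   together with `corr_slope` this sets the population correlation
#'   slope / sqrt(slope^2 + noise_sd^2) before measurement noise.
#' @return A one-row tibble.
#' @export
planted_axis <- function(ligand = "NECTIN2", receptor = "TIGIT",
                         source = "macrophage", target = "CD8_T",
                         coexpr_fold = 8, corr_slope = 0.5,
                         corr_noise_sd = 0.375) {
  assert_that(coexpr_fold > 0 && corr_slope >= 0 && corr_noise_sd >= 0,
              "planted axis effects must be non-negative (fold > 0)")
  tibble::tibble(ligand = ligand, receptor = receptor, source = source,
                 target = target, coexpr_fold = coexpr_fold,
                 corr_slope = corr_slope, corr_noise_sd = corr_noise_sd)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a plate-based (CEL-Seq2 style)
#' pre/post-chemotherapy cohort: 24 samples of which 10 pre-treatment, twelve
#' labeled populations, negative-binomial counts with lognormal gene baseline
#' means and per-cell library-size variation, ERCC-style spike-ins present in
#' every well including deliberately empty wells, and one planted
#' ligand-receptor/dysfunction axis among decoy pairs.
#'
#' @param n_samples number of tumor samples (one plate each).
#' @param frac_pre fraction of samples labeled `pre` (pre-treatment).
#' @param populations population panel; see [default_populations()].
#' @param n_genes total number of genes including annotation classes.
#' @param marker_fold fold-change of population marker genes in their own
#'   population.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size_lognormal `c(meanlog, sdlog)` of the per-cell library
#'   scale factor (re-centered to mean 1).
#' @param mean_library_size expected endogenous transcripts per cell.
#' @param n_spikein_genes number of spike-in control genes.
#' @param spikein_total expected total spike-in transcripts per well.
#' @param n_empty_wells_per_plate deliberately empty wells per plate.
#' @param empty_well_noise expected total endogenous transcripts leaking into
#'   an empty well.
#' @param planted_axes tibble of [planted_axis()] rows (may have zero rows).
#' @param decoy_pairs number of decoy ligand-receptor pairs with no planted
#'   structure.
#' @param sample_sigma sdlog of the sample-level ligand abundance multiplier
#'   for planted axes (drives the across-sample signal).
#' @param n_enriched_samples number of samples marked as sorted with an
#'   enriching gate (excluded from composition analysis downstream).
#' @param dysfunction_genes marker genes carrying the dysfunction signal.
#' @param seed master seed; every stage derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 24, frac_pre = 10 / 24,
                       populations = default_populations(),
                       n_genes = 1200, marker_fold = 8, nb_dispersion = 0.4,
                       library_size_lognormal = c(meanlog = 0, sdlog = 0.35),
                       mean_library_size = 6000,
                       n_spikein_genes = 20, spikein_total = 200,
                       n_empty_wells_per_plate = 8, empty_well_noise = 0.5,
                       planted_axes = planted_axis(), decoy_pairs = 50,
                       sample_sigma = 0.5, n_enriched_samples = 2,
                       dysfunction_genes = default_signatures()$dysfunction,
                       seed = 1) {
  assert_that(frac_pre >= 0 && frac_pre <= 1, "frac_pre must be in [0, 1]")
  assert_that(nb_dispersion > 0, "nb_dispersion must be positive")
  assert_that(n_samples >= 1, "need at least one sample")
  populations <- tibble::as_tibble(populations)
  no_markers <- lengths(populations$markers) == 0
  if (any(no_markers) && marker_fold > 1) {
    abort(paste("populations with marker_fold > 1 must have marker genes:",
                paste(populations$name[no_markers], collapse = ", ")))
  }
  structure(list(
    n_samples = n_samples, frac_pre = frac_pre, populations = populations,
    n_genes = n_genes, marker_fold = marker_fold,
    nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    mean_library_size = mean_library_size,
    n_spikein_genes = n_spikein_genes, spikein_total = spikein_total,
    n_empty_wells_per_plate = n_empty_wells_per_plate,
    empty_well_noise = empty_well_noise,
    planted_axes = planted_axes, decoy_pairs = decoy_pairs,
    sample_sigma = sample_sigma, n_enriched_samples = n_enriched_samples,
    dysfunction_genes = dysfunction_genes, seed = seed
  ), class = "sim_config")
}

# Gene annotation panel for a sim_config: named biology genes first, then
# decoy pair genes, filler protein-coding genes, and the special classes.
sim_gene_table <- function(cfg) {
  named <- unique(c(unlist(cfg$populations$markers),
                    default_signatures()$cytotoxicity,
                    cfg$dysfunction_genes,
                    c("CD226", "CD96"),  # checkpoint family for ratio stats
                    cfg$planted_axes$ligand, cfg$planted_axes$receptor))
  decoy_l <- sprintf("LG%03d", seq_len(cfg$decoy_pairs))
  decoy_r <- sprintf("RC%03d", seq_len(cfg$decoy_pairs))
  n_mito <- 8; n_genomic <- 40; n_pseudo <- 20
  n_special <- cfg$n_spikein_genes + n_mito + n_genomic + n_pseudo
  n_named <- length(named) + 2 * cfg$decoy_pairs
  n_filler <- max(0, cfg$n_genes - n_named - n_special)
  sym <- c(named, decoy_l, decoy_r,
           sprintf("GENE%04d", seq_len(n_filler)),
           sprintf("INTRON%03d", seq_len(n_genomic)),
           sprintf("PSG%03d", seq_len(n_pseudo)),
           sprintf("MT-G%02d", seq_len(n_mito)),
           sprintf("ERCC-%05d", seq_len(cfg$n_spikein_genes)))
  cls <- c(rep("protein_coding", n_named + n_filler),
           rep("genomic", n_genomic), rep("pseudogene", n_pseudo),
           rep("mitochondrial", n_mito), rep("spike_in", cfg$n_spikein_genes))
  tibble::tibble(gene_id = sprintf("G%05d", seq_along(sym)),
                 symbol = sym, class = cls)
}

#' Simulate a labeled single-cell cohort with planted structure
#'
#' Draws gene-wise negative-binomial counts with lognormal baseline means,
#' population marker fold-changes, per-cell library-size variation, and the
#' planted ligand-receptor/dysfunction axes of the configuration. Spike-in
#' counts appear in all wells including empty wells; empty wells carry
#' near-zero endogenous counts so the plate liveness threshold can separate
#' them. Byte-identical output under a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `matrix` (a [count_matrix()]), `lr` (an
#'   [lr_database()] of the planted plus decoy pairs), `localization`
#'   (pair genes annotated as `membrane`), `truth` (the planted axes) and
#'   `sample_info` (per-sample timepoint and latent axis covariates).
#' @export
simulate_cohort <- function(cfg) {
  assert_that(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  genes <- sim_gene_table(cfg)
  pops <- cfg$populations
  n_pre <- round(cfg$n_samples * cfg$frac_pre)
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(cfg$n_samples)),
    timepoint = rep(c("pre", "post"), c(n_pre, cfg$n_samples - n_pre)),
    sort_gate = "unbiased")
  if (cfg$n_enriched_samples > 0) {
    idx <- seq(to = cfg$n_samples, length.out = min(cfg$n_enriched_samples, cfg$n_samples))
    samples$sort_gate[idx] <- "enriched"
  }

  # Baseline endogenous means: lognormal, scaled so an average cell has
  # cfg$mean_library_size endogenous transcripts; special classes get fixed
  # small budgets (genomic ~2% of protein-coding, mito ~5%, pseudogenes low).
  endo <- genes$class != "spike_in"
  base <- with_stage_seed(cfg$seed, "base_means", {
    mu <- rlnorm(nrow(genes), meanlog = 0, sdlog = 1)
    named_pc <- genes$class == "protein_coding" &
      !grepl("^GENE", genes$symbol)
    mu[named_pc] <- 1.0
    mu[genes$class == "genomic"] <- 0.02 * sum(mu[genes$class == "protein_coding"]) /
      sum(genes$class == "genomic")
    mu[genes$class == "pseudogene"] <- 0.05
    mu[genes$class == "mitochondrial"] <- 0.05 * sum(mu[genes$class == "protein_coding"]) /
      sum(genes$class == "mitochondrial")
    mu[genes$class == "spike_in"] <- 0
    mu[endo] <- mu[endo] * (cfg$mean_library_size / sum(mu[endo]))
    mu
  })

  # Wells: per sample, Poisson cell numbers per population + empty wells.
  cells <- with_stage_seed(cfg$seed, "wells", {
    rows <- lapply(seq_len(cfg$n_samples), function(j) {
      mc <- if (samples$timepoint[j] == "pre") pops$mean_cells_pre else pops$mean_cells_post
      n <- rpois(nrow(pops), mc)
      pop <- rep(pops$name, n)
      k <- length(pop) + cfg$n_empty_wells_per_plate
      tibble::tibble(
        cell_id = sprintf("%s_W%03d", samples$sample_id[j], seq_len(k)),
        plate_id = samples$sample_id[j],
        sample_id = samples$sample_id[j],
        timepoint = samples$timepoint[j],
        sort_gate = c(rep(samples$sort_gate[j], length(pop)),
                      rep("empty_well", cfg$n_empty_wells_per_plate)),
        population = c(pop, rep("unassigned", cfg$n_empty_wells_per_plate)))
    })
    dplyr::bind_rows(rows)
  })
  real <- cells$sort_gate != "empty_well"
  n_cells <- nrow(cells)

  # Sample-level latent covariates for each planted axis.
  axes <- cfg$planted_axes
  axis_z <- with_stage_seed(cfg$seed, "axis_samples", {
    if (nrow(axes) == 0) matrix(0, cfg$n_samples, 0) else
      matrix(rnorm(cfg$n_samples * nrow(axes)), cfg$n_samples, nrow(axes))
  })
  axis_eps <- with_stage_seed(cfg$seed, "axis_noise", {
    if (nrow(axes) == 0) matrix(0, cfg$n_samples, 0) else
      matrix(rnorm(cfg$n_samples * nrow(axes)), cfg$n_samples, nrow(axes))
  })

  # Per-(gene, cell) mean matrix for real wells.
  mu <- matrix(base, nrow(genes), n_cells)
  cytotox <- default_signatures()$cytotoxicity
  for (p in seq_len(nrow(pops))) {
    in_pop <- cells$population == pops$name[p]
    if (!any(in_pop)) next
    mk <- match(pops$markers[[p]], genes$symbol)
    mu[mk[!is.na(mk)], in_pop] <- mu[mk[!is.na(mk)], in_pop] * cfg$marker_fold
  }
  ct <- match(cytotox, genes$symbol)
  eff <- cells$population %in% c("NK", "CD8_T")
  if (any(eff)) mu[ct[!is.na(ct)], eff] <- mu[ct[!is.na(ct)], eff] * 4
  # dysfunction markers concentrate in the tumor-reactive effector subsets,
  # with a weaker baseline in the remaining T/NK populations
  dys <- match(cfg$dysfunction_genes, genes$symbol)
  reactive <- cells$population %in% c("CD8_T", "CD4_T_DUSP4")
  bystander <- cells$population %in% c("CD4_T_TPT1", "Treg", "NK")
  if (any(reactive)) mu[dys[!is.na(dys)], reactive] <- mu[dys[!is.na(dys)], reactive] * 3
  if (any(bystander)) mu[dys[!is.na(dys)], bystander] <- mu[dys[!is.na(dys)], bystander] * 1.5

  smp <- match(cells$sample_id, samples$sample_id)
  for (a in seq_len(nrow(axes))) {
    li <- match(axes$ligand[a], genes$symbol)
    ri <- match(axes$receptor[a], genes$symbol)
    src <- cells$population == axes$source[a]
    tgt <- cells$population == axes$target[a]
    mu[li, src] <- mu[li, src] * axes$coexpr_fold[a] *
      exp(cfg$sample_sigma * axis_z[smp[src], a])
    mu[ri, tgt] <- mu[ri, tgt] * axes$coexpr_fold[a]
    shift <- exp(axes$corr_slope[a] * axis_z[smp, a] +
                   axes$corr_noise_sd[a] * axis_eps[smp, a])
    mu[dys, tgt] <- mu[dys, tgt] * rep(shift[tgt], each = length(dys))
  }

  lib <- with_stage_seed(cfg$seed, "library_sizes", {
    sdl <- cfg$library_size_lognormal[["sdlog"]]
    ml <- cfg$library_size_lognormal[["meanlog"]]
    rlnorm(n_cells, ml - sdl^2 / 2, sdl)
  })
  mu <- sweep(mu, 2, lib, "*")

  counts <- with_stage_seed(cfg$seed, "counts", {
    x <- matrix(0L, nrow(genes), n_cells)
    # endogenous counts: NB for real wells, sparse Poisson leak in empty wells
    x[endo, real] <- rnbinom(sum(endo) * sum(real),
                             mu = mu[endo, real, drop = FALSE],
                             size = 1 / cfg$nb_dispersion)
    if (any(!real)) {
      pr <- base[endo] / sum(base[endo])
      tot <- rpois(sum(!real), cfg$empty_well_noise)
      leak <- vapply(tot, function(t) {
        as.integer(rmultinom(1, t, pr))
      }, integer(sum(endo)))
      x[endo, !real] <- leak
    }
    spike <- genes$class == "spike_in"
    x[spike, ] <- rpois(sum(spike) * n_cells,
                        cfg$spikein_total / sum(spike))
    x
  })

  truth <- axes
  sample_info <- samples
  if (nrow(axes) > 0) {
    for (a in seq_len(nrow(axes))) {
      sample_info[[paste0("axis", a, "_z")]] <- axis_z[, a]
    }
  }
  db <- lr_database(
    pair_id = c(sprintf("%s_%s", axes$ligand, axes$receptor),
                sprintf("LG%03d_RC%03d", seq_len(cfg$decoy_pairs), seq_len(cfg$decoy_pairs))),
    ligand = c(as.list(axes$ligand), as.list(sprintf("LG%03d", seq_len(cfg$decoy_pairs)))),
    receptor = c(as.list(axes$receptor), as.list(sprintf("RC%03d", seq_len(cfg$decoy_pairs)))),
    annotation = rep(c("planted", "decoy"), c(nrow(axes), cfg$decoy_pairs)))
  loc <- tibble::tibble(
    symbol = unique(c(unlist(db$ligand), unlist(db$receptor))),
    class = "membrane")
  list(matrix = count_matrix(counts, genes, cells), lr = db,
       localization = loc, truth = truth, sample_info = sample_info)
}

#' Construct a hand-computable QC fixture
#'
#' Builds a small single-plate dataset in which exactly one cell violates each
#' cell-level QC rule (and passes all earlier rules), twelve cells pass every
#' rule, and the gene panel exercises the pseudogene and low-expression gene
#' filters, together with the expected per-rule removal table derived from the
#' construction itself — an oracle for [run_qc()].
#'
#' @param seed seed for the small random jitter on spike-in counts.
#' @return List with `matrix` (a [count_matrix()]), `expected_removals`
#'   (tibble `rule`, `n_removed`), `expected_gene_removals` (tibble `reason`,
#'   `n_removed`) and `expected_kept_genes` (gene ids retained by QC).
#' @export
make_qc_fixture <- function(seed = 1) {
  n_pc <- 553  # pc001..pc550 plus the three low-expression special cases
  genes <- tibble::tibble(
    gene_id = c(sprintf("pc%03d", 1:550), "pcA", "pcB", "pcC",
                sprintf("g%02d", 1:30), sprintf("m%02d", 1:10),
                sprintf("s%02d", 1:10), sprintf("p%02d", 1:10)),
    symbol = gene_id,
    class = rep(c("protein_coding", "genomic", "mitochondrial",
                  "spike_in", "pseudogene"), c(n_pc, 30, 10, 10, 10)))
  ids <- genes$gene_id
  n_genes <- nrow(genes)

  cell_names <- c(sprintf("pass%02d", 1:12), "v_liveness", "v_gpratio",
                  "v_mito", "v_lowtx", "v_lowgenes", "v_hightx",
                  sprintf("empty%02d", 1:3))
  x <- matrix(0L, n_genes, length(cell_names),
              dimnames = list(ids, cell_names))
  spikes <- sprintf("s%02d", 1:10)
  with_stage_seed(seed, "qc_fixture", {
    spike_counts <- matrix(5L + sample(0:1, 10 * length(cell_names), TRUE),
                           10, length(cell_names))
    x[spikes, ] <- spike_counts
  })

  pass <- sprintf("pass%02d", 1:12)
  x[sprintf("pc%03d", 1:520), pass] <- 2L   # 1040 nuclear tx, 520 genes
  x["g01", pass] <- 1L                      # GPratio = 1040 / 1
  x["m01", pass] <- 5L
  # low-expression gene cases, carried by passing cells only:
  x["pcA", pass[1:4]] <- 3L                       # 4 cells expressing -> removed
  x["pcB", pass[1:6]] <- c(2L, 1L, 1L, 1L, 1L, 1L) # 6 expressing, 1 cell >=2 -> removed
  x["pcC", pass[1:5]] <- c(2L, 2L, 1L, 1L, 1L)     # 5 expressing, 2 cells >=2 -> kept

  x[sprintf("pc%03d", 1:100), "v_liveness"] <- 2L   # total 200 + ~50 spikes < 500
  x[sprintf("pc%03d", 1:475), "v_gpratio"] <- 4L    # 1900 protein-coding
  x["g02", "v_gpratio"] <- 100L                     # GPratio 19 < 20
  x[sprintf("pc%03d", 1:350), "v_mito"] <- 4L       # nuclear 1400
  x["m02", "v_mito"] <- 1500L                       # mito > nuclear
  x[sprintf("pc%03d", 1:300), "v_lowtx"] <- 3L      # 900 nuclear < 1000
  x["g03", "v_lowtx"] <- 1L
  x[sprintf("pc%03d", 1:400), "v_lowgenes"] <- 3L   # 1200 nuclear, 400 genes < 500
  x["g04", "v_lowgenes"] <- 1L
  x[sprintf("pc%03d", 1:500), "v_hightx"] <- 400L   # 200000 nuclear > 150000
  x["g05", "v_hightx"] <- 1L
  x["pc001", sprintf("empty%02d", 1:3)] <- 1L       # tiny endogenous leak

  cells <- tibble::tibble(
    cell_id = cell_names, plate_id = "P1", sample_id = "S1",
    timepoint = "pre",
    sort_gate = ifelse(grepl("^empty", cell_names), "empty_well", "unbiased"),
    population = ifelse(grepl("^empty", cell_names), "unassigned", "CD8_T"))

  expected_removals <- tibble::tibble(
    rule = c("empty_well", "liveness", "gp_ratio", "mito_dominant",
             "low_transcripts", "low_genes", "high_transcripts"),
    n_removed = c(3L, 1L, 1L, 1L, 1L, 1L, 1L))
  # g01 is expressed in all passing cells but never at >= 2 transcripts, so
  # the low-expression rule removes it along with pcA, pcB, the unused
  # pc521..pc550 and the genomic genes only touched by violating cells.
  kept <- c(sprintf("pc%03d", 1:520), "pcC")
  expected_gene_removals <- tibble::tibble(
    reason = c("spike_in", "mitochondrial", "pseudogene", "low_expression"),
    n_removed = c(10L, 10L, 10L, n_genes - 30L - length(kept)))
  list(matrix = count_matrix(x, genes, cells),
       expected_removals = expected_removals,
       expected_gene_removals = expected_gene_removals,
       expected_kept_genes = kept)
}
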