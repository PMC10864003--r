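#' Gene classes recognized by the pipeline
#'
#' Per-gene annotation classes: `protein_coding`, `genomic` (intronic reads,
#' used for the GPratio purity filter), `pseudogene`, `mitochondrial`,
#' `spike_in` (ERCC-style synthetic controls) and `other`.
#' @export
GENE_CLASSES <- c("protein_coding", "genomic", "pseudogene",
                  "mitochondrial", "spike_in", "other")

TIMEPOINTS <- c("pre", "post", "reference_blood")
SORT_GATES <- c("unbiased", "enriched", "empty_well")

#' Construct a count matrix container
#'
#' Bundles a sparse gene x cell matrix of raw counts with its gene annotation
#' and per-cell (well) metadata, the in-memory unit every downstream stage
#' consumes.
#'
#' @param counts genes x cells matrix (coerced to sparse `dgCMatrix`);
#'   non-negative integers.
#' @param genes data frame with columns `gene_id`, `symbol`, `class`
#'   (one of [GENE_CLASSES]), one row per matrix row.
#' @param cells cell metadata; see [cell_table()]. One row per matrix column.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `genes`, `cells`.
#' @export
count_matrix <- function(counts, genes, cells) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  genes <- tibble::as_tibble(genes)
  cells <- cell_table(cells)
  need <- c("gene_id", "symbol", "class")
  assert_that(all(need %in% names(genes)),
              paste("gene table must have columns", paste(need, collapse = ", ")))
  genes$symbol <- trimws(genes$symbol)
  assert_that(!anyDuplicated(genes$gene_id), "gene ids must be unique")
  assert_that(all(genes$class %in% GENE_CLASSES),
              paste("unknown gene class:",
                    paste(setdiff(unique(genes$class), GENE_CLASSES), collapse = ", ")))
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d x %d but gene table has %d rows and cell table has %d rows",
      nrow(counts), ncol(counts), nrow(genes), nrow(cells)))
  }
  check_counts_integral(counts)
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "count_matrix")
}

check_counts_integral <- function(counts) {
  x <- counts@x
  bad <- which(x < 0 | x != round(x))
  if (length(bad)) {
    ij <- which_triplet(counts, bad[1])
    abort(sprintf("count at (gene %d, cell %d) is %g: counts must be non-negative integers",
                  ij[1], ij[2], x[bad[1]]))
  }
  invisible(TRUE)
}

# row/column (1-based) of the k-th stored entry of a dgCMatrix
which_triplet <- function(m, k) {
  i <- m@i[k] + 1L
  j <- max(which(m@p < k))
  c(i, j)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(table(x$genes$class)), table(x$genes$class)),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Validate and normalize a cell metadata table
#'
#' One row per well: `cell_id`, `plate_id`, `sample_id`, `timepoint`
#' (`pre`/`post`/`reference_blood`), `sort_gate` (`unbiased`/`enriched`/
#' `empty_well`), `population` (label or `"unassigned"`), plus QC bookkeeping
#' columns `qc_pass` and `qc_reason` (added if missing). Empty wells are never
#' marked as passing QC.
#'
#' @param cells a data frame.
#' @return A tibble with validated columns.
#' @export
cell_table <- function(cells) {
  cells <- tibble::as_tibble(cells)
  need <- c("cell_id", "plate_id", "sample_id", "timepoint", "sort_gate", "population")
  miss <- setdiff(need, names(cells))
  assert_that(length(miss) == 0,
              paste("cell table missing columns:", paste(miss, collapse = ", ")))
  assert_that(!anyDuplicated(cells$cell_id), "cell ids must be unique")
  assert_that(all(cells$timepoint %in% TIMEPOINTS),
              paste("unknown timepoint:",
                    paste(setdiff(unique(cells$timepoint), TIMEPOINTS), collapse = ", ")))
  assert_that(all(cells$sort_gate %in% SORT_GATES),
              paste("unknown sort_gate:",
                    paste(setdiff(unique(cells$sort_gate), SORT_GATES), collapse = ", ")))
  if (!"qc_pass" %in% names(cells)) cells$qc_pass <- TRUE
  if (!"qc_reason" %in% names(cells)) cells$qc_reason <- ""
  cells$qc_pass[cells$sort_gate == "empty_well"] <- FALSE
  cells$qc_reason[cells$sort_gate == "empty_well" & cells$qc_reason == ""] <- "empty_well"
  cells
}

#' Read a count matrix with gene and cell annotation
#'
#' Accepts a MatrixMarket coordinate file (`.mtx`, optionally gzipped) or a
#' dense TSV whose first column is `gene_id` and remaining columns are cells.
#' Gene and cell tables are headered TSVs (optionally gzipped).
#'
#' @param matrix_path path to `.mtx`/`.mtx.gz` or dense `.tsv`.
#' @param genes_path TSV with columns `gene_id`, `symbol`, `class`.
#' @param cells_path TSV with the [cell_table()] columns.
#' @return A [count_matrix()].
#' @export
read_counts <- function(matrix_path, genes_path, cells_path) {
  genes <- read_tsv_strict(genes_path)
  cells <- read_tsv_strict(cells_path)
  if (grepl("\\.mtx(\\.gz)?$", matrix_path)) {
    con <- if (grepl("\\.gz$", matrix_path)) gzfile(matrix_path) else matrix_path
    m <- Matrix::readMM(con)
  } else {
    d <- read_tsv_strict(matrix_path)
    assert_that(names(d)[1] == "gene_id",
                "dense count TSV must have 'gene_id' as its first column")
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$gene_id
  }
  count_matrix(m, genes, cells)
}

#' Write a count matrix and its annotation tables
#'
#' Inverse of [read_counts()]: writes `matrix.mtx`, `genes.tsv` and
#' `cells.tsv` under `dir`. Round-trips exactly.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three paths written.
#' @export
write_counts <- function(cm, dir) {
  assert_that(is_count_matrix(cm), "cm must be a count_matrix")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  m <- cm$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, paths[1])
  readr::write_tsv(cm$genes, paths[2])
  readr::write_tsv(cm$cells, paths[3])
  invisible(paths)
}

read_tsv_strict <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                  progress = FALSE, show_col_types = FALSE, quote = "")
}

#' Read a curated ligand-receptor pair database
#'
#' TSV with columns `pair_id`, `ligand`, `receptor` (and optional
#' `annotation`). Multi-subunit complexes are written as `"+"`-joined gene
#' symbols (e.g. `IL2RA+IL2RB`); subunit order is preserved.
#'
#' @param path TSV path (optionally gzipped).
#' @return A tibble of class `lr_database` with list-columns `ligand` and
#'   `receptor` holding character vectors of subunits.
#' @export
read_lr_database <- function(path) {
  d <- read_tsv_strict(path)
  need <- c("pair_id", "ligand", "receptor")
  assert_that(all(need %in% names(d)),
              paste("ligand-receptor table must have columns", paste(need, collapse = ", ")))
  for (col in c("ligand", "receptor")) {
    empty <- which(is.na(d[[col]]) | trimws(d[[col]]) == "")
    if (length(empty)) {
      abort(sprintf("empty %s field on line %d of %s", col, empty[1] + 1L, path))
    }
  }
  lr_database(d$pair_id, strsplit(trimws(d$ligand), "+", fixed = TRUE),
              strsplit(trimws(d$receptor), "+", fixed = TRUE),
              annotation = if ("annotation" %in% names(d)) d$annotation else "")
}

#' Construct a ligand-receptor database in memory
#'
#' @param pair_id unique pair identifiers.
#' @param ligand,receptor list of character vectors (complex subunits), or a
#'   character vector of single genes.
#' @param annotation free-text annotation, recycled.
#' @return A tibble of class `lr_database`.
#' @export
lr_database <- function(pair_id, ligand, receptor, annotation = "") {
  if (is.character(ligand)) ligand <- as.list(ligand)
  if (is.character(receptor)) receptor <- as.list(receptor)
  assert_that(!anyDuplicated(pair_id),
              paste("duplicate pair_id:",
                    paste(unique(pair_id[duplicated(pair_id)]), collapse = ", ")))
  assert_that(all(lengths(ligand) > 0) && all(lengths(receptor) > 0),
              "every ligand and receptor complex must be non-empty")
  db <- tibble::tibble(pair_id = pair_id, ligand = ligand, receptor = receptor,
                       annotation = rep_len(annotation, length(pair_id)))
  class(db) <- c("lr_database", class(db))
  db
}

#' Read a gene localization annotation table
#'
#' Maps gene symbols to a predicted cellular localization class
#' (`membrane`, `secreted` or `other`), the gate used by target
#' prioritization: only membrane-expressed or secreted partners are
#' therapeutically accessible. Genes absent from the table are `other`.
#'
#' @param path TSV with columns `symbol`, `class`.
#' @return A tibble with columns `symbol`, `class`.
#' @export
read_localization <- function(path) {
  d <- read_tsv_strict(path)
  assert_that(all(c("symbol", "class") %in% names(d)),
              "localization table must have columns symbol, class")
  assert_that(all(d$class %in% c("membrane", "secreted", "other")),
              "localization class must be membrane, secreted or other")
  tibble::tibble(symbol = trimws(d$symbol), class = d$class)
}

#' Look up localization classes, defaulting to "other"
#'
#' @param loc localization tibble (see [read_localization()]), or `NULL`.
#' @param symbols gene symbols to query.
#' @return Character vector of classes, `"other"` for unlisted genes.
#' @export
localization_class <- function(loc, symbols) {
  if (is.null(loc) || nrow(loc) == 0) return(rep("other", length(symbols)))
  cls <- loc$class[match(symbols, loc$symbol)]
  cls[is.na(cls)] <- "other"
  cls
}
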