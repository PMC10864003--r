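# Small in-code fixtures shared across test files.

# minimal cell table: n cells on one plate/sample unless overridden
make_cells <- function(n, population = "A", sample_id = "S1", plate_id = "P1",
                       timepoint = "pre", sort_gate = "unbiased",
                       prefix = "c") {
  tibble::tibble(
    cell_id = paste0(prefix, seq_len(n)),
    plate_id = rep_len(plate_id, n), sample_id = rep_len(sample_id, n),
    timepoint = rep_len(timepoint, n), sort_gate = rep_len(sort_gate, n),
    population = rep_len(population, n))
}

# dense integer matrix -> count_matrix, with gene classes (default all
# protein-coding); rownames/colnames used as ids
make_cm <- function(x, classes = NULL, cells = NULL) {
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  genes <- tibble::tibble(gene_id = rownames(x), symbol = rownames(x),
                          class = classes %||% rep("protein_coding", nrow(x)))
  if (is.null(cells)) cells <- make_cells(ncol(x))
  cells$cell_id <- colnames(x)
  count_matrix(x, genes, cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalized matrix straight from a dense matrix of expression values
make_nm <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  m <- methods::as(methods::as(x, "CsparseMatrix"), "dMatrix")
  attr(m, "normalization") <- "cp10k_log1p"
  m
}
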