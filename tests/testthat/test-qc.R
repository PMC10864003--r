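# A 6-gene panel with one gene per class knob lets every rule be exercised
# with hand-set counts: rows are protein-coding (x2), genomic, mitochondrial,
# spike-in, pseudogene.
qc_panel <- function(x) {
  make_cm(x, classes = c("protein_coding", "protein_coding", "genomic",
                         "mitochondrial", "spike_in", "pseudogene"))
}

test_that("liveness threshold is the empty-well bound with a 500 floor", {
  # cell1: 499 transcripts total -> below floor; cell2: 500 -> passes
  x <- matrix(0, 6, 5)
  x[1, 1] <- 499; x[1, 2] <- 500
  x[5, 3:5] <- c(10, 12, 8)  # empty wells: spike-in only
  cells <- make_cells(5)
  cells$sort_gate <- c("unbiased", "unbiased", rep("empty_well", 3))
  cm <- qc_panel(x); cm$cells <- cell_table(cells)
  cm <- count_matrix(x, cm$genes, cells)
  out <- liveness_filter(cm)
  expect_equal(out$qc_reason[1:2], c("liveness", ""))
  expect_equal(out$qc_reason[3:5], rep("empty_well", 3))

  # empty wells at {900, 1000}: threshold = mean + 3 sd, above the floor;
  # brute-force recomputation fixes the boundary
  thr <- mean(c(900, 1000)) + 3 * sd(c(900, 1000))
  x2 <- matrix(0, 6, 4)
  x2[1, 1] <- ceiling(thr)     # just above -> passes
  x2[1, 2] <- floor(thr)       # just below -> removed
  x2[5, 3:4] <- c(900, 1000)
  cells2 <- make_cells(4)
  cells2$sort_gate <- c("unbiased", "unbiased", "empty_well", "empty_well")
  cm2 <- count_matrix(x2, qc_panel(x2)$genes, cells2)
  out2 <- liveness_filter(cm2)
  expect_gt(thr, 500)
  expect_equal(out2$qc_pass[1:2], c(TRUE, FALSE))
})

test_that("plates without empty wells fall back to the configured floor", {
  x <- matrix(0, 6, 2)
  x[1, ] <- c(499, 501)
  cm <- qc_panel(x)
  out <- liveness_filter(cm)
  expect_equal(out$qc_pass, c(FALSE, TRUE))
})

test_that("GPratio removes low protein-coding purity; zero genomic passes", {
  x <- matrix(0, 6, 3)
  x[1, ] <- c(1900, 2000, 2000)  # protein-coding
  x[3, ] <- c(100, 100, 0)       # genomic: ratios 19, 20, Inf
  cm <- qc_panel(x)
  out <- gp_ratio_filter(cm)
  expect_equal(out$qc_reason, c("gp_ratio", "", ""))

  # reversed direction is available for the literal reading
  cfg <- qc_config(gp_ratio_direction = "genomic_over_protein")
  out2 <- gp_ratio_filter(cm, cfg = cfg)
  expect_equal(out2$qc_pass, c(FALSE, FALSE, FALSE))
})

test_that("mitochondrial dominance is a strict inequality over nuclear counts", {
  x <- matrix(0, 6, 3)
  x[1, ] <- c(500, 500, 500)   # nuclear
  x[4, ] <- c(600, 500, 0)     # mito: dominant, equal, none
  cm <- qc_panel(x)
  out <- mito_filter(cm)
  expect_equal(out$qc_reason, c("mito_dominant", "", ""))
})

test_that("transcript/gene bounds are strict with first-matching reasons", {
  n_genes <- 600
  mk <- function(n_expr, per) {
    col <- numeric(n_genes); col[seq_len(n_expr)] <- per; col
  }
  x <- cbind(mk(550, 2),    # 1100 tx, 550 genes: passes
             mk(499, 2),    # 998 tx -> low_transcripts (also <500 genes)
             mk(400, 3),    # 1200 tx, 400 genes -> low_genes
             mk(500, 301),  # 150500 tx -> high_transcripts
             mk(500, 300),  # 150000 tx: boundary passes
             mk(500, 2))    # 1000 tx, 500 genes: boundary passes
  cm <- make_cm(x)
  out <- transcript_gene_bounds(cm)
  expect_equal(out$qc_reason,
               c("", "low_transcripts", "low_genes", "high_transcripts", "", ""))
})

test_that("gene filter drops special classes and low-expression genes", {
  # 7 cells passing; gene rows constructed per rule
  x <- rbind(
    rep(2, 7),                   # kept
    c(3, 3, 3, 3, 0, 0, 0),      # 4 cells expressing -> removed
    c(2, 1, 1, 1, 1, 1, 0),      # 6 expressing, 1 cell >=2 -> removed
    c(2, 2, 1, 1, 1, 0, 0),      # 5 expressing, 2 cells >=2 -> kept
    rep(1, 7),                   # never >=2 -> removed
    rep(4, 7))                   # pseudogene -> removed regardless
  cm <- make_cm(x, classes = c(rep("protein_coding", 5), "pseudogene"))
  out <- gene_filter(cm)
  expect_equal(out$matrix$genes$gene_id, c("g1", "g4"))
  expect_equal(out$gene_removals$n_removed[out$gene_removals$reason == "pseudogene"], 1L)
  expect_equal(out$gene_removals$n_removed[out$gene_removals$reason == "low_expression"], 3L)
})

test_that("run_qc matches the constructed fixture oracle exactly", {
  fx <- make_qc_fixture(seed = 1)
  res <- run_qc(fx$matrix)
  expect_equal(res$report$cell_removals, fx$expected_removals)
  expect_equal(res$report$gene_removals, fx$expected_gene_removals)
  expect_setequal(res$matrix$genes$gene_id, fx$expected_kept_genes)
  # accounting identity
  expect_equal(sum(res$report$cell_removals$n_removed) + res$report$n_cells_out,
               res$report$n_cells_in)
})

test_that("the QC cascade agrees with per-cell brute-force recomputation", {
  fx <- make_qc_fixture(seed = 3)
  cm <- fx$matrix
  res <- run_qc(cm)
  x <- as.matrix(cm$counts)
  cls <- cm$genes$class
  empties <- cm$cells$sort_gate == "empty_well"
  thr <- max(500, mean(colSums(x)[empties]) + 3 * sd(colSums(x)[empties]))
  expected <- character(ncol(x))
  for (j in seq_len(ncol(x))) {
    pc <- sum(x[cls == "protein_coding", j]); gen <- sum(x[cls == "genomic", j])
    mito <- sum(x[cls == "mitochondrial", j])
    nuc_rows <- !(cls %in% c("mitochondrial", "spike_in"))
    nuclear <- sum(x[nuc_rows, j]); ngene <- sum(x[nuc_rows, j] > 0)
    expected[j] <-
      if (empties[j]) "empty_well"
      else if (sum(x[, j]) < thr) "liveness"
      else if (gen > 0 && pc / gen < 20) "gp_ratio"
      else if (mito > nuclear) "mito_dominant"
      else if (nuclear < 1000) "low_transcripts"
      else if (ngene < 500) "low_genes"
      else if (nuclear > 150000) "high_transcripts"
      else ""
  }
  expect_equal(res$cells$qc_reason, expected)
  expect_equal(res$cells$qc_pass, expected == "")
})

test_that("run_qc is idempotent and stable under cell permutation", {
  fx <- make_qc_fixture(seed = 5)
  res1 <- run_qc(fx$matrix)
  res2 <- run_qc(res1$matrix)
  expect_equal(sum(res2$report$cell_removals$n_removed), 0)
  expect_equal(sum(res2$report$gene_removals$n_removed), 0)
  expect_identical(as.matrix(res2$matrix$counts), as.matrix(res1$matrix$counts))

  perm <- withr::with_seed(9, sample(ncol(fx$matrix$counts)))
  cmp <- count_matrix(fx$matrix$counts[, perm], fx$matrix$genes,
                      fx$matrix$cells[perm, ])
  resp <- run_qc(cmp)
  reasons <- setNames(res1$cells$qc_reason, res1$cells$cell_id)
  expect_equal(resp$cells$qc_reason, unname(reasons[resp$cells$cell_id]))
  expect_equal(resp$report$cell_removals, res1$report$cell_removals)
})

test_that("fixture generation is deterministic and label-driven drops work", {
  a <- make_qc_fixture(seed = 2)
  b <- make_qc_fixture(seed = 2)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$expected_removals, b$expected_removals)

  cm <- a$matrix
  dropped <- drop_populations(cm, "CD8_T")
  expect_equal(sum(dropped$cells$population == "CD8_T"), 0)
  expect_equal(ncol(dropped$counts), sum(cm$cells$population != "CD8_T"))
})
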