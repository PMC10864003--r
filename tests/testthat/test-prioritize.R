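test_that("per-sample means aggregate and exclude small samples", {
  x <- rbind(G1 = c(0, 2, 1, 1, 1, 1), G2 = c(4, 4, 0, 0, 2, 2))
  nm <- make_nm(x)
  cells <- make_cells(6)
  cells$sample_id <- c("S1", "S1", "S2", "S2", "S3", "S3")
  cells$population <- c("X", "X", "X", "Y", "X", "X")
  m <- per_sample_means(nm, cells, "X", min_cells = 2, min_samples = 2)
  expect_equal(m["G1", "S1"], 1)          # (0 + 2) / 2
  expect_equal(sort(colnames(m)), c("S1", "S3"))
  expect_equal(attr(m, "excluded_samples"), "S2")  # one X cell < min_cells
  expect_error(per_sample_means(nm, cells, "NOPE", min_cells = 1, min_samples = 1),
               "population absent")

  # brute-force equality on a random fixture
  set.seed(31)
  y <- matrix(rexp(10 * 30), 10, 30, dimnames = list(paste0("g", 1:10), NULL))
  nm2 <- make_nm(y)
  cells2 <- make_cells(30)
  cells2$sample_id <- rep(paste0("S", 1:5), each = 6)
  cells2$population <- rep(c("X", "X", "X", "X", "X", "Z"), 5)
  m2 <- per_sample_means(nm2, cells2, "X", min_cells = 5, min_samples = 5)
  for (s in colnames(m2)) {
    idx <- which(cells2$sample_id == s & cells2$population == "X")
    expect_equal(unname(m2[, s]), unname(rowMeans(y[, idx])))
  }
})

test_that("dysfunction scores aggregate per sample over the subset", {
  scores <- tibble::tibble(cell_id = paste0("c", 1:6),
                           signature = "dysfunction",
                           score = c(0.1, 0.3, 0.5, 0.7, 0.2, 0.4))
  cells <- make_cells(6)
  cells$sample_id <- c("S1", "S1", "S2", "S2", "S2", "S2")
  cells$population <- c("Y", "Y", "Y", "Y", "Y", "Z")
  out <- dysfunction_by_sample(scores, cells, "Y", min_cells = 2)
  expect_equal(out[["S1"]], 0.2)
  expect_equal(out[["S2"]], mean(c(0.5, 0.7, 0.2)))
  out1 <- dysfunction_by_sample(scores, cells, "Z", min_cells = 1)
  expect_equal(out1[["S2"]], 0.4)
})

overlay_fixture <- function(r_target = 0.9, n_samples = 12, seed = 1) {
  set.seed(seed)
  samples <- paste0("S", seq_len(n_samples))
  dys <- setNames(rnorm(n_samples), samples)
  means <- rbind(
    HIT = dys * r_target + rnorm(n_samples, sd = sqrt(1 - r_target^2) * sd(dys)),
    MISS1 = rnorm(n_samples), MISS2 = rnorm(n_samples),
    INERT = rnorm(n_samples))
  colnames(means) <- samples
  ints <- tibble::tibble(
    source = "X", target = "Y",
    pair_id = c("HIT_R", "MISS1_R"),
    ligand_mean = 1, receptor_mean = 1, score = 1, p_value = 0.001,
    expr_frac_ligand = 1, expr_frac_receptor = 1, significant = TRUE)
  db <- lr_database(c("HIT_R", "MISS1_R", "INERT_R"),
                    list("HIT", "MISS1", "INERT"), list("R", "R", "R"))
  loc <- tibble::tibble(symbol = c("HIT", "MISS1", "MISS2"), class = "membrane")
  list(means = means, dys = dys, ints = ints, db = db, loc = loc)
}

test_that("overlay calls require localization, correlation and support jointly", {
  fx <- overlay_fixture()
  tt <- overlay_targets(fx$means, fx$dys, fx$ints, fx$db, fx$loc,
                        x = "X", y = "Y", min_samples = 5)
  hit <- tt[tt$gene == "HIT", ]
  expect_true(hit$call)
  expect_equal(hit$interaction_support[[1]], "HIT_R")
  expect_gt(hit$pearson_r, 0.5)
  # INERT lacks localization (other) and support; MISS2 lacks support
  expect_false(tt$call[tt$gene == "INERT"])
  expect_false(tt$call[tt$gene == "MISS2"])

  # correlations match direct cor.test per gene
  for (g in rownames(fx$means)) {
    ct <- cor.test(fx$means[g, ], fx$dys)
    expect_equal(tt$pearson_r[tt$gene == g], unname(ct$estimate))
    expect_equal(tt$corr_p[tt$gene == g], ct$p.value)
  }

  # empty localization table (everything "other"): gate closes all calls
  tt0 <- overlay_targets(fx$means, fx$dys, fx$ints, fx$db, NULL,
                         x = "X", y = "Y", min_samples = 5)
  expect_equal(sum(tt0$call), 0)
})

test_that("overlay is invariant to sample and gene ordering", {
  fx <- overlay_fixture(seed = 4)
  tt <- overlay_targets(fx$means, fx$dys, fx$ints, fx$db, fx$loc,
                        x = "X", y = "Y", min_samples = 5)
  sp <- withr::with_seed(2, sample(ncol(fx$means)))
  gp <- withr::with_seed(3, sample(nrow(fx$means)))
  tt2 <- overlay_targets(fx$means[gp, sp], fx$dys, fx$ints, fx$db, fx$loc,
                         x = "X", y = "Y", min_samples = 5)
  tt2 <- tt2[match(tt$gene, tt2$gene), ]
  expect_equal(tt$pearson_r, tt2$pearson_r)
  expect_equal(tt$call, tt2$call)
})

test_that("ranking puts called rows first with documented tie-breaks", {
  tt <- tibble::tibble(
    population_x = "X", gene = c("A", "B", "C", "D"), effector_y = "Y",
    pearson_r = c(0.7, 0.9, 0.8, 0.8), corr_p = c(0.01, 0.01, 0.01, 0.001),
    n_samples = 10, localization = "membrane",
    interaction_support = list("p", "p", "p", "p"),
    call = c(TRUE, TRUE, TRUE, TRUE))
  out <- rank_targets(tt)
  expect_equal(out$gene, c("B", "D", "C", "A"))  # r desc, tie by smaller p

  tt$call <- c(TRUE, FALSE, FALSE, TRUE)
  out2 <- rank_targets(tt)
  expect_equal(out2$gene[1:2], c("D", "A"))      # called rows first
})
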