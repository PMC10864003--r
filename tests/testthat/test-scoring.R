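test_that("cp10k log1p normalization matches its closed form", {
  x <- matrix(0, 3, 3)
  x[1, 1] <- 1; x[2, 1] <- 9999         # cell1 total 10000
  x[1, 2] <- 3; x[3, 2] <- 2            # cell2 total 5
  cm <- make_cm(x)
  nm <- normalize_cp10k_log1p(cm)
  expect_equal(nm[1, 1], log(2))
  expect_equal(nm[1, 2], log1p(3 / 5 * 1e4))
  expect_equal(as.numeric(nm[, 3]), c(0, 0, 0))  # all-zero cell stays zero
  expect_equal(attr(nm, "normalization"), "cp10k_log1p")

  # independent dense recomputation on a random fixture
  set.seed(5)
  y <- matrix(rpois(20, 3), 5, 4)
  ny <- normalize_cp10k_log1p(make_cm(y))
  ref <- apply(y, 2, function(col) {
    if (sum(col) == 0) rep(0, length(col)) else log1p(col / sum(col) * 1e4)
  })
  expect_equal(as.matrix(ny), ref, ignore_attr = TRUE)
})

# independent step-by-step module score: explicit loops, same control-draw
# procedure (bin by expression rank, sample n_ctrl per signature gene)
brute_module_score <- function(nm, sig, n_bins, n_ctrl, seed) {
  x <- as.matrix(nm)
  avg <- rowMeans(x)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk * n_bins / length(avg))
  sig_idx <- match(sig, rownames(x))
  set.seed(immunax:::stage_seed(seed, "module_score_controls"))
  ctrl <- c()
  for (g in sig_idx) {
    members <- which(bin == bin[g])
    k <- min(n_ctrl, length(members))
    ctrl <- c(ctrl, members[sample.int(length(members), k)])
  }
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    out[j] <- mean(x[sig_idx, j]) - mean(x[ctrl, j])
  }
  out
}

test_that("module score equals the brute-force oracle on a 50-gene fixture", {
  set.seed(42)
  x <- matrix(rexp(50 * 20), 50, 20)
  nm <- make_nm(x)
  sig <- rownames(nm)[c(3, 11, 27, 40)]
  got <- module_score(nm, sig, n_bins = 8, n_ctrl = 5, seed = 7)
  want <- brute_module_score(nm, sig, n_bins = 8, n_ctrl = 5, seed = 7)
  expect_lt(max(abs(got$score - want)), 1e-12)
})

test_that("module score symmetry and invariance properties hold", {
  # constant matrix: controls are indistinguishable from the signature
  nm <- make_nm(matrix(2, 30, 6))
  sc <- module_score(nm, rownames(nm)[1:3], seed = 1)
  expect_equal(sc$score, rep(0, 6))

  # one gene per bin: the control draw is forced back onto the gene itself
  set.seed(8)
  x <- matrix(rexp(24 * 5), 24, 5)
  nm1 <- make_nm(x)
  sc1 <- module_score(nm1, rownames(nm1)[10], n_bins = 24, seed = 3)
  expect_equal(sc1$score, rep(0, 5))

  # translation invariance: shifting every entry leaves scores unchanged
  set.seed(9)
  y <- matrix(rexp(40 * 8), 40, 8)
  s0 <- module_score(make_nm(y), paste0("g", c(2, 5, 9)), seed = 11)
  s1 <- module_score(make_nm(y + 3.7), paste0("g", c(2, 5, 9)), seed = 11)
  expect_equal(s0$score, s1$score)

  # determinism under a fixed seed
  s2 <- module_score(make_nm(y), paste0("g", c(2, 5, 9)), seed = 11)
  expect_identical(s0, s2)
})

test_that("random signatures on structureless data score near zero on average", {
  set.seed(13)
  x <- matrix(rexp(100 * 30), 100, 30)
  nm <- make_nm(x)
  means <- vapply(1:200, function(i) {
    sig <- rownames(nm)[sample.int(100, 5)]
    mean(module_score(nm, sig, seed = i)$score)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("signature handling warns on dropped genes and errors when empty", {
  nm <- make_nm(matrix(1:12, 4, 3))
  expect_warning(module_score(nm, c("g1", "nope"), seed = 1), "nope")
  expect_error(suppressWarnings(module_score(nm, "nope", seed = 1)),
               "empty after intersection")
})

test_that("receptor ratios use group means with zeros included", {
  x <- rbind(TIGIT = c(1.2, 0, 0.6, 0.6), CD226 = c(0.6, 0, 0.3, 0.3),
             CD96 = c(0, 0, 0, 0))
  nm <- make_nm(x)
  cells <- make_cells(4)
  cells$population <- c("NK", "NK", "NK", "T")
  out <- receptor_ratio(nm, cells, "TIGIT", "CD226", group_by = "population")
  expect_equal(out$ratio[out$population == "NK"], 2)   # means 0.6 / 0.3
  expect_equal(out$ratio[out$population == "T"], 2)
  out2 <- receptor_ratio(nm, cells, "CD96", "TIGIT", group_by = "population")
  expect_equal(out2$numerator_mean, c(0, 0))
  out3 <- receptor_ratio(nm, cells, "TIGIT", "CD96", group_by = "population")
  expect_true(all(is.na(out3$ratio)))                  # zero denominator: missing
  expect_error(receptor_ratio(nm, cells, "TIGIT", "FOO"), "unknown gene")
})

test_that("score correlation gives exact closed-form results", {
  x <- c(1, 2, 3)
  perfect <- correlate_scores(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  swapped <- correlate_scores(x, c(1, 3, 2))
  expect_equal(swapped$r, 0.5)
  expect_equal(swapped$n, 3)

  const <- correlate_scores(x, c(2, 2, 2))
  expect_false(const$defined)
  expect_true(is.na(const$r))
  expect_error(correlate_scores(c(1, 2), c(3, 4)), "at least 3")

  # affine invariance up to sign
  set.seed(21)
  a <- rnorm(10); b <- rnorm(10)
  r0 <- correlate_scores(a, b)$r
  expect_equal(correlate_scores(5 * a + 2, b)$r, r0)
  expect_equal(correlate_scores(-2 * a, b)$r, -r0)
})

test_that("percent killing is the normalized luminescence complement", {
  expect_equal(percent_killing(1000, 1000), 0)
  expect_equal(percent_killing(0, 1000), 100)
  expect_equal(percent_killing(250, 1000), 75)
  expect_error(percent_killing(1, 0), "positive")
})
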