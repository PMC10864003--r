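test_that("complex expression follows the limiting-subunit convention", {
  x <- rbind(A = c(2, 4, 0, 6), B = c(1, 0, 1, 3), C = c(5, 5, 5, 5))
  nm <- make_nm(x)
  # singleton: ordinary mean and detection fraction
  s <- complex_expression(nm, 1:4, "A")
  expect_equal(s$mean, 3)
  expect_equal(s$expressing_fraction, 0.75)
  # 2-subunit: min of means, all-subunits-detected fraction
  d <- complex_expression(nm, 1:4, c("A", "B"))
  expect_equal(d$mean, min(mean(x["A", ]), mean(x["B", ])))
  expect_equal(d$expressing_fraction, mean(x["A", ] > 0 & x["B", ] > 0))
  # absent subunit: unexpressed by convention
  z <- complex_expression(nm, 1:4, c("A", "MISSING"))
  expect_equal(z, list(mean = 0, expressing_fraction = 0))
  expect_error(complex_expression(nm, integer(0), "A"), "empty population")
})

small_interaction_data <- function(lig_vals, rec_vals, labels) {
  n <- length(labels)
  x <- rbind(L = lig_vals, R = rec_vals, F1 = rep(1, n))
  nm <- make_nm(x)
  cells <- make_cells(n)
  cells$population <- labels
  list(nm = nm, cells = cells,
       db = lr_database("L_R", list("L"), list("R")))
}

test_that("sampled permutation p agrees with the exhaustive oracle on 6 cells", {
  # 3 cells per population, no sample blocking (single sample): the null has
  # choose(6,3) = 20 equally likely label assignments
  lig <- c(5, 4, 6, 0, 1, 0)
  rec <- c(0, 1, 0, 3, 4, 5)
  labels <- c("A", "A", "A", "B", "B", "B")
  d <- small_interaction_data(lig, rec, labels)
  cfg <- interaction_config(n_permutations = 2000, min_cells = 3, seed = 5)
  res <- score_interactions(d$nm, d$cells, d$db, cfg,
                            sources = "A", targets = "B")
  obs <- mean(lig[1:3]) * mean(rec[4:6])
  expect_equal(res$score, obs)

  combos <- utils::combn(6, 3)
  null_scores <- apply(combos, 2, function(a) {
    mean(lig[a]) * mean(rec[setdiff(1:6, a)])
  })
  q <- mean(null_scores >= obs)   # exhaustive exceedance probability
  B <- cfg$n_permutations
  tol <- 3 * sqrt(q * (1 - q) / B) + 2 / B
  expect_lt(abs(res$p_value - q), tol)
})

test_that("interaction scoring conventions and determinism hold", {
  d <- small_interaction_data(c(2, 2, 2, 0, 0, 0), c(0, 0, 0, 2, 2, 2),
                              rep(c("A", "B"), each = 3))
  db <- lr_database(c("L_R", "GHOST_R", "L_GHOST2"),
                    list("L", "GHOST", "L"), list("R", "R", "GHOST2"))
  cfg <- interaction_config(n_permutations = 200, min_cells = 3, seed = 9)
  res <- score_interactions(d$nm, d$cells, db, cfg, "A", "B")
  ghost <- res[res$pair_id != "L_R", ]
  expect_equal(ghost$score, c(0, 0))
  expect_equal(ghost$p_value, c(1, 1))      # absent gene: p fixed at 1
  expect_false(any(ghost$significant))
  expect_true(all(res$p_value >= 1 / (cfg$n_permutations + 1)))

  res2 <- score_interactions(d$nm, d$cells, db, cfg, "A", "B")
  expect_identical(res, res2)               # bit-exact under fixed seed

  # cell order must not matter for observed scores
  perm <- withr::with_seed(2, sample(6))
  resp <- score_interactions(d$nm[, perm], d$cells[perm, ], db, cfg, "A", "B")
  expect_equal(resp$score, res$score)

  expect_error(score_interactions(d$nm, d$cells, db, cfg, "A", "NOPE"),
               "unknown population")
  expect_error(score_interactions(d$nm, d$cells, db,
                                  interaction_config(min_cells = 10, seed = 1),
                                  "A", "B"),
               "below min_cells")
})

test_that("the expressed-fraction gate blocks calls driven by few cells", {
  # ligand very high in 1/10 source cells: score large but fraction 0.1 < 0.2
  lig <- c(50, rep(0, 9), rep(0, 10))
  rec <- c(rep(0, 10), rep(3, 10))
  labels <- rep(c("A", "B"), each = 10)
  d <- small_interaction_data(lig, rec, labels)
  cfg <- interaction_config(min_expressing_fraction = 0.2,
                            n_permutations = 200, seed = 3)
  res <- score_interactions(d$nm, d$cells, d$db, cfg, "A", "B")
  expect_equal(res$expr_frac_ligand, 0.1)
  expect_false(res$significant)
})

test_that("merge keeps the strongest source per pair and target", {
  res <- tibble::tibble(
    source = c("mac", "cDC", "mac"), target = c("T", "T", "T2"),
    pair_id = c("p1", "p1", "p1"),
    ligand_mean = 1, receptor_mean = 1,
    score = c(0.2, 0.5, 0.3), p_value = c(0.01, 0.02, 0.03),
    expr_frac_ligand = 1, expr_frac_receptor = 1, significant = TRUE)
  out <- merge_max_probability(res)
  expect_equal(nrow(out), 2)
  expect_equal(out$source[out$target == "T"], "cDC")
  expect_equal(out$score[out$target == "T"], 0.5)
  one <- merge_max_probability(res[1, ])
  expect_equal(one$score, 0.2)
})

test_that("permutation p-values are uniform under an exchangeable null", {
  # labels carry no information: counts are i.i.d. across cells, so the
  # fraction of p < 0.05 over many (pair, population-pair) tests must sit in
  # the binomial band around the estimator's attainable mass
  set.seed(77)
  n_pop <- 6; per <- 30; n_pairs <- 40
  labels <- rep(paste0("P", seq_len(n_pop)), each = per)
  genes <- paste0("G", seq_len(2 * n_pairs))
  x <- matrix(rexp(length(genes) * length(labels)), length(genes),
              dimnames = list(genes, NULL))
  nm <- make_nm(x)
  cells <- make_cells(length(labels))
  cells$population <- labels
  db <- lr_database(paste0("pr", seq_len(n_pairs)),
                    as.list(genes[seq_len(n_pairs)]),
                    as.list(genes[n_pairs + seq_len(n_pairs)]))
  ps <- c()
  k <- 0
  for (s in paste0("P", seq_len(n_pop))) {
    k <- k + 1
    cfg <- interaction_config(n_permutations = 199, min_cells = 10, seed = 100 + k)
    res <- score_interactions(nm, cells, db, cfg, s,
                              setdiff(paste0("P", seq_len(n_pop)), s))
    ps <- c(ps, res$p_value)
  }
  n <- length(ps)
  expect_gte(n, 1200)
  frac <- mean(ps < 0.05)
  expected <- 9 / 200    # attainable mass below 0.05 with B = 199
  expect_lt(abs(frac - expected), 1.96 * sqrt(expected * (1 - expected) / n) + 0.005)
})
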