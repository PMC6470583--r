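test_that("age classes split at dS = 1 and 2, with dS = 2 old", {
  expect_equal(as.character(assign_age_class(c(0.5, 1.5, 2.5))),
               c("young", "middle-age", "old"))
  expect_equal(as.character(assign_age_class(c(0, 1, 2))),
               c("young", "middle-age", "old"))
  expect_error(assign_age_class(-0.1), "non-negative")
})

test_that("pair-context counts are unordered and order-invariant", {
  env <- data.frame(gene_id = paste0("g", 1:6),
                    density = c(0, 0, 1e-4, 1e-3, 1e-4, 1e-3),
                    coverage = c(0, 0, 0.1, 0.3, 0.1, 0.3),
                    category = factor(c("TE-free", "TE-free",
                                        "TE-very-poor", "TE-rich",
                                        "TE-very-poor", "TE-rich"),
                                      levels = te_categories()))
  fam <- data.frame(family_id = c("F1", "F2", "F3"),
                    gene1_id = c("g1", "g3", "g5"),
                    gene2_id = c("g2", "g4", "g6"))
  counts <- pair_context_counts(fam, env)
  expect_equal(sum(counts), 3)
  expect_equal(unname(counts["TE-free / TE-free"]), 1L)
  expect_equal(unname(counts["TE-rich / TE-very-poor"]), 2L)
  swapped <- fam
  swapped$gene1_id <- fam$gene2_id
  swapped$gene2_id <- fam$gene1_id
  expect_equal(pair_context_counts(swapped, env),
               pair_context_counts(fam, env),
               ignore_attr = TRUE)
  expect_equal(pair_context_counts(fam[c(3, 1, 2), ], env),
               counts, ignore_attr = TRUE)
  bad <- fam
  bad$gene2_id[1] <- "missing_gene"
  expect_error(pair_context_counts(bad, env), "missing_gene")
})

test_that("expected pair probabilities follow the binomial expansion", {
  q <- expected_pair_probs(c(1, 1, 0, 0, 0))
  expect_equal(unname(q["TE-free / TE-free"]), 0.25)
  expect_equal(unname(q["TE-very-poor / TE-free"]), 0.5)
  expect_equal(unname(q["TE-very-poor / TE-very-poor"]), 0.25)
  expect_equal(sum(q), 1)

  one <- expected_pair_probs(c(0, 0, 5, 0, 0))
  expect_equal(unname(one["TE-poor / TE-poor"]), 1)

  expect_equal(sum(expected_pair_probs(published_marginals())), 1)
  expect_error(expected_pair_probs(rep(0, 5)), "zero")
})

test_that("chi-squared statistic matches direct arithmetic and the brute oracle", {
  # exact fit
  q <- expected_pair_probs(c(2, 2, 2, 2, 2))
  expect_equal(chisq_gof(q * 1000, q), 0)
  # 3-cell toy: q = (1/4, 1/2, 1/4), O = (30, 40, 30)
  expect_equal(chisq_gof(c(30, 40, 30), c(0.25, 0.5, 0.25)), 4)
  # random tables against sum((O - E)^2 / E)
  set.seed(112)
  for (i in 1:40) {
    k <- sample(3:15, 1)
    q <- stats::rgamma(k, 1); q <- q / sum(q)
    O <- as.numeric(stats::rmultinom(1, 500, q))
    E <- 500 * q
    expect_equal(chisq_gof(O, q), sum((O - E)^2 / E), tolerance = 1e-9)
  }
  expect_error(chisq_gof(c(1, 1), c(1, 0)), "probability 0")
})

test_that("Monte-Carlo p-values are reproducible, lattice-valued, and match chisq.test", {
  q <- as.numeric(expected_pair_probs(published_marginals()))
  O <- published_pair_counts()
  r1 <- monte_carlo_pvalue(O, q, B = 200, seed = 9)
  r2 <- monte_carlo_pvalue(O, q, B = 200, seed = 9)
  expect_identical(r1$p.value, r2$p.value)
  expect_true(r1$p.value %in% (seq_len(201) / 201))
  # a perfectly fitting table (statistic 0) has p = 1
  q_unif <- as.numeric(expected_pair_probs(c(2, 2, 2, 2, 2)))
  expect_equal(monte_carlo_pvalue(q_unif * 2500, q_unif, B = 99,
                                  seed = 1)$p.value, 1)
  # cross-check against the standard simulated chi-squared test on a toy
  # table where replicates can exceed the observed statistic
  toy_q <- c(0.25, 0.5, 0.25)
  toy_O <- c(32, 48, 20)
  mine <- monte_carlo_pvalue(toy_O, toy_q, B = 5000, seed = 2)
  ref <- stats::chisq.test(toy_O, p = toy_q, simulate.p.value = TRUE,
                           B = 5000)
  expect_equal(mine$statistic, unname(ref$statistic))
  # both p-values are Monte-Carlo estimates (sd ~ 0.006 at B = 5000)
  expect_lt(abs(mine$p.value - ref$p.value), 0.03)
})

test_that("same-environment partition equals the diagonal of the pair table", {
  counts <- published_pair_counts()
  diag_cells <- c(1, 3, 6, 10, 15)
  expect_equal(sum(counts[diag_cells]), 453)
  expect_equal(round(100 * sum(counts[diag_cells]) / sum(counts), 1), 31.9)

  env <- shared_env()
  b <- shared_bundle()
  part <- same_environment_partition(b$families, env)
  pct <- pair_context_test(b$families, env, B = 19, seed = 1)
  expect_equal(attr(part, "fraction"), pct$same_fraction)
  expect_equal(nrow(part), nrow(b$families))
})

test_that("within-family correlation recovers exact and degenerate cases", {
  fam <- data.frame(family_id = paste0("F", 1:10),
                    gene1_id = paste0("a", 1:10),
                    gene2_id = paste0("b", 1:10))
  v1 <- stats::setNames(1:10, fam$gene1_id)
  same <- c(v1, stats::setNames(1:10, fam$gene2_id))
  expect_equal(within_family_correlation(same, fam, seed = 1)$rho, 1)
  anti <- c(v1, stats::setNames(-(1:10), fam$gene2_id))
  expect_equal(within_family_correlation(anti, fam, seed = 1)$rho, -1)
  # fewer than 3 complete pairs is not computable
  few <- same
  few[paste0("b", 3:10)] <- NA
  r <- within_family_correlation(few, fam, seed = 1)
  expect_false(r$computable)
  expect_true(is.na(r$rho))
})

test_that("BH adjustment reproduces the step-up arithmetic and brute oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  set.seed(113)
  for (i in 1:20) {
    p <- stats::runif(sample(2:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone along sorted p-values
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(1.5), "0, 1")
})

test_that("distribution comparisons dispatch KS for 2 groups, KW for more", {
  x <- c(stats::rnorm(50), stats::rnorm(50))
  g2 <- rep(c("a", "b"), each = 50)
  same <- distribution_comparisons(c(1:50, 1:50), g2)
  expect_equal(same$method, "ks")
  expect_equal(same$statistic, 0)
  sep <- distribution_comparisons(c(1:50, 101:150), g2)
  expect_equal(sep$statistic, 1)

  g3 <- rep(c("a", "b", "c"), each = 30)
  kw <- distribution_comparisons(stats::rnorm(90), g3)
  expect_equal(kw$method, "kruskal")
  expect_equal(kw$df, 2)
  # degenerate group sizes are flagged
  expect_false(distribution_comparisons(1:3, c("a", "a", "b"))$computable)
})

test_that("KW p-values are roughly uniform under the null", {
  set.seed(114)
  p <- replicate(300, {
    distribution_comparisons(stats::rnorm(60),
                             rep(c("a", "b", "c"), each = 20))$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.001)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
})
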