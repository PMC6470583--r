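test_that("density and coverage match the worked neighborhood examples", {
  g <- gene_records("G1", "chr1", 10000, 11000)

  none <- te_environment(g, te_insertions(character(), character(),
                                          numeric(), numeric())[0, ])
  expect_equal(none$density, 0)
  expect_equal(none$coverage, 0)

  t1 <- te_insertions(c("a", "b"), "chr1", c(8500, 12000), c(9000, 12500))
  e1 <- te_environment(g, t1, flank = 2000)
  expect_equal(e1$region_start, 8000)
  expect_equal(e1$region_end, 13000)
  expect_equal(e1$density, 2 / 5000)
  expect_equal(e1$coverage, 0.2)

  # overlapping TEs crossing the region edge: union semantics
  t2 <- te_insertions(c("a", "b"), "chr1", c(7500, 8400), c(8500, 8600))
  e2 <- te_environment(g, t2, flank = 2000)
  expect_equal(e2$density, 2 / 5000)
  expect_equal(e2$coverage, 600 / 5000)
})

test_that("metrics agree with the per-base brute-force oracle on random fixtures", {
  # 120 independent fixtures, one per chromosome, analysed in a single call
  set.seed(104)
  n_fix <- 120
  gs <- sample.int(3000, n_fix, replace = TRUE) + 500
  ge <- gs + sample.int(1500, n_fix, replace = TRUE)
  genes <- gene_records(sprintf("g%03d", 1:n_fix),
                        sprintf("chr%03d", 1:n_fix), gs, ge)
  te_list <- lapply(1:n_fix, function(i) {
    n_te <- sample(0:8, 1)
    if (n_te == 0) return(NULL)
    ts <- sample.int(6000, n_te, replace = TRUE)
    data.frame(chrom = sprintf("chr%03d", i), start = ts,
               end = ts + sample.int(700, n_te, replace = TRUE))
  })
  all_te <- do.call(rbind, te_list)
  tes <- te_insertions(sprintf("t%04d", seq_len(nrow(all_te))),
                       all_te$chrom, all_te$start, all_te$end)
  env <- te_environment(genes, tes, flank = 300)
  for (i in 1:n_fix) {
    sub <- all_te[all_te$chrom == sprintf("chr%03d", i) &
                    all_te$start < env$region_end[i] &
                    all_te$end > env$region_start[i], ]
    oracle <- brute_te_metrics(env$region_start[i], env$region_end[i],
                               sub$start, sub$end)
    expect_equal(env$density[i], oracle$density, tolerance = 1e-12)
    expect_equal(env$coverage[i], oracle$coverage, tolerance = 1e-12)
    expect_lte(env$coverage[i], 1)
  }
})

test_that("regions clip at zero and at supplied chromosome ends", {
  g <- gene_records(c("a", "b"), "chr1", c(500, 9000), c(1500, 9800))
  env <- te_environment(g, te_insertions("t", "chr1", 0, 100),
                        flank = 2000,
                        chrom_sizes = c(chr1 = 10000))
  expect_equal(env$region_start, c(0, 7000))
  expect_equal(env$region_end, c(3500, 10000))
  expect_equal(env$density[1], 1 / 3500)
  expect_equal(env$coverage[1], 100 / 3500)
})

test_that("adding an intersecting TE never decreases density or coverage", {
  set.seed(105)
  g <- gene_records("g", "chr1", 5000, 8000)
  tes <- te_insertions(paste0("t", 1:4), "chr1",
                       c(3500, 6000, 6100, 9500), c(4200, 6600, 6400, 9900))
  for (i in 1:8) {
    keep <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    sub <- tes[keep, , drop = FALSE]
    new_start <- sample(3000:9000, 1)
    extra <- rbind(sub, te_insertions("x", "chr1", new_start,
                                      new_start + 400)[,
                                        c("te_id", "chrom", "start", "end",
                                          "strand", "family_label")])
    e_before <- te_environment(g, sub)
    e_after <- te_environment(g, extra)
    expect_gte(e_after$density, e_before$density)
    expect_gte(e_after$coverage, e_before$coverage)
  }
})

test_that("PAM objective equals the exhaustive-search optimum on small separable instances", {
  set.seed(106)
  for (i in 1:15) {
    centers <- matrix(c(1e-4, 0.05, 5e-4, 0.15, 1e-3, 0.3, 2e-3, 0.45),
                      ncol = 2, byrow = TRUE)
    n_per <- 2
    pts <- do.call(rbind, lapply(1:4, function(c.)
      cbind(centers[c., 1] + stats::rnorm(n_per, 0, 1e-5),
            centers[c., 2] + stats::rnorm(n_per, 0, 1e-3))))
    pts <- pmax(pts, 1e-6)
    env <- data.frame(gene_id = seq_len(nrow(pts)), density = pts[, 1],
                      coverage = pts[, 2])
    model <- fit_category_model(env, k = 4)
    expect_equal(model$objective, brute_medoid_objective(pts, 4),
                 tolerance = 1e-10)
  }
})

test_that("separable blobs map to density-ordered labels and medoids are input points", {
  set.seed(107)
  dens <- c(rep(1e-4, 3), rep(5e-4, 3), rep(1.2e-3, 3), rep(2.5e-3, 3)) +
    stats::runif(12, 0, 2e-5)
  cov <- c(rep(0.08, 3), rep(0.2, 3), rep(0.3, 3), rep(0.42, 3)) +
    stats::runif(12, 0, 5e-3)
  env <- data.frame(gene_id = sprintf("g%02d", 1:12), density = dens,
                    coverage = cov)
  model <- fit_category_model(env, k = 4)
  # medoid rows are members of the input set
  for (m in seq_len(4)) {
    match_found <- any(abs(env$density - model$medoids$density[m]) < 1e-15 &
                         abs(env$coverage - model$medoids$coverage[m]) <
                           1e-15)
    expect_true(match_found)
  }
  expect_equal(model$labels,
               c("TE-very-poor", "TE-poor", "TE-rich", "TE-very-rich"))
  assigned <- assign_categories(env, model)
  expect_equal(as.character(assigned$category),
               rep(c("TE-very-poor", "TE-poor", "TE-rich", "TE-very-rich"),
                   each = 3))
})

test_that("all-identical points except k distinct ones make those the medoids", {
  env <- data.frame(gene_id = 1:9,
                    density = c(rep(1e-4, 5), 6e-4, 1.1e-3, 2e-3, 3e-3),
                    coverage = c(rep(0.1, 5), 0.2, 0.3, 0.4, 0.5))
  model <- fit_category_model(env, k = 4)
  expect_equal(model$objective, brute_medoid_objective(
    env[, c("density", "coverage")], 4), tolerance = 1e-12)
  # the duplicated point must be one of the medoids (cost of its copies is 0)
  expect_true(any(model$medoids$density == 1e-4 &
                    model$medoids$coverage == 0.1))
})

test_that("assignment is TE-free by rule, deterministic, tie-broken by label order", {
  env <- data.frame(gene_id = 1:4,
                    density = c(1e-4, 1e-3, 2e-3, 3e-3),
                    coverage = c(0.1, 0.2, 0.3, 0.4))
  model <- fit_category_model(env, k = 4)
  free <- assign_categories(data.frame(gene_id = "z", density = 0,
                                       coverage = 0), model)
  expect_equal(as.character(free$category), "TE-free")
  # a point equal to a medoid takes its label
  onmed <- assign_categories(env, model)
  expect_equal(as.character(onmed$category),
               c("TE-very-poor", "TE-poor", "TE-rich", "TE-very-rich"))
  # an exactly equidistant point goes to the lower-index label; use
  # binary-exact coordinates so the two distances are bit-identical
  env2 <- data.frame(gene_id = 1:4,
                     density = c(0.25, 0.75, 2, 4),
                     coverage = c(0.5, 0.5, 0.5, 0.5))
  model2 <- fit_category_model(env2, k = 4)
  mid <- data.frame(gene_id = "m", density = 0.5, coverage = 0.5)
  expect_equal(as.character(assign_categories(mid, model2)$category),
               "TE-very-poor")
})

test_that("fitting requires at least k distinct non-free points", {
  env <- data.frame(gene_id = 1:6, density = rep(c(1e-4, 2e-4), 3),
                    coverage = rep(c(0.1, 0.2), 3))
  expect_error(fit_category_model(env, k = 4), "distinct")
})

test_that("category distribution sums to the gene count and ignores input order", {
  env <- shared_env()
  dist <- category_distribution(env)
  expect_equal(sum(dist$count), nrow(env))
  expect_equal(sum(dist$percent), 100)
  shuffled <- category_distribution(env[sample.int(nrow(env)), ])
  expect_equal(shuffled$count, dist$count)
})

test_that("published category counts give the published percentages", {
  counts <- c(109, 713, 915, 729, 374)
  printed <- c(3.84, 25.10, 32.22, 25.67, 13.17)
  expect_true(all(abs(100 * counts / sum(counts) - printed) < 0.01))
})
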