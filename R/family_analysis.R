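# Family-level statistics: age classes, the 15-cell unordered pair-context
# table with a Monte-Carlo chi-squared goodness-of-fit test, within-family
# Spearman correlations with BH correction, and distribution comparisons.

#' Family age class from the synonymous substitution rate
#'
#' young: dS < 1; middle-age: 1 <= dS < 2; old: dS >= 2 (the boundary dS = 2
#' is assigned to old).
#'
#' @param dS non-negative numeric vector.
#' @return Ordered factor with levels `young`, `middle-age`, `old`.
#' @export
assign_age_class <- function(dS) {
  if (any(dS < 0)) stop("dS must be non-negative")
  lev <- c("young", "middle-age", "old")
  factor(lev[findInterval(dS, c(0, 1, 2))], levels = lev, ordered = TRUE)
}

# canonical ordering of the 15 unordered category pairs: for i in 1..5,
# j in 1..i (lower-triangle, row-wise, category order of te_categories())
.pair_cells <- function() {
  cats <- te_categories()
  i <- rep(seq_along(cats), seq_along(cats))
  j <- unlist(lapply(seq_along(cats), seq_len))
  data.frame(cat1 = cats[i], cat2 = cats[j],
             cell = paste(cats[i], cats[j], sep = " / "),
             stringsAsFactors = FALSE)
}

#' Count families by the unordered TE-category pair of their members
#'
#' Each family increments exactly one of the 15 unordered cells over the
#' five TE-neighborhood categories; swapping gene1/gene2 leaves the counts
#' unchanged.
#'
#' @param families family table.
#' @param env categorized TE-environment table covering all family genes.
#' @return Named integer vector of 15 counts in canonical cell order, with
#'   attribute `n` = number of families.
#' @export
pair_context_counts <- function(families, env) {
  cat_by_gene <- setNames(as.character(env$category), env$gene_id)
  for (g in c(families$gene1_id, families$gene2_id)) {
    if (is.na(cat_by_gene[g]) || is.null(cat_by_gene[g]))
      stop("gene without an assigned TE category: ", g)
  }
  cats <- te_categories()
  i1 <- match(cat_by_gene[families$gene1_id], cats)
  i2 <- match(cat_by_gene[families$gene2_id], cats)
  hi <- pmax(i1, i2); lo <- pmin(i1, i2)
  cells <- .pair_cells()
  key <- paste(cats[hi], cats[lo], sep = " / ")
  counts <- table(factor(key, levels = cells$cell))
  out <- setNames(as.integer(counts), cells$cell)
  attr(out, "n") <- nrow(families)
  out
}

#' Expected unordered-pair probabilities from category marginals
#'
#' Under the null that the two members of a family draw their categories
#' independently from the marginal distribution p, the unordered pair (i, j)
#' has probability p_i^2 on the diagonal and 2 p_i p_j off the diagonal.
#'
#' @param marginal_counts 5 non-negative counts in [te_categories()] order.
#' @return Named numeric vector of 15 probabilities (canonical cell order),
#'   summing to 1.
#' @export
expected_pair_probs <- function(marginal_counts) {
  if (length(marginal_counts) != length(te_categories()))
    stop("need one marginal count per TE category")
  if (sum(marginal_counts) <= 0) stop("marginal counts are all zero")
  p <- marginal_counts / sum(marginal_counts)
  cells <- .pair_cells()
  cats <- te_categories()
  i <- match(cells$cat1, cats); j <- match(cells$cat2, cats)
  q <- ifelse(i == j, p[i]^2, 2 * p[i] * p[j])
  setNames(q, cells$cell)
}

#' Pearson chi-squared goodness-of-fit statistic
#'
#' X^2 = sum over cells of (O_c - n q_c)^2 / (n q_c), with n = sum of the
#' observed counts. Cells with null probability 0 must have observed count
#' 0 and are excluded from the sum.
#'
#' @param observed non-negative integer counts.
#' @param expected_probs null cell probabilities (same length, summing
#'   to 1).
#' @return The statistic (numeric scalar).
#' @export
chisq_gof <- function(observed, expected_probs) {
  stopifnot(length(observed) == length(expected_probs))
  n <- sum(observed)
  if (n <= 0) stop("observed counts are all zero")
  zero <- expected_probs == 0
  if (any(zero & observed > 0))
    stop("observed count in a cell with expected probability 0")
  E <- n * expected_probs[!zero]
  sum((observed[!zero] - E)^2 / E)
}

#' Monte-Carlo p-value for the goodness-of-fit test
#'
#' Draws B multinomial(n, expected_probs) tables with n = sum(observed),
#' recomputes the chi-squared statistic for each, and returns
#' p = (1 + #\{X2_sim >= X2_obs\}) / (B + 1). With B = 2000 the smallest
#' attainable p-value is 1/2001 ~ 0.0004998.
#'
#' @inheritParams chisq_gof
#' @param B number of Monte-Carlo replicates (default 2000).
#' @param seed optional integer seed (local to the call: the global RNG
#'   state is restored on exit).
#' @return A list: `statistic`, `p.value`, `B`, `n`, `seed`.
#' @export
monte_carlo_pvalue <- function(observed, expected_probs, B = 2000,
                               seed = NULL) {
  stopifnot(B >= 1)
  obs_stat <- chisq_gof(observed, expected_probs)
  n <- sum(observed)
  keep <- expected_probs > 0
  q <- expected_probs[keep]
  E <- n * q
  sims <- with_seed(seed, stats::rmultinom(B, size = n, prob = q))
  stat_sim <- colSums((sims - E)^2 / E)
  list(statistic = obs_stat,
       p.value = (1 + sum(stat_sim >= obs_stat)) / (B + 1),
       B = B, n = n, seed = seed)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the evaluation only and restores the caller's RNG
#' state afterwards; with `seed = NULL` the expression consumes the current
#' stream as usual.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pair-context table and test
#'
#' Builds the 15-cell unordered pair-context table of a family set, derives
#' expected probabilities from a category marginal, and runs the
#' chi-squared goodness-of-fit test with a Monte-Carlo p-value. The
#' marginal source is either the duplicated genes' own category
#' distribution (`"duplicated"`, the default) or the distribution of all
#' genes (`"genome"`).
#'
#' @param families family table.
#' @param env categorized TE-environment table of all genes.
#' @param marginal_source `"duplicated"` or `"genome"`.
#' @param B,seed Monte-Carlo parameters, see [monte_carlo_pvalue()].
#' @return A `pair_context_table` list: `counts`, `n`, `expected_probs`,
#'   `statistic`, `p.value`, `B`, `seed`, `marginal_source`,
#'   `same_fraction` (diagonal mass of the table).
#' @export
pair_context_test <- function(families, env,
                              marginal_source = c("duplicated", "genome"),
                              B = 2000, seed = NULL) {
  marginal_source <- match.arg(marginal_source)
  counts <- pair_context_counts(families, env)
  genes <- if (marginal_source == "duplicated")
    env[env$gene_id %in% c(families$gene1_id, families$gene2_id), ]
  else env
  marg <- table(factor(genes$category, levels = te_categories()))
  q <- expected_pair_probs(as.numeric(marg))
  mc <- monte_carlo_pvalue(as.numeric(counts), as.numeric(q), B = B,
                           seed = seed)
  cells <- .pair_cells()
  structure(list(counts = counts,
                 n = attr(counts, "n"),
                 marginals = setNames(as.integer(marg), te_categories()),
                 expected_probs = q,
                 statistic = mc$statistic,
                 p.value = mc$p.value,
                 B = B, seed = seed,
                 marginal_source = marginal_source,
                 same_fraction =
                   sum(counts[cells$cat1 == cells$cat2]) / sum(counts)),
            class = "pair_context_table")
}

#' @export
print.pair_context_table <- function(x, ...) {
  cat("Pair-context table over", x$n, "families",
      sprintf("(marginals: %s)\n", x$marginal_source))
  cat(sprintf("same-category fraction: %.1f%%\n", 100 * x$same_fraction))
  cat(sprintf("chi-squared = %.2f, Monte-Carlo p = %.6g (B = %d)\n",
              x$statistic, x$p.value, x$B))
  invisible(x)
}

#' Same- vs different-TE-environment partition of families
#'
#' @param families family table.
#' @param env categorized TE-environment table.
#' @return A `data.frame` `family_id`, `same_environment` (logical), with
#'   attribute `fraction` = share of same-environment families (equals the
#'   diagonal mass of the pair-context table).
#' @export
same_environment_partition <- function(families, env) {
  cat_by_gene <- setNames(as.character(env$category), env$gene_id)
  c1 <- cat_by_gene[families$gene1_id]
  c2 <- cat_by_gene[families$gene2_id]
  if (anyNA(c1) || anyNA(c2))
    stop("gene without an assigned TE category")
  out <- data.frame(family_id = families$family_id,
                    same_environment = unname(c1 == c2))
  attr(out, "fraction") <- mean(out$same_environment)
  out
}

#' Within-family Spearman correlation of a per-gene summary
#'
#' Pairs each family's two genes' values and computes the Spearman rank
#' correlation across families. Because "gene 1 vs gene 2" is an arbitrary
#' orientation, each pair is randomly flipped under the given seed before
#' correlating, removing systematic ordering artifacts while staying
#' reproducible. Families with a missing value on either side are dropped.
#'
#' @param values named numeric vector of per-gene summaries (names = gene
#'   ids); `NA` for undefined values.
#' @param families family table.
#' @param seed integer seed for the pair-orientation randomization.
#' @return A list: `rho`, `p.value` (large-sample approximation), `n`
#'   (complete pairs), `computable` (FALSE when fewer than 3 complete
#'   pairs).
#' @export
within_family_correlation <- function(values, families, seed = NULL) {
  x <- unname(values[families$gene1_id])
  y <- unname(values[families$gene2_id])
  flip <- with_seed(seed, stats::runif(nrow(families)) < 0.5)
  tmp <- x[flip]; x[flip] <- y[flip]; y[flip] <- tmp
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3)
    return(list(rho = NA_real_, p.value = NA_real_, n = sum(ok),
                computable = FALSE))
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = sum(ok),
       computable = TRUE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] with `method = "BH"`), applied within one declared
#' battery of hypotheses.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare distributions across groups
#'
#' Two groups: two-sample Kolmogorov-Smirnov test. More than two groups:
#' Kruskal-Wallis rank-sum test (the H statistic is reported as a
#' chi-squared with #groups - 1 degrees of freedom). A group with fewer
#' than 2 observations renders the comparison not computable.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor; empty levels dropped).
#' @return A list: `method` (`"ks"` or `"kruskal"`), `statistic`, `df`
#'   (Kruskal-Wallis only), `p.value`, `computable`.
#' @export
distribution_comparisons <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    return(list(method = NA_character_, statistic = NA_real_, df = NA_real_,
                p.value = NA_real_, computable = FALSE))
  if (nlevels(groups) == 2) {
    lv <- levels(groups)
    kt <- suppressWarnings(stats::ks.test(values[groups == lv[1]],
                                          values[groups == lv[2]]))
    list(method = "ks", statistic = unname(kt$statistic), df = NA_real_,
         p.value = kt$p.value, computable = TRUE)
  } else {
    kw <- stats::kruskal.test(values, groups)
    list(method = "kruskal", statistic = unname(kw$statistic),
         df = unname(kw$parameter), p.value = kw$p.value, computable = TRUE)
  }
}
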