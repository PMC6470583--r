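# End-to-end orchestration: TE classification, epigenetic and expression
# summaries, family-level tests, and report artifacts.

#' Pipeline configuration
#'
#' All defaults equal the analysis constants: 2 kb flanks, k = 4 medoids,
#' methylation status thresholds 0.25/0.75, expression threshold FPKM 0.5,
#' age-class dS thresholds 1 and 2, B = 2000 Monte-Carlo replicates, and
#' expected pair probabilities from the duplicated genes' own category
#' marginals.
#'
#' @param flank flanking width (bp) of the TE neighborhood.
#' @param k number of k-medoids clusters for non-TE-free genes.
#' @param methylation_thresholds `c(hypo, hyper)` gene-status cutoffs.
#' @param expression_threshold FPKM cutoff for the expressed flag.
#' @param age_thresholds dS boundaries between young/middle-age/old.
#' @param B Monte-Carlo replicates for the pair-context test.
#' @param marginal_source `"duplicated"` or `"genome"`; which category
#'   marginal feeds [expected_pair_probs()].
#' @param standardize z-score (density, coverage) before clustering.
#' @param seed master seed for the Monte-Carlo test and the pair-orientation
#'   randomization of the correlation analyses.
#' @return A `duplite_pipeline_config` list.
#' @export
pipeline_config <- function(flank = 2000,
                            k = 4,
                            methylation_thresholds = c(0.25, 0.75),
                            expression_threshold = 0.5,
                            age_thresholds = c(1, 2),
                            B = 2000,
                            marginal_source = c("duplicated", "genome"),
                            standardize = FALSE,
                            seed = 1L) {
  stopifnot(methylation_thresholds[1] < methylation_thresholds[2],
            age_thresholds[1] < age_thresholds[2])
  marginal_source <- match.arg(marginal_source)
  structure(as.list(environment()), class = "duplite_pipeline_config")
}

#' Run the full analysis on an input bundle
#'
#' Stages: (1) TE density/coverage per gene and five-category
#' classification; (2) category distribution and family pair-context table
#' with the Monte-Carlo chi-squared test; (3) per-gene epigenetic summaries;
#' (4) expression TPM, expressed flags, per-family Manhattan divergence;
#' (5) within-family Spearman correlations of every cell type x mark (and
#' methylation), split by all / same-TE-environment /
#' different-TE-environment, with BH q-values per table; (6) distribution
#' comparisons (d_m across age classes, omega between same and different TE
#' environments); (7) gene-pair physical distances.
#'
#' @param bundle a `duplite_bundle` (from [simulate_te_dataset()],
#'   [read_bundle()] or built by hand).
#' @param config a [pipeline_config()].
#' @return A `duplite_report` list; see the individual elements.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  genes <- bundle$genes
  families <- bundle$families
  # stage: TE environment
  env <- te_environment(genes, bundle$tes, flank = config$flank,
                        chrom_sizes = bundle$chrom_sizes)
  model <- fit_category_model(env, k = config$k,
                              standardize = config$standardize,
                              seed = config$seed)
  env <- assign_categories(env, model)
  # stage: family context
  pct <- pair_context_test(families, env,
                           marginal_source = config$marginal_source,
                           B = config$B, seed = config$seed)
  partition <- same_environment_partition(families, env)
  families$same_environment <- partition$same_environment
  families$age_class <- assign_age_class(families$dS)
  # stage: physical distances
  g1 <- genes[match(families$gene1_id, genes$gene_id), ]
  g2 <- genes[match(families$gene2_id, genes$gene_id), ]
  distances <- cbind(family_id = families$family_id,
                     gene_pair_distance(g1, g2))
  # stage: epigenome
  epi <- summarize_epigenome(genes, bundle$enrichment, bundle$methylation,
                             hypo = config$methylation_thresholds[1],
                             hyper = config$methylation_thresholds[2])
  # stage: expression
  tpm <- fpkm_to_tpm(bundle$fpkm)
  expressed <- is_expressed(bundle$fpkm,
                            threshold = config$expression_threshold)
  divergence <- family_divergence(bundle$fpkm, families)
  divergence$age_class <-
    families$age_class[match(divergence$family_id, families$family_id)]
  divergence$same_environment <-
    families$same_environment[match(divergence$family_id,
                                    families$family_id)]
  # stage: within-family correlations
  correlations <- correlation_battery(epi, families, seed = config$seed)
  # stage: distribution comparisons
  comparisons <- list(
    d_m_by_age = distribution_comparisons(divergence$d_m,
                                          divergence$age_class),
    d_m_by_age_same = with(divergence[divergence$same_environment, ],
                           distribution_comparisons(d_m, age_class)),
    d_m_by_age_different = with(divergence[!divergence$same_environment, ],
                                distribution_comparisons(d_m, age_class)),
    omega_same_vs_different = distribution_comparisons(
      families$omega,
      ifelse(families$same_environment, "same", "different")))
  structure(list(env = env,
                 model = model,
                 category_distribution = category_distribution(env),
                 pair_context = pct,
                 same_fraction = attr(partition, "fraction"),
                 distances = distances,
                 epigenome = epi,
                 tpm = tpm,
                 expressed = expressed,
                 divergence = divergence,
                 correlations = correlations,
                 comparisons = comparisons,
                 families = families,
                 config = config),
            class = "duplite_report")
}

#' Within-family correlation battery over epigenetic summaries
#'
#' One Spearman test per cell type x mark x partition (all /
#' same-TE-environment / different-TE-environment) on mean enrichment, plus
#' one per cell type x partition on the gene methylation mean. BH q-values
#' are computed within the enrichment table and within the methylation
#' table (two hypothesis families, mirroring the two report tables).
#'
#' @param epi output of [summarize_epigenome()].
#' @param families family table with a logical `same_environment` column.
#' @param seed orientation-randomization seed.
#' @return A `data.frame`: `measure`, `cell_type`, `mark`, `partition`,
#'   `rho`, `p`, `q`, `n`.
#' @export
correlation_battery <- function(epi, families, seed = NULL) {
  partitions <- list(all = rep(TRUE, nrow(families)),
                     same = families$same_environment,
                     different = !families$same_environment)
  res <- list()
  for (ct in unique(epi$enrichment$cell_type)) {
    for (mk in unique(epi$enrichment$mark)) {
      sub <- epi$enrichment[epi$enrichment$cell_type == ct &
                              epi$enrichment$mark == mk, ]
      vals <- setNames(sub$mean_enrichment, sub$gene_id)
      for (pn in names(partitions)) {
        r <- within_family_correlation(vals, families[partitions[[pn]], ],
                                       seed = seed)
        res[[length(res) + 1]] <-
          data.frame(measure = "enrichment", cell_type = ct, mark = mk,
                     partition = pn, rho = r$rho, p = r$p.value, n = r$n)
      }
    }
  }
  for (ct in unique(epi$methylation$cell_type)) {
    sub <- epi$methylation[epi$methylation$cell_type == ct, ]
    vals <- setNames(sub$methylation_mean, sub$gene_id)
    for (pn in names(partitions)) {
      r <- within_family_correlation(vals, families[partitions[[pn]], ],
                                     seed = seed)
      res[[length(res) + 1]] <-
        data.frame(measure = "methylation", cell_type = ct, mark = NA,
                   partition = pn, rho = r$rho, p = r$p.value, n = r$n)
    }
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  for (ms in unique(out$measure)) {
    i <- out$measure == ms
    out$q[i] <- bh_adjust(out$p[i])
  }
  out
}

#' @export
print.duplite_report <- function(x, ...) {
  cat("dupliTE report:", nrow(x$env), "genes,",
      nrow(x$families), "families\n\n")
  print(x$category_distribution)
  cat("\n")
  print(x$pair_context)
  invisible(x)
}

#' Pair-context test straight from printed category tables
#'
#' Entry point for running the pair-context goodness-of-fit machinery on
#' already-tabulated counts (no interval data needed): supply the 5
#' category marginal counts and the 15 unordered pair counts in canonical
#' cell order (see `dupliTE:::.pair_cells()`; lower-triangle, row-wise).
#'
#' @param marginals 5 gene counts per TE category.
#' @param pair_counts 15 family counts per unordered category pair.
#' @param B,seed Monte-Carlo parameters.
#' @return A list: `statistic`, `p.value`, `B`, `n`, `same_fraction`,
#'   `expected_probs`, `seed`.
#' @export
from_printed_tables <- function(marginals, pair_counts, B = 2000,
                                seed = NULL) {
  q <- expected_pair_probs(marginals)
  mc <- monte_carlo_pvalue(pair_counts, as.numeric(q), B = B, seed = seed)
  cells <- .pair_cells()
  list(statistic = mc$statistic,
       p.value = mc$p.value,
       B = B,
       n = mc$n,
       same_fraction = sum(pair_counts[cells$cat1 == cells$cat2]) /
         sum(pair_counts),
       expected_probs = q,
       seed = seed)
}

#' Write report artifacts to a directory
#'
#' Emits the machine-readable results: per-gene TE table
#' (`te_environment.tsv`), category distribution
#' (`category_distribution.tsv`), category model (`category_model.json`),
#' pair-context table and test (`pair_context.tsv`,
#' `pair_context_test.json`), correlation battery (`correlations.tsv`),
#' per-family divergence (`divergence.tsv`) and distribution comparisons
#' (`comparisons.json`). Every statistics JSON echoes seed and B.
#'
#' @param report a `duplite_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$env, "te_environment.tsv")
  tsv(report$category_distribution, "category_distribution.tsv")
  jsonlite::write_json(list(k = report$model$k,
                            medoids = report$model$medoids,
                            labels = report$model$labels,
                            objective = report$model$objective,
                            standardize = report$model$standardize),
                       file.path(dir, "category_model.json"),
                       auto_unbox = TRUE, digits = NA)
  pc <- report$pair_context
  tsv(data.frame(cell = names(pc$counts), observed = as.integer(pc$counts),
                 expected = pc$n * as.numeric(pc$expected_probs)),
      "pair_context.tsv")
  jsonlite::write_json(list(statistic = pc$statistic, p.value = pc$p.value,
                            B = pc$B, n = pc$n, seed = pc$seed,
                            marginal_source = pc$marginal_source,
                            same_fraction = pc$same_fraction),
                       file.path(dir, "pair_context_test.json"),
                       auto_unbox = TRUE, digits = NA)
  tsv(report$correlations, "correlations.tsv")
  tsv(report$divergence, "divergence.tsv")
  jsonlite::write_json(c(report$comparisons,
                         list(seed = report$config$seed,
                              B = report$config$B)),
                       file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
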