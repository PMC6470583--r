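# Seeded synthetic input bundles emulating the structure of the real data:
# genes and Poisson-placed TE insertions on a small multi-chromosome genome,
# two-gene families with a controllable probability of sharing a TE
# category, copula-correlated epigenetic summaries, beta-profiled
# methylation regions, Dirichlet expression profiles whose divergence grows
# with family age, and dS/dN tables spanning the three age classes.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the analysed data at reduced genome scale: ~4000 genes
#' over four 60-Mb chromosomes (so the 1420 two-gene families hold 2840
#' genes, as in the real family set), lognormal gene lengths (median
#' ~20 kb), TE insertions at 8e-4 per bp with ~300 bp lognormal lengths
#' (giving density/coverage in the range of the reported category means),
#' family dS mixture weights (99, 189, 1132)/1420 over young/middle-age/old,
#' per-mark within-family rank correlations near the reported all-duplicate
#' correlations, and a 31.9% target same-category fraction.
#'
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @param n_chromosomes,chromosome_length genome shape.
#' @param n_genes number of genes (>= 2 * n_families).
#' @param gene_length_meanlog,gene_length_sdlog lognormal gene-length
#'   parameters (bp).
#' @param te_rate expected TE insertions per bp inside gene neighborhoods;
#'   0 makes every gene TE-free.
#' @param te_length_meanlog,te_length_sdlog lognormal TE-length parameters.
#' @param te_rate_sdlog spread of the per-gene lognormal rate multiplier
#'   creating TE-poor vs TE-rich neighborhoods.
#' @param flank neighborhood flank used when inducing shared TE categories
#'   (must match the analysis flank).
#' @param n_families number of two-gene families.
#' @param p_same_category target probability that the two members of a
#'   family fall in the same TE-neighborhood category.
#' @param rho_epigenome named per-mark target within-family Spearman
#'   correlation of mean enrichment (scalar recycled over marks).
#' @param rho_methylation target within-family Spearman correlation of the
#'   gene methylation mean.
#' @param p_methylation_missing probability a gene has no methylation
#'   region call in a cell type.
#' @param enrichment_shape,enrichment_rate gamma marginal of per-gene mean
#'   fold enrichment.
#' @param dS_weights mixture weights over (young, middle-age, old).
#' @param dirichlet_concentration per-age-class concentration of member
#'   expression profiles around the family profile; larger means less
#'   expression divergence (d_m decreases), so values decrease with age.
#' @param fpkm_scale median per-gene total FPKM.
#' @param p_family_silent probability both members are silent in all cell
#'   types; `p_gene_silent` is the additional independent per-member
#'   silencing probability.
#' @param p_gene_silent see above.
#' @param cell_types names of the four cell types.
#' @return A `duplite_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_chromosomes = 4,
                             chromosome_length = 6e7,
                             n_genes = 4000,
                             gene_length_meanlog = log(2e4),
                             gene_length_sdlog = 0.75,
                             te_rate = 8e-4,
                             te_length_meanlog = log(300),
                             te_length_sdlog = 0.7,
                             te_rate_sdlog = 0.9,
                             flank = 2000,
                             n_families = 1420,
                             p_same_category = 0.319,
                             rho_epigenome = c(H3K27me3 = 0.32,
                                               H3K9me3 = 0.15,
                                               H3K27ac = 0.25,
                                               H3K4me1 = 0.22,
                                               H3K4me3 = 0.34,
                                               H3K36me3 = 0.30),
                             rho_methylation = 0.16,
                             p_methylation_missing = 0.10,
                             enrichment_shape = 2,
                             enrichment_rate = 1,
                             dS_weights = c(young = 99, `middle-age` = 189,
                                            old = 1132) / 1420,
                             dirichlet_concentration = c(young = 80,
                                                         `middle-age` = 30,
                                                         old = 8),
                             fpkm_scale = 10,
                             p_family_silent = 267 / 1420,
                             p_gene_silent = 0.08,
                             cell_types = c("CD14", "erythroblast", "CD8T",
                                            "macrophage")) {
  if (length(rho_epigenome) == 1)
    rho_epigenome <- setNames(rep(rho_epigenome, length(histone_marks())),
                              histone_marks())
  stopifnot(te_rate >= 0,
            p_same_category >= 0, p_same_category <= 1,
            all(abs(rho_epigenome) < 1), abs(rho_methylation) < 1,
            abs(sum(dS_weights) - 1) < 1e-8,
            n_genes >= 2 * n_families,
            length(cell_types) == 4)
  structure(as.list(environment()), class = "duplite_config")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  # a zero row (all shapes tiny) is resampled from a flat profile
  z <- rowSums(x) == 0
  if (any(z)) x[z, ] <- matrix(stats::rgamma(sum(z) * length(alpha), 1, 1),
                               nrow = sum(z))
  x / rowSums(x)
}

# Spearman target -> latent bivariate-normal correlation (Gaussian copula)
.latent_r <- function(rho_s) 2 * sin(pi * rho_s / 6)

# correlated standard-normal pairs for family members, independent values
# for the rest; gene1/gene2 indices into 1..n
.copula_u <- function(n, i1, i2, rho_s) {
  z <- stats::rnorm(n)
  r <- .latent_r(rho_s)
  z[i2] <- r * z[i1] + sqrt(1 - r^2) * stats::rnorm(length(i2))
  stats::pnorm(z)
}

#' Generate a complete synthetic input bundle
#'
#' Deterministic under `config$seed`. Genes are placed without overlap
#' within each chromosome; TE insertions are Poisson-placed inside each
#' gene's flanked neighborhood with a per-gene lognormal rate multiplier;
#' family members share the member-1 gene length, and for a calibrated
#' subset of families member 2's neighborhood TE layout is a translated
#' copy of member 1's so that the realized same-category fraction tracks
#' `p_same_category`; epigenetic summaries are Gaussian-copula-correlated
#' within families; expression profiles are Dirichlet draws around a family
#' profile with concentration decreasing over age classes, so expression
#' divergence grows with dS.
#'
#' @param config a [generator_config()].
#' @return A `duplite_bundle` list: `genes`, `tes`, `families`,
#'   `chrom_sizes`, `fpkm` (matrix genes x cell types), `enrichment`
#'   (nested list cell type -> mark -> track), `methylation` (list cell
#'   type -> region table), `config`.
#' @export
simulate_te_dataset <- function(config = generator_config()) {
  with_seed(config$seed, .simulate_bundle(config))
}

.simulate_bundle <- function(cf) {
  n <- cf$n_genes
  chroms <- paste0("chr", seq_len(cf$n_chromosomes))
  chrom_sizes <- data.frame(chrom = chroms,
                            size = rep(cf$chromosome_length,
                                       cf$n_chromosomes))
  gene_id <- sprintf("G%05d", seq_len(n))
  len <- pmax(200, round(stats::rlnorm(n, cf$gene_length_meanlog,
                                       cf$gene_length_sdlog)))

  # family pairing decided first so member lengths can be tied
  members <- matrix(sample.int(n, 2 * cf$n_families), ncol = 2)
  len[members[, 2]] <- len[members[, 1]]

  chrom_of <- sample(chroms, n, replace = TRUE)
  start <- numeric(n); end <- numeric(n)
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    if (length(idx) == 0) next
    L <- cf$chromosome_length
    free <- L - sum(len[idx]) - length(idx)
    if (free < 0)
      stop("infeasible packing: genes exceed capacity of ", ch)
    gaps <- diff(c(0, sort(stats::runif(length(idx))))) * free
    s <- round(cumsum(gaps) + cumsum(c(0, len[idx][-length(idx)] + 1)))
    start[idx] <- s
    end[idx] <- s + len[idx]
  }
  genes <- gene_records(gene_id, chrom_of, start, end,
                        strand = sample(c("+", "-"), n, replace = TRUE))

  # neighborhood TE fields with per-gene rate multipliers
  rs <- pmax(0, start - cf$flank)
  re <- pmin(cf$chromosome_length, end + cf$flank)
  mult <- stats::rlnorm(n, -cf$te_rate_sdlog^2 / 2, cf$te_rate_sdlog)
  tes <- .simulate_tes(cf, genes, rs, re, mult)

  families <- data.frame(family_id = sprintf("F%04d",
                                             seq_len(cf$n_families)),
                         gene1_id = gene_id[members[, 1]],
                         gene2_id = gene_id[members[, 2]],
                         stringsAsFactors = FALSE)

  tes <- .induce_shared_categories(cf, genes, tes, members, rs, re)

  families <- cbind(families, .simulate_divergence(cf))
  families <- validate_families(families)

  fam_ages <- assign_age_class(families$dS)
  bundle <- list(genes = genes,
                 tes = tes,
                 families = families,
                 chrom_sizes = chrom_sizes,
                 fpkm = .simulate_expression(cf, gene_id, members, fam_ages),
                 enrichment = .simulate_enrichment(cf, genes, members),
                 methylation = .simulate_methylation(cf, genes, members),
                 config = cf)
  class(bundle) <- "duplite_bundle"
  bundle
}

.simulate_tes <- function(cf, genes, rs, re, mult) {
  if (cf$te_rate == 0)
    return(te_insertions(character(), character(), numeric(),
                         numeric())[0, ])
  counts <- stats::rpois(nrow(genes), (re - rs) * cf$te_rate * mult)
  src <- rep(seq_len(nrow(genes)), counts)
  total <- sum(counts)
  if (total == 0)
    return(te_insertions(character(), character(), numeric(),
                         numeric())[0, ])
  ts <- round(rs[src] + stats::runif(total) * (re[src] - rs[src]))
  tl <- pmax(20, round(stats::rlnorm(total, cf$te_length_meanlog,
                                     cf$te_length_sdlog)))
  te <- te_insertions(sprintf("TE%06d", seq_len(total)),
                      genes$chrom[src], ts,
                      pmin(ts + tl, cf$chromosome_length))
  te$source_gene <- genes$gene_id[src]
  te
}

# Copy member 1's neighborhood TE layout onto member 2 for a calibrated
# fraction of families so the realized same-category probability tracks
# p_same_category: copied pairs share (density, coverage) exactly, the rest
# match by chance at roughly the squared category frequencies.
.induce_shared_categories <- function(cf, genes, tes, members, rs, re) {
  if (nrow(tes) == 0 || cf$p_same_category == 0) return(tes)
  env <- te_environment(genes, tes, flank = cf$flank,
                        chrom_sizes = setNames(rep(cf$chromosome_length,
                                                   cf$n_chromosomes),
                                               unique(genes$chrom)))
  pts <- env[env$density > 0 | env$coverage > 0, c("density", "coverage")]
  if (nrow(unique(pts)) < 4) return(tes)
  env <- assign_categories(env, fit_category_model(env))
  fam_cat <- env$category[c(members[, 1], members[, 2])]
  f <- table(fam_cat) / length(fam_cat)
  p_chance <- sum(f^2)
  p_copy <- min(1, max(0, (cf$p_same_category - p_chance) / (1 - p_chance)))
  copy <- stats::runif(nrow(members)) < p_copy
  if (!any(copy)) return(tes)
  tgr <- .as_granges(tes)
  drop <- rep(FALSE, nrow(tes))
  added <- vector("list", sum(copy))
  k <- 0
  for (i in which(copy)) {
    m1 <- members[i, 1]; m2 <- members[i, 2]
    r1 <- genomic_intervals(genes$chrom[m1], rs[m1], re[m1])
    r2 <- genomic_intervals(genes$chrom[m2], rs[m2], re[m2])
    drop <- drop | (GenomicRanges::countOverlaps(tgr, .as_granges(r2)) > 0)
    src <- intersect_length(tes[, c("chrom", "start", "end")],
                            r1[rep(1, nrow(tes)), ]) > 0
    if (!any(src)) { k <- k + 1; added[[k]] <- NULL; next }
    shift <- (rs[m2] - rs[m1])
    ns <- pmax(0, tes$start[src] + shift)
    ne <- pmin(cf$chromosome_length, tes$end[src] + shift)
    keep <- ne > ns
    k <- k + 1
    added[[k]] <- data.frame(chrom = genes$chrom[m2], start = ns[keep],
                             end = ne[keep],
                             source_gene = genes$gene_id[m2])
  }
  base <- tes[!drop, c("chrom", "start", "end", "source_gene")]
  new <- do.call(rbind, c(list(base), added[!vapply(added, is.null,
                                                    logical(1))]))
  out <- te_insertions(sprintf("TE%06d", seq_len(nrow(new))),
                       new$chrom, new$start, new$end)
  out$source_gene <- new$source_gene
  out
}

.simulate_divergence <- function(cf) {
  nf <- cf$n_families
  age <- sample(names(cf$dS_weights), nf, replace = TRUE,
                prob = cf$dS_weights)
  dS <- numeric(nf)
  dS[age == "young"] <- stats::runif(sum(age == "young"), 0.02, 1)
  dS[age == "middle-age"] <- stats::runif(sum(age == "middle-age"), 1, 2)
  dS[age == "old"] <- 2 + stats::rexp(sum(age == "old"), rate = 1 / 1.2)
  omega <- stats::rbeta(nf, 2, 12)
  data.frame(dS = dS, dN = omega * dS)
}

.simulate_enrichment <- function(cf, genes, members) {
  out <- list()
  for (ct in cf$cell_types) {
    out[[ct]] <- list()
    for (mk in histone_marks()) {
      u <- .copula_u(nrow(genes), members[, 1], members[, 2],
                     cf$rho_epigenome[[mk]])
      v <- stats::qgamma(u, shape = cf$enrichment_shape,
                         rate = cf$enrichment_rate)
      tr <- data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, value = round(v, 4),
                       stringsAsFactors = FALSE)
      out[[ct]][[mk]] <- tr[order(tr$chrom, tr$start), ]
    }
  }
  out
}

.simulate_methylation <- function(cf, genes, members) {
  out <- list()
  for (ct in cf$cell_types) {
    u <- .copula_u(nrow(genes), members[, 1], members[, 2],
                   cf$rho_methylation)
    has <- stats::runif(nrow(genes)) >= cf$p_methylation_missing
    rl <- stats::runif(nrow(genes), 0.02, 0.23)
    rh <- stats::runif(nrow(genes), 0.77, 0.98)
    cut <- genes$start + round((genes$end - genes$start) * (1 - u))
    rows <- list()
    for (i in which(has)) {
      lo_len <- cut[i] - genes$start[i]
      hi_len <- genes$end[i] - cut[i]
      if (lo_len > 0)
        rows[[length(rows) + 1]] <- c(genes$start[i], cut[i], rl[i])
      if (hi_len > 0)
        rows[[length(rows) + 1]] <- c(cut[i], genes$end[i], rh[i])
    }
    if (length(rows) == 0) {
      out[[ct]] <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), mean_ratio = numeric())
      next
    }
    m <- do.call(rbind, rows)
    ch <- rep(genes$chrom[has],
              (cut[has] > genes$start[has]) + (genes$end[has] > cut[has]))
    out[[ct]] <- data.frame(chrom = ch, start = m[, 1], end = m[, 2],
                            mean_ratio = round(m[, 3], 4),
                            stringsAsFactors = FALSE)
  }
  out
}

.simulate_expression <- function(cf, gene_id, members, fam_ages) {
  n <- length(gene_id)
  fpkm <- matrix(0, n, 4, dimnames = list(gene_id, cf$cell_types))
  total <- stats::rlnorm(n, log(cf$fpkm_scale), 1)
  in_family <- rep(FALSE, n); in_family[members] <- TRUE

  solo <- which(!in_family)
  if (length(solo) > 0) {
    prof <- .rdirichlet(length(solo), rep(1.5, 4))
    silent <- stats::runif(length(solo)) < 0.25
    fpkm[solo, ] <- prof * total[solo] * 4 * !silent
  }

  conc <- cf$dirichlet_concentration[as.character(fam_ages)]
  theta <- .rdirichlet(nrow(members), rep(1.5, 4))
  fam_silent <- stats::runif(nrow(members)) < cf$p_family_silent
  for (m in 1:2) {
    idx <- members[, m]
    prof <- t(vapply(seq_len(nrow(members)), function(i)
      .rdirichlet(1, pmax(conc[i] * theta[i, ], 1e-3))[1, ], numeric(4)))
    silent <- fam_silent | stats::runif(nrow(members)) < cf$p_gene_silent
    fpkm[idx, ] <- prof * total[idx] * 4 * !silent
  }
  round(fpkm, 4)
}

#' Write a synthetic bundle to a directory
#'
#' Emits the exact dialects the readers consume: `genes.bed`, `tes.bed`
#' (0-based half-open BED), `chrom_sizes.tsv`, `families.tsv`, `fpkm.tsv`,
#' `enrichment/<cell_type>_<mark>.bedGraph`,
#' `methylation/<cell_type>.tsv`.
#'
#' @param bundle a `duplite_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "enrichment"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "methylation"), showWarnings = FALSE)
  write_bed(bundle$genes, file.path(dir, "genes.bed"))
  write_bed(bundle$tes, file.path(dir, "tes.bed"))
  write.table(bundle$chrom_sizes, file.path(dir, "chrom_sizes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- bundle$families[, c("family_id", "gene1_id", "gene2_id", "dS",
                             "dN")]
  write.table(fam, file.path(dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fp <- data.frame(gene_id = rownames(bundle$fpkm), bundle$fpkm,
                   check.names = FALSE)
  write.table(fp, file.path(dir, "fpkm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (ct in names(bundle$enrichment))
    for (mk in names(bundle$enrichment[[ct]]))
      write_bedgraph(bundle$enrichment[[ct]][[mk]],
                     file.path(dir, "enrichment",
                               paste0(ct, "_", mk, ".bedGraph")))
  for (ct in names(bundle$methylation))
    write.table(bundle$methylation[[ct]],
                file.path(dir, "methylation", paste0(ct, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#' @param dir bundle directory.
#' @return A `duplite_bundle` (without the generator config).
#' @export
read_bundle <- function(dir) {
  genes_iv <- read_intervals(file.path(dir, "genes.bed"), "bed")
  genes <- gene_records(genes_iv$id, genes_iv$chrom, genes_iv$start,
                        genes_iv$end, genes_iv$strand)
  tes_iv <- read_intervals(file.path(dir, "tes.bed"), "bed")
  tes <- if (nrow(tes_iv) > 0)
    te_insertions(tes_iv$id, tes_iv$chrom, tes_iv$start, tes_iv$end,
                  tes_iv$strand)
  else te_insertions(character(), character(), numeric(), numeric())[0, ]
  fp <- read.table(file.path(dir, "fpkm.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE)
  fpkm <- as.matrix(fp[, -1, drop = FALSE])
  rownames(fpkm) <- fp$gene_id
  enr_files <- list.files(file.path(dir, "enrichment"),
                          full.names = TRUE)
  enrichment <- list()
  for (f in enr_files) {
    nm <- sub("\\.bedGraph$", "", basename(f))
    parts <- strsplit(nm, "_(?=[^_]+$)", perl = TRUE)[[1]]
    enrichment[[parts[1]]][[parts[2]]] <- read_bedgraph(f)
  }
  met_files <- list.files(file.path(dir, "methylation"), full.names = TRUE)
  methylation <- list()
  for (f in met_files)
    methylation[[sub("\\.tsv$", "", basename(f))]] <-
      read_methylation_regions(f)[, c("chrom", "start", "end",
                                      "mean_ratio")]
  structure(list(genes = genes, tes = tes,
                 families = read_family_table(file.path(dir,
                                                        "families.tsv")),
                 chrom_sizes = read.table(file.path(dir, "chrom_sizes.tsv"),
                                          header = TRUE, sep = "\t"),
                 fpkm = fpkm, enrichment = enrichment,
                 methylation = methylation, config = NULL),
            class = "duplite_bundle")
}

#' Hand-sized worked fixture with independently computed expectations
#'
#' Six genes, five TE insertions and three families whose density,
#' coverage, enrichment, methylation and d_m values were computed by hand;
#' the expectations ship alongside the bundle so pipeline runs can be
#' checked cell by cell.
#'
#' @return A list with `bundle` (a `duplite_bundle` without generator
#'   config) and `expected` (named list of hand-computed values).
#' @export
worked_fixture <- function() {
  genes <- gene_records(paste0("G", 1:6), "chr1",
                        c(10000, 30000, 50000, 70000, 90000, 110000),
                        c(11000, 31000, 52000, 71000, 91000, 111000))
  # G1 region [8000,13000): TEs [8500,9000) + [12000,12500) -> 2/5000, 0.2
  # G3 region [48000,54000): TE [47000,49000) overlaps 1000 of 6000 bases
  # G5 region [88000,93000): TE [88000,90500) -> 1/5000, 0.5
  tes <- te_insertions(paste0("TE", 1:5), "chr1",
                       c(8500, 12000, 47000, 68500, 88000),
                       c(9000, 12500, 49000, 69500, 90500))
  families <- validate_families(
    data.frame(family_id = c("F1", "F2", "F3"),
               gene1_id = c("G1", "G3", "G5"),
               gene2_id = c("G2", "G4", "G6"),
               dS = c(0.5, 1.5, 2.5),
               dN = c(0.05, 0.30, 0.25),
               stringsAsFactors = FALSE))
  # column sums are all 9, so TPM is proportional to FPKM and the d_m
  # values can be read off the FPKM profiles directly
  fpkm <- matrix(c(2, 2, 0, 0,    # G1
                   1, 1, 1, 1,    # G2 vs G1: d_m = 0.5
                   4, 0, 4, 0,    # G3
                   0, 4, 0, 4,    # G4: disjoint support vs G3 -> d_m = 1
                   1, 1, 2, 2,    # G5
                   1, 1, 2, 2),   # G6 proportional to G5 -> d_m = 0
                 nrow = 6, byrow = TRUE,
                 dimnames = list(paste0("G", 1:6),
                                 c("CD14", "erythroblast", "CD8T",
                                   "macrophage")))
  track <- data.frame(chrom = "chr1", start = c(10000, 30200),
                      end = c(10500, 30500), value = c(4, 2))
  enrichment <- list(CD14 = setNames(rep(list(track), 6), histone_marks()))
  meth <- data.frame(chrom = "chr1",
                     start = c(10000, 30000, 30600),
                     end = c(11000, 30600, 31000),
                     mean_ratio = c(0.8, 0.1, 0.9))
  bundle <- structure(list(genes = genes, tes = tes, families = families,
                           chrom_sizes = data.frame(chrom = "chr1",
                                                    size = 2e5),
                           fpkm = fpkm,
                           enrichment = enrichment,
                           methylation = list(CD14 = meth),
                           config = NULL),
                      class = "duplite_bundle")
  expected <- list(
    te_metrics = data.frame(
      gene_id = paste0("G", 1:6),
      density = c(2 / 5000, 0, 1 / 6000, 1 / 5000, 1 / 5000, 0),
      coverage = c(1000 / 5000, 0, 1000 / 6000, 1000 / 5000, 2500 / 5000,
                   0)),
    # (4 x 500)/1000 for G1; (2 x 300)/1000 for G2; others uncovered
    mean_enrichment = setNames(c(2, 0.6, 0, 0, 0, 0), paste0("G", 1:6)),
    methylation = data.frame(
      gene_id = c("G1", "G2"),
      methylation_mean = c(0.8, (0.1 * 600 + 0.9 * 400) / 1000),
      methylation_status = c("hyper", "standard")),
    d_m = setNames(c(0.5, 1, 0), c("F1", "F2", "F3")))
  list(bundle = bundle, expected = expected)
}
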