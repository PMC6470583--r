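# TE-neighborhood metrics and the five-category classification.

#' TE-neighborhood category labels
#'
#' Ordered from empty to dense neighborhoods. TE-free is assigned by rule
#' (density and coverage both exactly 0); the remaining four labels come
#' from k-medoids clustering of (density, coverage), ordered by medoid
#' density.
#'
#' @return Character vector of the five category labels.
#' @export
te_categories <- function() {
  c("TE-free", "TE-very-poor", "TE-poor", "TE-rich", "TE-very-rich")
}

#' Per-gene TE density and coverage in the flanked gene region
#'
#' For each gene the region is the gene body extended by `flank` bases on
#' both sides, clipped at position 0 and (when `chrom_sizes` is given) at
#' the chromosome end. Density is the number of TE insertions intersecting
#' the region divided by the region length (insertions/bp); coverage is the
#' fraction of region bases inside the union of TE intervals, so nested or
#' overlapping insertions are never double-counted.
#'
#' @param genes gene table from [gene_records()].
#' @param tes TE table from [te_insertions()] (may have zero rows).
#' @param flank flanking width in bp on each side (default 2000, covering
#'   the promoter region in addition to the entire gene).
#' @param chrom_sizes optional named vector (or two-column data.frame
#'   `chrom`, `size`) of chromosome lengths used to clip regions.
#' @return A `data.frame`: `gene_id`, `chrom`, `region_start`, `region_end`,
#'   `density`, `coverage`, and `category` (all `NA` until
#'   [assign_categories()]).
#' @examples
#' g <- gene_records("G1", "chr1", 10000, 11000)
#' t <- te_insertions(c("t1", "t2"), "chr1", c(8500, 12000), c(9000, 12500))
#' te_environment(g, t) # density 4e-4, coverage 0.2 over [8000,13000)
#' @export
te_environment <- function(genes, tes, flank = 2000, chrom_sizes = NULL) {
  stopifnot(flank >= 0)
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  region_start <- pmax(0, genes$start - flank)
  region_end <- genes$end + flank
  if (!is.null(chrom_sizes)) {
    cap <- unname(chrom_sizes[genes$chrom])
    region_end <- ifelse(is.na(cap), region_end, pmin(region_end, cap))
  }
  regions <- genomic_intervals(genes$chrom, region_start, region_end,
                               id = genes$gene_id)
  len <- regions$end - regions$start
  n_te <- numeric(nrow(genes))
  cov_bases <- numeric(nrow(genes))
  if (nrow(tes) > 0) {
    rgr <- .as_granges(regions)
    tgr <- .as_granges(tes)
    n_te <- suppressWarnings(
      GenomicRanges::countOverlaps(rgr, tgr, ignore.strand = TRUE))
    # union semantics: reduce TEs, then sum per-region overlap widths
    red <- GenomicRanges::reduce(tgr, ignore.strand = TRUE)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(rgr, red, ignore.strand = TRUE))
    if (length(hits) > 0) {
      w <- GenomicRanges::width(IRanges::pintersect(
        rgr[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      cov_bases[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  data.frame(gene_id = genes$gene_id,
             chrom = genes$chrom,
             region_start = regions$start,
             region_end = regions$end,
             density = n_te / len,
             coverage = cov_bases / len,
             category = NA_character_,
             stringsAsFactors = FALSE)
}

#' Fit the four-cluster k-medoids category model
#'
#' Genes with any TE signal (density > 0 or coverage > 0) are clustered on
#' their raw (density, coverage) points with the PAM algorithm
#' (BUILD + SWAP, [cluster::pam()]), Euclidean distance, k = 4. Clusters are
#' relabeled by medoid density ascending: TE-very-poor, TE-poor, TE-rich,
#' TE-very-rich. Points are not standardized by default (set
#' `standardize = TRUE` for z-scored clustering).
#'
#' @param env TE-environment table from [te_environment()].
#' @param k number of clusters (default 4; the fifth category, TE-free, is
#'   assigned by rule, not by clustering).
#' @param standardize z-score density and coverage before clustering.
#' @param seed recorded in the model for provenance; PAM itself is
#'   deterministic.
#' @return A `te_category_model` list: `k`, `medoids` (data.frame ordered by
#'   density, rownames = category labels), `labels`, `objective` (sum of
#'   Euclidean distances of points to their nearest medoid), `standardize`,
#'   `center`, `scale`, `seed`.
#' @export
fit_category_model <- function(env, k = 4, standardize = FALSE, seed = NULL) {
  pts <- as.matrix(env[env$density > 0 | env$coverage > 0,
                       c("density", "coverage")])
  if (nrow(unique(pts)) < k)
    stop("need at least ", k, " distinct non-TE-free points to fit ", k,
         " medoids")
  center <- c(0, 0); scale <- c(1, 1)
  work <- pts
  if (standardize) {
    center <- colMeans(pts)
    scale <- apply(pts, 2, stats::sd)
    scale[scale == 0] <- 1
    work <- sweep(sweep(pts, 2, center), 2, scale, "/")
  }
  if (nrow(work) == k) {
    med <- work  # with exactly k points each is its own medoid
  } else {
    fit <- cluster::pam(work, k = k, metric = "euclidean",
                        keep.diss = FALSE, keep.data = FALSE)
    med <- work[fit$id.med, , drop = FALSE]
  }
  ord <- order(med[, "density"], med[, "coverage"])
  med <- med[ord, , drop = FALSE]
  labels <- te_categories()[-1]
  rownames(med) <- labels
  # objective on the clustering scale, as a brute-force oracle would compute it
  d <- .medoid_distances(work, med)
  objective <- sum(apply(d, 1, min))
  structure(list(k = k,
                 medoids = as.data.frame(med),
                 labels = labels,
                 objective = objective,
                 standardize = standardize,
                 center = center,
                 scale = scale,
                 seed = seed),
            class = "te_category_model")
}

.medoid_distances <- function(pts, medoids) {
  medoids <- as.matrix(medoids)
  d <- matrix(0, nrow(pts), nrow(medoids))
  for (m in seq_len(nrow(medoids)))
    d[, m] <- sqrt((pts[, 1] - medoids[m, 1])^2 +
                     (pts[, 2] - medoids[m, 2])^2)
  d
}

#' @export
print.te_category_model <- function(x, ...) {
  cat("TE-neighborhood category model (PAM, k =", x$k, ")\n")
  cat("objective:", format(x$objective), "\n")
  print(x$medoids)
  invisible(x)
}

#' Assign the five TE-neighborhood categories
#'
#' A gene with density and coverage both 0 is TE-free by rule, without
#' consulting the model; every other gene takes the label of its nearest
#' medoid (Euclidean distance on the model's clustering scale). Distance
#' ties go to the lower-indexed label in the density-ordered label list, so
#' assignment is deterministic.
#'
#' @param env TE-environment table from [te_environment()].
#' @param model a `te_category_model` from [fit_category_model()].
#' @return `env` with `category` filled in (factor over [te_categories()]).
#' @export
assign_categories <- function(env, model) {
  category <- rep(NA_character_, nrow(env))
  free <- env$density == 0 & env$coverage == 0
  category[free] <- "TE-free"
  if (any(!free)) {
    pts <- as.matrix(env[!free, c("density", "coverage")])
    if (model$standardize)
      pts <- sweep(sweep(pts, 2, model$center), 2, model$scale, "/")
    d <- .medoid_distances(pts, model$medoids)
    category[!free] <- model$labels[max.col(-d, ties.method = "first")]
  }
  env$category <- factor(category, levels = te_categories())
  env
}

#' Category counts and percentages
#'
#' @param env categorized TE-environment table.
#' @return A `data.frame` with one row per category: `category`, `count`,
#'   `percent` (of all genes).
#' @export
category_distribution <- function(env) {
  if (anyNA(env$category))
    stop("all genes must have an assigned category")
  counts <- table(factor(env$category, levels = te_categories()))
  data.frame(category = factor(te_categories(), levels = te_categories()),
             count = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(env))
}
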