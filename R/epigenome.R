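# Per-gene epigenetic summaries: mean histone fold enrichment over the gene
# body and a gene-level methylation mean/status from hypo/hyper-methylated
# regions.

.HISTONE_MARKS <- c("H3K27me3", "H3K9me3", "H3K27ac",
                    "H3K4me1", "H3K4me3", "H3K36me3")

#' The six histone modifications summarized per gene
#' @return Character vector of mark names (repressive: H3K27me3, H3K9me3;
#'   activating: H3K27ac, H3K4me1, H3K4me3; gene-body-associated: H3K36me3).
#' @export
histone_marks <- function() .HISTONE_MARKS

#' Read a fold-enrichment track (bedGraph)
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @return A `data.frame`: `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = as.numeric(gr$score),
             stringsAsFactors = FALSE)
}

#' Write a fold-enrichment track (bedGraph)
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write.table(data.frame(track$chrom,
                         format(track$start, scientific = FALSE, trim = TRUE),
                         format(track$end, scientific = FALSE, trim = TRUE),
                         track$value),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Mean histone fold enrichment per gene
#'
#' The average fold enrichment over the positions covered by the gene,
#' normalized by the gene size: positions of the gene with no track segment
#' contribute fold 0, so the result is
#' sum(fold x overlap bases) / gene length. Track segments must not overlap
#' one another.
#'
#' @param genes gene table from [gene_records()].
#' @param track enrichment track (`chrom`, `start`, `end`, `value`), fold
#'   values >= 0.
#' @return Numeric vector of mean enrichments, one per gene (named by
#'   `gene_id`).
#' @examples
#' g <- gene_records("G1", "chr1", 0, 1000)
#' tr <- data.frame(chrom = "chr1", start = 200, end = 700, value = 4)
#' mean_histone_enrichment(g, tr) # (4 * 500) / 1000 = 2
#' @export
mean_histone_enrichment <- function(genes, track) {
  out <- setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(track) == 0) return(out)
  if (any(track$value < 0) || any(!is.finite(track$value)))
    stop("fold enrichment values must be finite and non-negative")
  tiv <- genomic_intervals(track$chrom, track$start, track$end)
  tgr <- .as_granges(tiv)
  if (!IRanges::isDisjoint(tgr))
    stop("enrichment track segments overlap within the track")
  ggr <- .as_granges(genes)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ggr, tgr, ignore.strand = TRUE))
  if (length(hits) > 0) {
    w <- GenomicRanges::width(IRanges::pintersect(
      ggr[S4Vectors::queryHits(hits)], tgr[S4Vectors::subjectHits(hits)]))
    contrib <- w * track$value[S4Vectors::subjectHits(hits)]
    agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out / (genes$end - genes$start)
}

#' Read methylation regions
#'
#' Expects a TSV with header columns `chrom`, `start`, `end`, `mean_ratio`
#' (0-based half-open; ratio of unconverted-cytosine reads, in `[0, 1]`).
#' Typical inputs carry only hypo- (< 0.25) and hyper- (> 0.75) methylated
#' region calls.
#'
#' @param path TSV path.
#' @param hypo,hyper thresholds for the region call column.
#' @return A `data.frame`: `chrom`, `start`, `end`, `mean_ratio`, `call`.
#' @export
read_methylation_regions <- function(path, hypo = 0.25, hyper = 0.75) {
  reg <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "mean_ratio")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0)
    stop("methylation table lacks columns: ", paste(missing, collapse = ", "))
  validate_methylation_regions(reg[required], hypo = hypo, hyper = hyper)
}

#' Validate methylation regions and attach the region call
#' @param regions data.frame with `chrom`, `start`, `end`, `mean_ratio`.
#' @inheritParams read_methylation_regions
#' @return The table with a `call` column (`hypo`/`hyper`/`standard`).
#' @export
validate_methylation_regions <- function(regions, hypo = 0.25, hyper = 0.75) {
  if (any(regions$mean_ratio < 0) || any(regions$mean_ratio > 1))
    stop("methylation mean_ratio must lie in [0, 1]")
  invisible(genomic_intervals(regions$chrom, regions$start, regions$end))
  regions$call <- ifelse(regions$mean_ratio < hypo, "hypo",
                         ifelse(regions$mean_ratio > hyper, "hyper",
                                "standard"))
  regions
}

#' Gene-level methylation mean and status
#'
#' The gene mean is the overlap-length-weighted average of the mean ratios
#' of all methylation regions intersecting the gene. A gene is called hypo-
#' methylated when the mean is < `hypo`, hyper-methylated when > `hyper`,
#' and standard otherwise. Genes covered by no region get an undefined
#' (`NA`) mean and status standard.
#'
#' @param genes gene table from [gene_records()].
#' @param regions methylation region table (`chrom`, `start`, `end`,
#'   `mean_ratio`).
#' @param hypo,hyper gene-status thresholds (defaults 0.25 and 0.75).
#' @return A `data.frame`: `gene_id`, `methylation_mean`,
#'   `methylation_status`.
#' @examples
#' g <- gene_records("G1", "chr1", 0, 1000)
#' r <- data.frame(chrom = "chr1", start = c(0, 600), end = c(600, 1000),
#'                 mean_ratio = c(0.1, 0.9))
#' gene_methylation(g, r) # mean 0.42 -> standard
#' @export
gene_methylation <- function(genes, regions, hypo = 0.25, hyper = 0.75) {
  mean_ratio <- rep(NA_real_, nrow(genes))
  if (nrow(regions) > 0) {
    if (any(regions$mean_ratio < 0) || any(regions$mean_ratio > 1))
      stop("methylation mean_ratio must lie in [0, 1]")
    rgr <- .as_granges(genomic_intervals(regions$chrom, regions$start,
                                         regions$end))
    ggr <- .as_granges(genes)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(ggr, rgr, ignore.strand = TRUE))
    if (length(hits) > 0) {
      w <- GenomicRanges::width(IRanges::pintersect(
        ggr[S4Vectors::queryHits(hits)], rgr[S4Vectors::subjectHits(hits)]))
      q <- S4Vectors::queryHits(hits)
      num <- tapply(w * regions$mean_ratio[S4Vectors::subjectHits(hits)],
                    q, sum)
      den <- tapply(w, q, sum)
      mean_ratio[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
    }
  }
  status <- rep("standard", nrow(genes))
  status[!is.na(mean_ratio) & mean_ratio < hypo] <- "hypo"
  status[!is.na(mean_ratio) & mean_ratio > hyper] <- "hyper"
  data.frame(gene_id = genes$gene_id,
             methylation_mean = mean_ratio,
             methylation_status = factor(status,
                                         levels = c("hypo", "standard",
                                                    "hyper")),
             stringsAsFactors = FALSE)
}

#' Summarize the epigenome of every gene across cell types
#'
#' Convenience wrapper producing the long-format table the family-level
#' correlation analyses consume.
#'
#' @param genes gene table.
#' @param enrichment nested named list: `enrichment[[cell_type]][[mark]]` is
#'   an enrichment track data.frame.
#' @param methylation named list: `methylation[[cell_type]]` is a
#'   methylation region data.frame.
#' @param hypo,hyper gene methylation status thresholds.
#' @return A list with `enrichment` (gene_id, cell_type, mark,
#'   mean_enrichment) and `methylation` (gene_id, cell_type,
#'   methylation_mean, methylation_status).
#' @export
summarize_epigenome <- function(genes, enrichment, methylation,
                                hypo = 0.25, hyper = 0.75) {
  enr <- do.call(rbind, lapply(names(enrichment), function(ct) {
    do.call(rbind, lapply(names(enrichment[[ct]]), function(mk) {
      data.frame(gene_id = genes$gene_id, cell_type = ct, mark = mk,
                 mean_enrichment =
                   unname(mean_histone_enrichment(genes,
                                                  enrichment[[ct]][[mk]])),
                 stringsAsFactors = FALSE)
    }))
  }))
  met <- do.call(rbind, lapply(names(methylation), function(ct) {
    gm <- gene_methylation(genes, methylation[[ct]], hypo = hypo,
                           hyper = hyper)
    cbind(gm[, "gene_id", drop = FALSE], cell_type = ct,
          gm[, c("methylation_mean", "methylation_status")])
  }))
  list(enrichment = enr, methylation = met)
}
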