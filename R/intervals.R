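#' @importFrom stats setNames
#' @importFrom utils read.table write.table
NULL

# Internal coordinate convention: 0-based, half-open [start, end), BED-native.
# GFF3 input (1-based, inclusive) is converted on read; GRanges objects used
# internally are built on the fly with start + 1.

.STRANDS <- c("+", "-", "*")

#' Construct a validated genomic-interval table
#'
#' Intervals use the 0-based half-open convention throughout the package:
#' `start` is the first base of the feature, `end` is one past the last, so
#' `end - start` is the feature length. Strand is carried along but ignored
#' by every metric in the package.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; `0 <= start < end` required.
#' @param strand one of `"+"`, `"-"`, `"*"` (unspecified); recycled.
#' @param id optional feature identifiers.
#' @return A `data.frame` with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' genomic_intervals("chr1", 10000, 11000, id = "geneA")
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", id = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- as.character(rep_len(chrom, n))
  start <- as.numeric(rep_len(start, n))
  end <- as.numeric(rep_len(end, n))
  strand <- as.character(rep_len(strand, n))
  if (is.null(id)) id <- rep_len(NA_character_, n)
  id <- as.character(rep_len(id, n))
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing")
  if (any(start < 0))
    stop("negative coordinates are not allowed")
  if (any(end <= start))
    stop("malformed interval: end must be strictly greater than start")
  if (!all(strand %in% .STRANDS))
    stop("strand must be one of '+', '-', '*'")
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Gene records
#'
#' A gene is its full annotated body span (exon structure is not modelled);
#' metrics in this package always treat the entire gene.
#'
#' @param gene_id unique gene identifiers.
#' @inheritParams genomic_intervals
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
gene_records <- function(gene_id, chrom, start, end, strand = "*") {
  iv <- genomic_intervals(chrom, start, end, strand, id = gene_id)
  if (anyDuplicated(iv$id))
    stop("gene_id values must be unique")
  names(iv)[names(iv) == "id"] <- "gene_id"
  iv
}

#' Transposable-element insertions
#'
#' @param te_id insertion identifiers.
#' @param family_label optional repeat family label (carried, unused by
#'   metrics: TE classes are treated globally).
#' @inheritParams genomic_intervals
#' @return A `data.frame` with columns `te_id`, `chrom`, `start`, `end`,
#'   `strand`, `family_label`.
#' @export
te_insertions <- function(te_id, chrom, start, end, strand = "*",
                          family_label = NA_character_) {
  iv <- genomic_intervals(chrom, start, end, strand, id = te_id)
  names(iv)[names(iv) == "id"] <- "te_id"
  iv$family_label <- as.character(rep_len(family_label, nrow(iv)))
  iv
}

# data.frame of 0-based half-open intervals -> GRanges (1-based inclusive)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
}

.from_granges <- function(gr, id = NULL) {
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = id
  )
}

#' Length of the intersection of two intervals
#'
#' @param a,b interval tables as returned by [genomic_intervals()]; rows are
#'   paired (shorter one recycled).
#' @return Integer vector of intersection lengths in bases; 0 when the
#'   chromosomes differ or the spans are disjoint.
#' @examples
#' a <- genomic_intervals("chr1", 8000, 13000)
#' b <- genomic_intervals("chr1", 8500, 9000)
#' intersect_length(a, b) # 500
#' @export
intersect_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  len <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  len[a$chrom[ai] != b$chrom[bi]] <- 0
  as.integer(len)
}

#' Read genomic intervals from BED or GFF3
#'
#' BED is read as 0-based half-open; GFF3 coordinates (1-based inclusive)
#' are converted to the internal 0-based half-open convention.
#'
#' @param path file path.
#' @param format `"bed"`, `"gff3"`, or `"auto"` (by file extension).
#' @return A `data.frame` as from [genomic_intervals()]; the BED name column
#'   or the GFF3 `ID` attribute populates `id`. An empty file yields a
#'   zero-row table.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", path, " as ", toupper(format),
                             ": ", conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  id <- if (format == "bed") {
    if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  } else {
    if (!is.null(gr$ID)) as.character(gr$ID)
    else if (!is.null(gr$Name)) as.character(gr$Name)
    else NA_character_
  }
  .from_granges(gr, id = id)
}

#' Write intervals as BED
#'
#' @param intervals an interval table (`id`/`gene_id`/`te_id` column used as
#'   the BED name).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  idcol <- intersect(c("id", "gene_id", "te_id"), names(intervals))[1]
  nm <- if (is.na(idcol)) rep(".", nrow(intervals)) else intervals[[idcol]]
  nm[is.na(nm)] <- "."
  bed <- data.frame(intervals$chrom, format(intervals$start, scientific = FALSE,
                                            trim = TRUE),
                    format(intervals$end, scientific = FALSE, trim = TRUE),
                    nm, 0L,
                    ifelse(intervals$strand %in% c("+", "-"),
                           intervals$strand, "."))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a two-gene family table
#'
#' Expects a TSV with header columns `family_id`, `gene1_id`, `gene2_id`,
#' `dS`, `dN`. The omega ratio dN/dS is computed; it is `NA` (undefined)
#' when dS is 0.
#'
#' @param path TSV path.
#' @return A `data.frame` with the five input columns plus `omega`.
#' @export
read_family_table <- function(path) {
  fam <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  required <- c("family_id", "gene1_id", "gene2_id", "dS", "dN")
  missing <- setdiff(required, names(fam))
  if (length(missing) > 0)
    stop("family table lacks columns: ", paste(missing, collapse = ", "))
  validate_families(fam[required])
}

#' Validate a family table and attach the omega ratio
#'
#' @param families data.frame with columns `family_id`, `gene1_id`,
#'   `gene2_id`, `dS`, `dN`.
#' @return The validated table with an `omega` column (`NA` where dS = 0).
#' @export
validate_families <- function(families) {
  if (any(families$gene1_id == families$gene2_id))
    stop("a family must contain two distinct genes")
  if (anyDuplicated(families$family_id))
    stop("family_id values must be unique")
  if (any(families$dS < 0) || any(families$dN < 0))
    stop("dS and dN must be non-negative")
  families$omega <- ifelse(families$dS > 0, families$dN / families$dS, NA_real_)
  families
}

#' Distance between two located genes
#'
#' Classifies each gene pair as lying on different chromosomes, overlapping,
#' or separated by a gap; the gap is measured between the nearest ends.
#'
#' @param g1,g2 single-row (or paired, recycled) gene tables.
#' @return A `data.frame` with columns `status` (one of
#'   `"different_chromosomes"`, `"overlapping"`, `"same_chromosome"`) and
#'   `distance` (bp gap; `NA` unless status is `"same_chromosome"`).
#' @examples
#' g1 <- gene_records("a", "chr1", 10000, 11000)
#' g2 <- gene_records("b", "chr1", 91000, 92000)
#' gene_pair_distance(g1, g2) # gap of 80000
#' @export
gene_pair_distance <- function(g1, g2) {
  n <- max(nrow(g1), nrow(g2))
  i1 <- rep_len(seq_len(nrow(g1)), n)
  i2 <- rep_len(seq_len(nrow(g2)), n)
  same_chrom <- g1$chrom[i1] == g2$chrom[i2]
  gap <- pmax(g1$start[i1], g2$start[i2]) - pmin(g1$end[i1], g2$end[i2])
  status <- ifelse(!same_chrom, "different_chromosomes",
                   ifelse(gap < 0, "overlapping", "same_chromosome"))
  data.frame(status = status,
             distance = ifelse(status == "same_chromosome", gap, NA_real_))
}
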