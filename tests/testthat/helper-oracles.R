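# Independent brute-force oracles: every one of these walks positions or
# subsets explicitly and never calls the interval/cluster machinery it is
# used to check.

# bases of [s1,e1) also in [s2,e2), counted one position at a time
brute_intersect_length <- function(s1, e1, s2, e2) {
  if (e1 <= s1 || e2 <= s2) return(0L)
  sum(seq(s1, e1 - 1) >= s2 & seq(s1, e1 - 1) < e2)
}

# per-base union coverage and intersect count of TEs over a region
brute_te_metrics <- function(region_start, region_end, te_starts, te_ends) {
  pos <- seq(region_start, region_end - 1)
  covered <- rep(FALSE, length(pos))
  n_hit <- 0L
  for (i in seq_along(te_starts)) {
    inside <- pos >= te_starts[i] & pos < te_ends[i]
    if (any(inside)) n_hit <- n_hit + 1L
    covered <- covered | inside
  }
  list(density = n_hit / length(pos), coverage = mean(covered))
}

# per-base mean fold enrichment over a gene (uncovered positions are 0)
brute_enrichment <- function(gene_start, gene_end, seg_starts, seg_ends,
                             seg_values) {
  pos <- seq(gene_start, gene_end - 1)
  fold <- rep(0, length(pos))
  for (i in seq_along(seg_starts)) {
    inside <- pos >= seg_starts[i] & pos < seg_ends[i]
    fold[inside] <- fold[inside] + seg_values[i]
  }
  mean(fold)
}

# per-base length-weighted methylation mean (NA when nothing overlaps)
brute_methylation_mean <- function(gene_start, gene_end, reg_starts,
                                   reg_ends, ratios) {
  pos <- seq(gene_start, gene_end - 1)
  num <- 0; den <- 0
  for (i in seq_along(reg_starts)) {
    n_in <- sum(pos >= reg_starts[i] & pos < reg_ends[i])
    num <- num + n_in * ratios[i]
    den <- den + n_in
  }
  if (den == 0) NA_real_ else num / den
}

# exhaustive k-medoid search: best objective over all C(n, k) medoid subsets
brute_medoid_objective <- function(pts, k) {
  pts <- as.matrix(pts)
  d <- as.matrix(stats::dist(pts))
  best <- Inf
  for (idx in utils::combn(nrow(pts), k, simplify = FALSE)) {
    obj <- sum(apply(d[, idx, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# Benjamini-Hochberg by the step-up definition on sorted p-values
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
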