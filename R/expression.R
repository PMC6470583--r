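# Expression normalization and the Manhattan expression-divergence d_m.

#' Convert FPKM to TPM within each cell type
#'
#' TPM_i = FPKM_i / sum_j FPKM_j x 10^6, computed independently per cell
#' type (column), so TPM values are directly comparable across cell types.
#'
#' @param fpkm numeric vector (one cell type) or matrix/data.frame with
#'   genes in rows and cell types in columns; values >= 0.
#' @return Object of the same shape with TPM values; each column sums to
#'   10^6.
#' @examples
#' fpkm_to_tpm(c(3, 1)) # 750000, 250000
#' @export
fpkm_to_tpm <- function(fpkm) {
  if (is.null(dim(fpkm))) {
    if (any(fpkm < 0)) stop("FPKM values must be non-negative")
    s <- sum(fpkm)
    if (s == 0) stop("all FPKM values are zero: TPM normalization undefined")
    return(fpkm / s * 1e6)
  }
  m <- as.matrix(fpkm)
  if (any(m < 0)) stop("FPKM values must be non-negative")
  s <- colSums(m)
  if (any(s == 0))
    stop("cell type(s) with all-zero FPKM: ",
         paste(colnames(m)[s == 0], collapse = ", "))
  out <- sweep(m, 2, s, "/") * 1e6
  if (is.data.frame(fpkm)) out <- as.data.frame(out)
  out
}

#' Expressed-gene flag
#'
#' A gene counts as expressed in a sample when its FPKM is at least the
#' threshold (boundary inclusive).
#'
#' @param fpkm numeric vector of FPKM values (>= 0).
#' @param threshold expression cutoff (default 0.5).
#' @return Logical vector.
#' @export
is_expressed <- function(fpkm, threshold = 0.5) {
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  fpkm >= threshold
}

#' Manhattan expression divergence between two genes
#'
#' d_m = 1/2 sum_k | g1_k / sum(g1) - g2_k / sum(g2) | over the cell types:
#' half the L1 distance between the genes' normalized expression profiles,
#' i.e. the total-variation distance, in `[0, 1]`. If exactly one gene is
#' silent in all cell types its normalized profile is taken as the zero
#' vector, giving d_m = 0.5; pairs silent in all cell types on both sides
#' are an error (remove such families upstream).
#'
#' @param g1,g2 non-negative expression vectors (TPM) of equal length.
#' @return d_m in `[0, 1]`.
#' @examples
#' manhattan_divergence(c(2, 2, 0, 0), c(1, 1, 1, 1)) # 0.5
#' @export
manhattan_divergence <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  if (any(g1 < 0) || any(g2 < 0))
    stop("expression values must be non-negative")
  s1 <- sum(g1); s2 <- sum(g2)
  if (s1 == 0 && s2 == 0)
    stop("both genes are silent in every cell type: d_m undefined")
  p1 <- if (s1 > 0) g1 / s1 else rep(0, length(g1))
  p2 <- if (s2 > 0) g2 / s2 else rep(0, length(g2))
  sum(abs(p1 - p2)) / 2
}

#' Expression-divergence class
#'
#' Bins d_m into very low `[0, 0.25)`, low `[0.25, 0.5)`, medium
#' `[0.5, 0.75)` and high `[0.75, 1]` (left-closed intervals; the last is
#' closed at 1).
#'
#' @param d_m numeric vector in `[0, 1]`.
#' @return Ordered factor with levels `very low`, `low`, `medium`, `high`.
#' @export
divergence_class <- function(d_m) {
  if (any(d_m < 0 | d_m > 1, na.rm = TRUE))
    stop("d_m must lie in [0, 1]")
  lev <- c("very low", "low", "medium", "high")
  idx <- pmin(findInterval(d_m, c(0, 0.25, 0.5, 0.75)), 4L)
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Per-family expression divergence
#'
#' Converts an FPKM matrix to TPM, drops families whose two members are
#' both silent in every cell type, and computes d_m and its class for each
#' remaining family. Families with exactly one silent member get the
#' documented d_m = 0.5 convention and are flagged.
#'
#' @param fpkm numeric matrix/data.frame, genes x cell types, rownames =
#'   gene ids.
#' @param families family table (see [validate_families()]).
#' @return A `data.frame`: `family_id`, `d_m`, `divergence_class`,
#'   `one_member_silent`; both-silent families are absent (attribute
#'   `n_dropped` records how many were removed).
#' @export
family_divergence <- function(fpkm, families) {
  m <- as.matrix(fpkm)
  missing <- setdiff(c(families$gene1_id, families$gene2_id), rownames(m))
  if (length(missing) > 0)
    stop("expression matrix lacks genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  tpm <- fpkm_to_tpm(m)
  s1 <- rowSums(tpm[families$gene1_id, , drop = FALSE])
  s2 <- rowSums(tpm[families$gene2_id, , drop = FALSE])
  keep <- s1 > 0 | s2 > 0
  fam <- families[keep, , drop = FALSE]
  d <- vapply(seq_len(nrow(fam)), function(i) {
    manhattan_divergence(tpm[fam$gene1_id[i], ], tpm[fam$gene2_id[i], ])
  }, numeric(1))
  out <- data.frame(family_id = fam$family_id,
                    d_m = d,
                    divergence_class = divergence_class(d),
                    one_member_silent = xor(s1[keep] == 0, s2[keep] == 0),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
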