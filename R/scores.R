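#' Continuous A/B/C archetype scores
#'
#' For each cell, the mean z-score over each identity-gene set (za, zb, zc)
#' is rescaled to \[0, 1\] against that score's own distribution across cells,
#' s = clip((z - P_lo) / (P_hi - P_lo), 0, 1) with P_lo the `lo_pct`-th and
#' P_hi the `hi_pct`-th percentile, and the three rescaled scores are
#' normalized to probabilities pa + pb + pc = 1. Cells with all three
#' rescaled scores zero get the uniform (1/3, 1/3, 1/3). Values below P_lo
#' clip to 0 (they do not reflect): the percentile bounds absorb constant
#' shifts and make the scores comparable across gene sets.
#'
#' @param nm a [normalized_matrix()] or z-scored cells x genes matrix.
#' @param gene_sets named list of three gene-id vectors (A, B, C order).
#' @param lo_pct,hi_pct percentile bounds of the rescaling (40 and 95).
#' @param archetypal_threshold flag a cell archetypal when max(p) exceeds
#'   this (0.6).
#' @return data.frame of class `abc_scores` with per-cell columns `za, zb,
#'   zc, sa, sb, sc, pa, pb, pc`, `assigned_type` (A/B/C, the argmax) and
#'   `archetypal`.
#' @export
abc_scores <- function(nm, gene_sets, lo_pct = 40, hi_pct = 95,
                       archetypal_threshold = 0.6) {
  Z <- if (inherits(nm, "normalized_matrix")) nm$z else as.matrix(nm)
  stopifnot(length(gene_sets) == 3)
  if (is.null(names(gene_sets))) names(gene_sets) <- c("A", "B", "C")
  for (s in names(gene_sets)) {
    if (!length(gene_sets[[s]])) stop("abc_scores: empty gene set ", s)
    miss <- setdiff(gene_sets[[s]], colnames(Z))
    if (length(miss))
      stop("abc_scores: genes missing from matrix in set ", s, ": ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  zmat <- vapply(gene_sets, function(g)
    rowMeans(Z[, g, drop = FALSE]), numeric(nrow(Z)))
  smat <- apply(zmat, 2, function(z) {
    p <- stats::quantile(z, c(lo_pct, hi_pct) / 100, names = FALSE)
    if (p[2] == p[1])
      stop("abc_scores: degenerate score scale (P", hi_pct, " == P", lo_pct, ")")
    clip01((z - p[1]) / (p[2] - p[1]), 0, 1)
  })
  tot <- rowSums(smat)
  pmat <- smat / tot
  pmat[tot == 0, ] <- 1 / 3
  type_names <- c("A", "B", "C")
  assigned <- type_names[max.col(pmat, ties.method = "first")]
  out <- data.frame(zmat, smat, pmat,
                    assigned_type = assigned,
                    archetypal = apply(pmat, 1, max) > archetypal_threshold,
                    stringsAsFactors = FALSE)
  names(out)[1:9] <- c("za", "zb", "zc", "sa", "sb", "sc", "pa", "pb", "pc")
  rownames(out) <- rownames(Z)
  class(out) <- c("abc_scores", "data.frame")
  out
}
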