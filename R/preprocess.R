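#' Quality-control filter for imaging-based count matrices
#'
#' Keeps cells with segmented volume inside the closed `volume_range`, total
#' transcript count strictly greater than `min_transcripts`, and blank-barcode
#' false-positive rate `blanks / (blanks + total)` strictly below
#' `max_blank_rate`. Cell order is preserved. The defaults reproduce the
#' first-pass MERFISH filter (volume 50-2000, > 10 transcripts, < 5% blanks);
#' a stricter pass (e.g. `min_transcripts = 50`) is a separate call.
#'
#' @param m a [count_matrix()] whose metadata has `volume` and `blanks`.
#' @param volume_range closed interval c(lo, hi).
#' @param min_transcripts keep cells with total counts > this.
#' @param max_blank_rate keep cells with blank rate < this.
#' @return A filtered [count_matrix()].
#' @export
qc_filter_cells <- function(m, volume_range = c(50, 2000),
                            min_transcripts = 10, max_blank_rate = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  md <- m$cell_meta
  if (!all(c("volume", "blanks") %in% names(md)))
    stop("qc_filter_cells: cell_meta must have volume and blanks columns")
  total <- rowSums(m$counts)
  blank_rate <- ifelse(md$blanks + total > 0,
                       md$blanks / (md$blanks + total), 0)
  keep <- md$volume >= volume_range[1] & md$volume <= volume_range[2] &
    total > min_transcripts & blank_rate < max_blank_rate
  subset_cells(m, which(keep))
}

#' MERFISH-style normalization (volume, per-sample mean, log, z-score)
#'
#' Per cell, counts are divided by segmented volume; per sample, values are
#' rescaled so the mean per-cell total over genes *not* in `exclude` equals
#' `target_mean` exactly (the exclusion set is typically the IEG panel, whose
#' condition-driven upshift would otherwise bias the size factors); then
#' log10(x + 1); then each gene is z-scored across all retained cells pooled
#' over samples. Genes with zero variance get z = 0.
#'
#' @param m a [count_matrix()] with `volume` (and optionally `sample`)
#'   metadata.
#' @param target_mean target mean per-cell total per sample (250 in the
#'   reference protocol).
#' @param exclude gene ids excluded from size-factor computation.
#' @return A [normalized_matrix()]; `lognorm` holds log10(x + 1), `z` the
#'   z-scored layer.
#' @export
normalize_merfish <- function(m, target_mean = 250, exclude = character()) {
  stopifnot(inherits(m, "count_matrix"))
  md <- m$cell_meta
  if (!"volume" %in% names(md)) stop("normalize_merfish: volume missing")
  if (any(md$volume <= 0)) stop("normalize_merfish: volumes must be positive")
  sample_id <- if ("sample" %in% names(md)) md$sample else rep("all", nrow(md))
  exclude <- intersect(exclude, m$gene_ids)
  x <- m$counts / md$volume
  keep_genes <- setdiff(m$gene_ids, exclude)
  for (s in unique(sample_id)) {
    idx <- sample_id == s
    tot <- mean(rowSums(x[idx, keep_genes, drop = FALSE]))
    if (tot <= 0) stop(sprintf("normalize_merfish: sample '%s' has zero total", s))
    x[idx, ] <- x[idx, ] * (target_mean / tot)
  }
  lognorm <- log10(x + 1)
  z <- scale(lognorm)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  normalized_matrix(
    lognorm, z,
    provenance = c("divide by cell volume",
                   sprintf("per-sample rescale: mean per-cell total over %d non-excluded genes = %g",
                           length(keep_genes), target_mean),
                   "log10(x + 1)",
                   "per-gene z-score across all cells (pooled samples)"),
    excluded_genes = exclude, cell_meta = md)
}

#' snRNA-seq-style size normalization (CP10k, log, optional z-score)
#'
#' Rescales each cell's counts to total 10,000, adds a pseudo-count of 1,
#' log10-transforms, and z-scores each gene. Cells with zero total counts are
#' dropped with a warning.
#'
#' @param m a [count_matrix()].
#' @return A [normalized_matrix()].
#' @export
normalize_snrnaseq <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  total <- rowSums(m$counts)
  if (any(total == 0)) {
    warning(sprintf("normalize_snrnaseq: dropping %d all-zero cell(s)",
                    sum(total == 0)))
    m <- subset_cells(m, which(total > 0))
    total <- total[total > 0]
  }
  cp10k <- m$counts / total * 1e4
  lognorm <- log10(cp10k + 1)
  z <- scale(lognorm)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  normalized_matrix(lognorm, z,
                    provenance = c("rescale per-cell totals to 10,000 (CP10k)",
                                   "log10(x + 1)", "per-gene z-score"),
                    cell_meta = m$cell_meta)
}

#' Highly variable gene selection by binned variance-to-mean ratio
#'
#' Works on counts-per-10k values. Genes with non-zero counts in fewer than
#' `min_cells` cells are dropped; remaining genes are ranked into `n_bins`
#' equal-size bins by mean CP10k expression (ties fall in the lower bin), and
#' within each bin the `top_fraction` genes with the highest variance/mean
#' ratio are selected. Under pure Poisson sampling the ratio is flat in the
#' mean, so binning makes the selection mean-independent.
#'
#' @param m a [count_matrix()].
#' @param min_cells minimum number of cells with non-zero counts.
#' @param n_bins number of mean-expression bins (10 = deciles).
#' @param top_fraction fraction of genes kept per bin.
#' @return Character vector of selected gene ids.
#' @export
select_hvgs <- function(m, min_cells = 10, n_bins = 10, top_fraction = 0.30) {
  stopifnot(inherits(m, "count_matrix"))
  n_nonzero <- colSums(m$counts > 0)
  keep <- n_nonzero >= min_cells
  if (n_bins > sum(keep))
    stop("select_hvgs: n_bins exceeds the number of eligible genes")
  cp10k <- m$counts / pmax(rowSums(m$counts), 1) * 1e4
  cp10k <- cp10k[, keep, drop = FALSE]
  mu <- colMeans(cp10k)
  v <- apply(cp10k, 2, stats::var)
  ratio <- v / pmax(mu, .Machine$double.eps)
  r <- rank(mu, ties.method = "min")
  bin <- floor((r - 1) * n_bins / length(mu)) + 1
  selected <- unlist(lapply(split(seq_along(mu), bin), function(idx) {
    n_top <- ceiling(top_fraction * length(idx))
    idx[order(ratio[idx], decreasing = TRUE)][seq_len(n_top)]
  }), use.names = FALSE)
  sort(colnames(cp10k)[selected])
}

# Vectorized one-vs-rest Wilcoxon rank-sum p-values for the columns of X.
# Mid-ranks for ties; exact null (no ties, both groups < exact_max) else
# normal approximation with tie correction and continuity correction.
wilcox_vec <- function(X, in_group, exact_max = 25) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    r <- rank(x)
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of group
    ties <- table(x)
    has_ties <- any(ties > 1)
    if (!has_ties && n1 < exact_max && n2 < exact_max) {
      if (W > n1 * n2 / 2) {
        p <- 2 * stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
      } else {
        p <- 2 * stats::pwilcox(W, n1, n2)
      }
      return(min(1, p))
    }
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1))
}

#' Derive type-identity (marker) genes by one-vs-rest testing
#'
#' For each type, each gene is tested one-vs-rest with a Wilcoxon rank-sum on
#' log-normalized values; p-values are BH-adjusted within type. A gene is a
#' marker of a type if FDR < `max_fdr`, fold change > `min_fc` (computed on
#' CP10k means with a pseudo-count of 1 on both sides), and it is expressed
#' (count > 0) in more than `min_frac` of the type's cells. Types with fewer
#' than 3 cells are excluded with a warning.
#'
#' @param m a [count_matrix()].
#' @param labels per-cell type labels (length = number of cells).
#' @param min_frac minimum expressed fraction in the up-regulated type.
#' @param min_fc minimum fold change (CP10k scale).
#' @param max_fdr BH FDR threshold.
#' @return data.frame with one row per (gene, type): `p`, `fdr`, `fc`,
#'   `frac_in`, `marker`.
#' @export
derive_identity_genes <- function(m, labels, min_frac = 0.30, min_fc = 2,
                                  max_fdr = 0.05) {
  stopifnot(inherits(m, "count_matrix"), length(labels) == nrow(m$counts))
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("derive_identity_genes: excluding types with < 3 cells: ",
            paste(small, collapse = ", "))
  }
  types <- setdiff(names(tab), small)
  if (length(types) < 2) stop("derive_identity_genes: need >= 2 usable types")
  cp10k <- m$counts / pmax(rowSums(m$counts), 1) * 1e4
  logx <- log10(cp10k + 1)
  res <- lapply(types, function(ty) {
    ing <- labels == ty
    p <- wilcox_vec(logx, ing)
    fdr <- stats::p.adjust(p, method = "BH")
    fc <- (colMeans(cp10k[ing, , drop = FALSE]) + 1) /
      (colMeans(cp10k[!ing, , drop = FALSE]) + 1)
    frac <- colMeans(m$counts[ing, , drop = FALSE] > 0)
    data.frame(gene = m$gene_ids, type = ty, p = p, fdr = fdr, fc = fc,
               frac_in = frac,
               marker = fdr < max_fdr & fc > min_fc & frac > min_frac,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}
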