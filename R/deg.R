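# Pseudo-bulk differential expression between conditions, overlap
# enrichment, and regulation-pattern grouping of identity genes.

# Vectorized two-sided pooled-variance (Student) t-test across the rows of
# two matrices of per-sample values. Matches the classic independent-sample
# t-test with equal-variance assumption.
t_test_rows <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- apply(A, 1, stats::var); v2 <- apply(B, 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  list(t = t, p = p, df = df)
}

#' Pseudo-bulk differential expression between two conditions
#'
#' Single cells are not treated as replicates: raw counts are aggregated to
#' one pseudo-bulk profile per (type, sample), CPM-normalized, and each gene
#' is tested per type with a two-sided independent-sample t-test across
#' sample-level CPM values between the two conditions. Genes enter testing
#' when their mean CPM exceeds `min_cpm` in at least one type in either
#' condition; p-values are BH-adjusted within each type; a gene is a DEG in
#' a type when FDR < `max_fdr` and |log2FC| > log2(`min_fc`). log2FC is
#' condition-of-interest over `condition_ref`, with a pseudo-count of 1 CPM
#' on both sides.
#'
#' @param m a [count_matrix()] or raw counts matrix (cells x genes).
#' @param type_labels,sample_labels,condition_labels per-cell vectors; each
#'   condition needs >= 2 samples, and exactly 2 conditions are compared.
#' @param condition_ref reference (denominator) condition.
#' @param min_cpm expression filter on pseudo-bulk mean CPM.
#' @param min_fc fold-change threshold (2 means |log2FC| > 1).
#' @param max_fdr BH FDR threshold.
#' @return data.frame of class `deg_table`, one row per (gene, type):
#'   `mean_cpm_ref`, `mean_cpm_alt`, `log2fc`, `t`, `p`, `fdr`, `deg`.
#'   Attribute `n_deg_union` counts unique DEGs across types.
#' @export
pseudobulk_deg <- function(m, type_labels, sample_labels, condition_labels,
                           condition_ref = "NR", min_cpm = 10, min_fc = 2,
                           max_fdr = 0.05) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  stopifnot(length(type_labels) == nrow(counts),
            length(sample_labels) == nrow(counts),
            length(condition_labels) == nrow(counts))
  samp_cond <- unique(data.frame(sample = sample_labels,
                                 condition = condition_labels))
  if (anyDuplicated(samp_cond$sample))
    stop("pseudobulk_deg: a sample maps to multiple conditions")
  conds <- unique(samp_cond$condition)
  if (length(conds) != 2)
    stop("pseudobulk_deg: exactly two conditions are required")
  if (!condition_ref %in% conds)
    stop("pseudobulk_deg: condition_ref not among the conditions")
  cond_alt <- setdiff(conds, condition_ref)
  if (any(table(samp_cond$condition) < 2))
    stop("pseudobulk_deg: each condition needs >= 2 samples")

  types <- sort(unique(stats::na.omit(type_labels)))
  # pseudo-bulk CPM per (type, sample)
  agg <- list()
  for (ty in types) {
    for (s in samp_cond$sample) {
      sel <- !is.na(type_labels) & type_labels == ty & sample_labels == s
      if (!any(sel)) next
      cs <- colSums(counts[sel, , drop = FALSE])
      agg[[paste(ty, s, sep = "\r")]] <- cs / sum(cs) * 1e6
    }
  }
  cpm <- do.call(cbind, agg)
  meta <- do.call(rbind, strsplit(names(agg), "\r"))
  pb_type <- meta[, 1]
  pb_cond <- samp_cond$condition[match(meta[, 2], samp_cond$sample)]

  # expression filter: mean CPM > min_cpm in >= 1 (type, condition) stratum
  grp <- paste(pb_type, pb_cond)
  gm <- vapply(split(seq_along(grp), grp), function(idx)
    rowMeans(cpm[, idx, drop = FALSE]), numeric(nrow(cpm)))
  tested <- apply(gm, 1, max) > min_cpm
  if (!any(tested)) stop("pseudobulk_deg: no genes pass the CPM filter")

  out <- lapply(types, function(ty) {
    A <- cpm[tested, pb_type == ty & pb_cond == cond_alt, drop = FALSE]
    B <- cpm[tested, pb_type == ty & pb_cond == condition_ref, drop = FALSE]
    if (ncol(A) < 2 || ncol(B) < 2)
      stop("pseudobulk_deg: type ", ty, " lacks >= 2 samples per condition")
    tt <- t_test_rows(A, B)
    fdr <- stats::p.adjust(tt$p, method = "BH")
    l2fc <- log2((rowMeans(A) + 1) / (rowMeans(B) + 1))
    data.frame(gene = rownames(cpm)[tested], type = ty,
               mean_cpm_ref = rowMeans(B), mean_cpm_alt = rowMeans(A),
               log2fc = l2fc, t = tt$t, p = tt$p, fdr = fdr,
               deg = fdr < max_fdr & abs(l2fc) > log2(min_fc),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "n_deg_union") <- length(unique(res$gene[res$deg]))
  attr(res, "conditions") <- c(ref = condition_ref, alt = cond_alt)
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Fisher overlap enrichment between two gene lists
#'
#' Builds the 2x2 membership table of `list_a` x `list_b` over `background`
#' and reports the sample odds ratio ad/bc (with the Haldane 0.5 correction
#' when any cell is zero, flagged) and the two-sided Fisher exact p-value.
#'
#' @param list_a,list_b gene-id vectors, subsets of `background`.
#' @param background the gene universe (e.g. the HVG panel).
#' @return list: `odds_ratio`, `p_value`, `table` (2x2), `corrected`
#'   (logical; TRUE when the Haldane correction was applied).
#' @export
overlap_enrichment <- function(list_a, list_b, background) {
  if (!length(background)) stop("overlap_enrichment: empty background")
  if (!all(list_a %in% background) || !all(list_b %in% background))
    stop("overlap_enrichment: lists must be subsets of the background")
  in_a <- background %in% list_a
  in_b <- background %in% list_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), 2, 2,
                dimnames = list(a = c("in", "out"), b = c("in", "out")))
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(odds_ratio = unname(or), p_value = p, table = tab,
       corrected = corrected)
}

#' Group identity genes by their pattern of regulation across types
#'
#' Each identity gene gets a per-type status from the DEG table (`up`,
#' `down`, or `0`), a pattern string over the A/B/C types, and a group from
#' the pattern -> group rule table. The default six-group mapping — by
#' direction and by how many types respond — is a documented reconstruction:
#' up in all three types (group 1), up in exactly two (group 2, e.g. genes
#' up-regulated in types B and C but unchanged in A), up in one (group 3),
#' down in all three (group 4), down in two (group 5), down in one (group
#' 6); genes with no significant change in any type are
#' `vision-independent identity`, mixed up/down patterns are `mixed`.
#'
#' @param deg a [pseudobulk_deg()] table covering the types.
#' @param identity_sets named list of identity gene sets (the genes to
#'   classify: their union).
#' @param ieg_set optional IEG list; when given, the three-way overlap
#'   counts (vision-dependent x identity x IEG) are attached.
#' @param rules optional data.frame(pattern, group) overriding the mapping.
#' @param types the types whose calls must all be present (default: A/B/C).
#' @return data.frame: `gene`, `pattern` (e.g. `0/up/up` over types in
#'   sorted order), `group`; attribute `overlap_counts` when `ieg_set` is
#'   given.
#' @export
classify_regulation_groups <- function(deg, identity_sets, ieg_set = NULL,
                                       rules = NULL, types = c("A", "B", "C")) {
  if (!all(types %in% deg$type))
    stop("classify_regulation_groups: missing per-type calls for type(s) ",
         paste(setdiff(types, deg$type), collapse = ", "))
  genes <- sort(unique(unlist(identity_sets)))
  status <- matrix("0", length(genes), length(types),
                   dimnames = list(genes, types))
  for (ty in types) {
    sub <- deg[deg$type == ty, ]
    idx <- match(genes, sub$gene)
    if (anyNA(idx))
      stop("classify_regulation_groups: missing per-type calls for some genes")
    s <- ifelse(sub$deg[idx], ifelse(sub$log2fc[idx] > 0, "up", "down"), "0")
    status[, ty] <- s
  }
  pattern <- apply(status, 1, paste, collapse = "/")
  n_up <- rowSums(status == "up")
  n_dn <- rowSums(status == "down")
  group <- rep("mixed", length(genes))
  group[n_up == 0 & n_dn == 0] <- "vision-independent identity"
  group[n_up == 3 & n_dn == 0] <- "group1: up in all types"
  group[n_up == 2 & n_dn == 0] <- "group2: up in two types"
  group[n_up == 1 & n_dn == 0] <- "group3: up in one type"
  group[n_dn == 3 & n_up == 0] <- "group4: down in all types"
  group[n_dn == 2 & n_up == 0] <- "group5: down in two types"
  group[n_dn == 1 & n_up == 0] <- "group6: down in one type"
  if (!is.null(rules)) {
    hit <- match(pattern, rules$pattern)
    group[!is.na(hit)] <- rules$group[hit[!is.na(hit)]]
  }
  out <- data.frame(gene = genes, pattern = pattern, group = group,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(ieg_set)) {
    vd <- unique(deg$gene[deg$deg])
    idg <- genes
    attr(out, "overlap_counts") <- c(
      vision_dependent = length(vd),
      identity = length(idg),
      ieg = length(ieg_set),
      vd_and_identity = length(intersect(vd, idg)),
      vd_and_ieg = length(intersect(vd, ieg_set)),
      identity_and_ieg = length(intersect(idg, ieg_set)),
      all_three = length(Reduce(intersect, list(vd, idg, ieg_set))))
  }
  out
}
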