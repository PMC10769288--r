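make_pb_data <- function(n_genes = 40, cells_per_sample = 40,
                         planted = NULL, fold = 4, seed = 81) {
  set.seed(seed)
  smp <- rep(sprintf("s%d", 1:8), each = cells_per_sample)
  cond <- ifelse(smp %in% sprintf("s%d", 1:4), "NR", "DR")
  lam <- matrix(10, length(smp), n_genes)
  if (!is.null(planted)) lam[cond == "DR", planted] <- 10 * fold
  cnt <- matrix(rpois(length(lam), lam), nrow = length(smp))
  colnames(cnt) <- sprintf("g%03d", seq_len(n_genes))
  list(counts = cnt, type = rep("T1", length(smp)), sample = smp,
       condition = cond)
}

test_that("pseudo-bulk DEG flags a planted 4-fold gene with the textbook t", {
  d <- make_pb_data(planted = 1)
  deg <- pseudobulk_deg(d$counts, d$type, d$sample, d$condition)
  row <- deg[deg$gene == "g001", ]
  expect_true(row$deg)
  expect_gt(row$log2fc, 1)
  # oracle: hand-computed pooled t on the 8 per-sample CPM values
  cpm <- vapply(sprintf("s%d", 1:8), function(s) {
    cs <- colSums(d$counts[d$sample == s, ])
    (cs / sum(cs) * 1e6)[1]
  }, numeric(1))
  tt <- t.test(cpm[5:8], cpm[1:4], var.equal = TRUE)
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  # FDR is monotone-consistent with p under BH
  o <- order(deg$p)
  expect_true(all(diff(cummin(rev(deg$fdr[o]))) <= 1e-15))
})

test_that("constant pseudo-bulk profiles are never DEGs", {
  d <- make_pb_data()
  # make gene 2 exactly proportional everywhere: equal CPM in every sample
  cnt <- d$counts
  cnt[, ] <- 10
  deg <- pseudobulk_deg(cnt, d$type, d$sample, d$condition)
  expect_true(all(deg$p == 1))
  expect_false(any(deg$deg))
})

test_that("pseudo-bulk DEG enforces replicate and condition structure", {
  d <- make_pb_data()
  expect_error(pseudobulk_deg(d$counts, d$type, d$sample,
                              rep("NR", length(d$type))),
               "two conditions")
  one_rep <- d$sample %in% c("s1", "s5", "s6")
  expect_error(pseudobulk_deg(d$counts[one_rep, ], d$type[one_rep],
                              d$sample[one_rep], d$condition[one_rep]),
               ">= 2 samples")
  expect_error(pseudobulk_deg(d$counts, d$type, d$sample, d$condition,
                              condition_ref = "XX"), "condition_ref")
})

test_that("empirical FDR stays at or below nominal on null simulations", {
  set.seed(82)
  false_pos <- 0; tested <- 0
  for (r in 1:20) {
    smp <- rep(sprintf("s%d", 1:8), each = 25)
    cond <- ifelse(smp %in% sprintf("s%d", 1:4), "NR", "DR")
    base <- exp(runif(1000, log(1), log(50)))
    sf <- rlnorm(8, 0, 0.1)[as.integer(factor(smp))]
    lam <- outer(sf, base)
    cnt <- matrix(rpois(length(lam), lam), nrow = length(smp))
    colnames(cnt) <- sprintf("g%04d", 1:1000)
    deg <- pseudobulk_deg(cnt, rep("T1", length(smp)), smp, cond)
    false_pos <- false_pos + sum(deg$deg)
    tested <- tested + nrow(deg)
  }
  # all calls are false positives here; the fraction must not exceed the
  # nominal FDR (0.05) — in practice the |log2FC| > 1 gate keeps it near 0
  expect_lte(false_pos / max(tested, 1), 0.05)
})

test_that("Fisher overlap matches a direct hypergeometric enumeration", {
  bg <- sprintf("x%03d", 1:100)
  A <- bg[1:20]; B <- bg[c(1:10, 21:30)]   # table (10, 10, 10, 70)
  oe <- overlap_enrichment(A, B, bg)
  expect_equal(oe$odds_ratio, 7)           # ad / bc = 10*70 / (10*10)
  # two-sided p by direct hypergeometric summation over all tables
  probs <- dhyper(0:20, 20, 80, 20)
  p_oracle <- sum(probs[probs <= dhyper(10, 20, 80, 20) * (1 + 1e-7)])
  expect_equal(oe$p_value, p_oracle, tolerance = 1e-9)
  expect_false(oe$corrected)
  # perfect association: corrected finite OR with a flag
  half <- bg[1:50]
  oe2 <- overlap_enrichment(half, half, bg)
  expect_true(oe2$corrected)
  expect_true(is.finite(oe2$odds_ratio))
  expect_lt(oe2$p_value, 1e-20)
  expect_error(overlap_enrichment(A, B, character()), "background")
  expect_error(overlap_enrichment(c(A, "zzz"), B, bg), "subsets")
})

test_that("independent lists give calibrated overlap p-values", {
  set.seed(83)
  n_rep <- 400
  bg <- sprintf("g%04d", 1:400)
  p <- vapply(seq_len(n_rep), function(r) {
    overlap_enrichment(sample(bg, 80), sample(bg, 80), bg)$p_value
  }, numeric(1))
  # super-uniformity at several levels (Fisher p is discrete, conservative)
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
})

test_that("regulation groups follow the pattern rule table", {
  # plant one gene per pattern over three types and check the mapping
  types <- c("A", "B", "C")
  pat <- expand.grid(A = c("0", "up", "down"), B = c("0", "up", "down"),
                     C = c("0", "up", "down"), stringsAsFactors = FALSE)
  genes <- sprintf("gene%02d", seq_len(nrow(pat)))
  deg <- do.call(rbind, lapply(seq_along(types), function(t_i) {
    s <- pat[[types[t_i]]]
    data.frame(gene = genes, type = types[t_i],
               log2fc = ifelse(s == "up", 2, ifelse(s == "down", -2, 0.1)),
               fdr = ifelse(s == "0", 0.9, 0.01),
               deg = s != "0", stringsAsFactors = FALSE)
  }))
  out <- classify_regulation_groups(deg, list(identity = genes),
                                    ieg_set = genes[1:5])
  # independent rule-table oracle
  oracle <- apply(pat, 1, function(s) {
    nu <- sum(s == "up"); nd <- sum(s == "down")
    if (nu == 0 && nd == 0) "vision-independent identity"
    else if (nu == 3 && nd == 0) "group1: up in all types"
    else if (nu == 2 && nd == 0) "group2: up in two types"
    else if (nu == 1 && nd == 0) "group3: up in one type"
    else if (nd == 3 && nu == 0) "group4: down in all types"
    else if (nd == 2 && nu == 0) "group5: down in two types"
    else if (nd == 1 && nu == 0) "group6: down in one type"
    else "mixed"
  })
  expect_identical(out$group[match(genes, out$gene)], unname(oracle))
  # the documented two-up pattern: up in B and C, unchanged in A
  g2 <- genes[pat$A == "0" & pat$B == "up" & pat$C == "up"]
  expect_identical(out$group[out$gene == g2], "group2: up in two types")
  oc <- attr(out, "overlap_counts")
  expect_equal(unname(oc["identity"]), length(genes))
  expect_equal(unname(oc["vd_and_identity"]),
               length(unique(deg$gene[deg$deg])))
  expect_error(classify_regulation_groups(deg[deg$type != "C", ],
                                          list(identity = genes)),
               "missing")
})
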