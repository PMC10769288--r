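make_toy <- function(counts, volume = NULL, blanks = NULL, sample = NULL) {
  n <- nrow(counts)
  meta <- data.frame(cell_id = rownames(counts) %||% sprintf("c%02d", 1:n))
  rownames(counts) <- meta$cell_id
  if (!is.null(volume)) meta$volume <- volume
  if (!is.null(blanks)) meta$blanks <- blanks
  if (!is.null(sample)) meta$sample <- sample
  count_matrix(counts, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC removes cells violating volume, count and blank-rate rules", {
  cnt <- matrix(20, 5, 4)
  m <- make_toy(cnt, volume = c(30, 50, 100, 2000, 2500), blanks = rep(0, 5))
  kept <- qc_filter_cells(m, volume_range = c(50, 2000))
  expect_equal(nrow(kept$counts), 3)       # enumerated: volumes 50, 100, 2000
  expect_identical(kept$cell_ids, m$cell_ids[2:4])  # order preserved
  # a stricter pass with > 50 transcripts is a separate call
  strict <- qc_filter_cells(m, min_transcripts = 50)
  expect_equal(nrow(strict$counts), 3)     # totals 80 > 50 everywhere
  strict2 <- qc_filter_cells(m, min_transcripts = 80)
  expect_equal(nrow(strict2$counts), 0)    # strictly greater than
  # blank rate boundary: blanks/(blanks+total) must be strictly < threshold,
  # so 1/(1+19) = 0.05 exactly is removed
  m2 <- make_toy(matrix(19, 3, 1), volume = rep(100, 3),
                 blanks = c(0, 1, 5))
  expect_equal(nrow(qc_filter_cells(m2)$counts), 1)
  expect_error(qc_filter_cells(make_toy(matrix(1, 2, 2))), "volume")
})

test_that("MERFISH normalization hits the target mean exactly per sample", {
  sec <- simulate_cortical_section(tiny_section_spec(seed = 7))
  m <- qc_filter_cells(sec$matrix)
  iegs <- sec$truth$gene_sets$iegs
  nm <- normalize_merfish(m, target_mean = 250, exclude = iegs)
  x <- 10^nm$lognorm - 1
  keep <- setdiff(colnames(x), iegs)
  for (s in unique(m$cell_meta$sample)) {
    tot <- mean(rowSums(x[m$cell_meta$sample == s, keep]))
    expect_equal(tot, 250, tolerance = 1e-12)
  }
  expect_identical(nm$excluded_genes, iegs)
  expect_gte(length(nm$provenance), 4)
})

test_that("volume division is linear: half the volume doubles the values", {
  cnt <- rbind(c(10, 20), c(10, 20))
  m <- make_toy(cnt, volume = c(100, 200))
  nm <- normalize_merfish(m, target_mean = 250)
  x <- 10^nm$lognorm - 1
  expect_equal(x[1, ], 2 * x[2, ], tolerance = 1e-12)
})

test_that("one-sample toy gets the arithmetic scale factor 1.25", {
  # volume-normalized non-excluded totals (100, 300) -> factor 1.25
  cnt <- rbind(c(60, 40), c(180, 120))
  m <- make_toy(cnt, volume = c(1, 1))
  nm <- normalize_merfish(m, target_mean = 250)
  x <- 10^nm$lognorm - 1
  expect_equal(rowSums(x), c(125, 375), tolerance = 1e-12,
               ignore_attr = TRUE)
  m0 <- make_toy(matrix(0, 2, 2), volume = c(1, 1),
                 sample = c("bad", "bad"))
  expect_error(normalize_merfish(m0), "bad")
})

test_that("snRNA-seq normalization rescales to 10k, with the documented log", {
  cnt <- rbind(c(1, 3), c(5, 5), c(0, 0))
  rownames(cnt) <- c("a", "b", "empty")
  m <- count_matrix(cnt)
  expect_warning(nm <- normalize_snrnaseq(m), "all-zero")
  cp10k <- 10^nm$lognorm - 1
  expect_equal(unname(rowSums(cp10k)), c(10000, 10000), tolerance = 1e-9)
  expect_equal(unname(nm$lognorm["a", ]), log10(c(2501, 7501)),
               tolerance = 1e-12)
  # all-zero gene gives an identically zero log layer
  cnt2 <- cbind(c(3, 5), c(0, 0)); rownames(cnt2) <- c("a", "b")
  nm2 <- normalize_snrnaseq(count_matrix(cnt2))
  expect_true(all(nm2$lognorm[, 2] == 0))
})

test_that("z-layer is standardized per gene within tolerance", {
  sim <- simulate_continuum(n_cells = 200, n_genes = 20, seed = 8)
  nm <- suppressWarnings(normalize_snrnaseq(sim$matrix))
  expect_true(all(abs(colMeans(nm$z)) < 1e-8))
  sds <- apply(nm$z, 2, sd)
  expect_true(all(abs(sds - 1) < 1e-6))
  # determinism: same input, bit-identical output
  nm2 <- suppressWarnings(normalize_snrnaseq(sim$matrix))
  expect_identical(nm$z, nm2$z)
})

test_that("HVG selection honours thresholds and recovers planted dispersion", {
  set.seed(11)
  ng <- 200; nc <- 400
  mu <- exp(runif(ng, log(0.5), log(20)))
  cnt <- vapply(mu, function(m) rpois(nc, m), numeric(nc))
  planted <- c(10, 100, 190)
  for (j in planted) cnt[, j] <- rnbinom(nc, size = 0.5, mu = mu[j])
  colnames(cnt) <- sprintf("g%03d", seq_len(ng))
  m <- count_matrix(cnt)
  hv <- select_hvgs(m, min_cells = 10, n_bins = 10, top_fraction = 0.30)
  expect_true(all(sprintf("g%03d", planted) %in% hv))
  # oracle: within each decile bin the kept genes have the top ratios
  cp10k <- cnt / rowSums(cnt) * 1e4
  keep <- colSums(cnt > 0) >= 10
  mu_k <- colMeans(cp10k[, keep]); ratio <- apply(cp10k[, keep], 2, var) / mu_k
  r <- rank(mu_k, ties.method = "min")
  bin <- floor((r - 1) * 10 / length(mu_k)) + 1
  oracle <- unlist(lapply(split(seq_along(mu_k), bin), function(idx)
    names(sort(ratio[idx], decreasing = TRUE))[seq_len(ceiling(0.3 * length(idx)))]))
  expect_setequal(hv, oracle)
  # a gene in < min_cells cells is excluded before binning
  cnt2 <- cnt; cnt2[, 5] <- 0; cnt2[1:5, 5] <- 1
  hv2 <- select_hvgs(count_matrix(cnt2))
  expect_false("g005" %in% hv2)
  # invariance to gene order permutation
  perm <- sample(ng)
  hv3 <- select_hvgs(count_matrix(cnt[, perm]))
  expect_setequal(hv3, hv)
  expect_error(select_hvgs(m, n_bins = 1000), "n_bins")
})

test_that("identity-gene derivation detects a planted 4-fold marker", {
  set.seed(12)
  lab <- rep(c("A", "B"), each = 200)
  cnt <- matrix(rpois(400 * 30, 5), 400)
  colnames(cnt) <- sprintf("g%02d", 1:30)
  cnt[lab == "A", 1] <- rpois(200, 20)
  mk <- derive_identity_genes(count_matrix(cnt), lab)
  row <- mk[mk$gene == "g01" & mk$type == "A", ]
  expect_true(row$marker)
  expect_gt(row$fc, 2)
  expect_gt(row$frac_in, 0.8)
  # oracle: explicit rank-sum on the log-normalized values
  cp10k <- cnt / rowSums(cnt) * 1e4
  x <- log10(cp10k[, 1] + 1)
  r <- rank(x)
  n1 <- 200; n2 <- 200
  W <- sum(r[lab == "A"]) - n1 * (n1 + 1) / 2
  ties <- table(x)
  sig2 <- n1 * n2 / 12 * ((400 + 1) - sum(ties^3 - ties) / (400 * 399))
  z <- (W - n1 * n2 / 2 - 0.5) / sqrt(sig2)
  p_oracle <- 2 * pnorm(-abs(z))
  expect_equal(row$p, p_oracle, tolerance = 1e-12)
  # a gene identical across types is never a marker
  expect_false(any(mk$marker[mk$gene == "g02"]))
})

test_that("identity-gene derivation enforces its preconditions", {
  cnt <- matrix(rpois(40, 5), 10, 4)
  expect_error(derive_identity_genes(count_matrix(cnt),
                                     rep("A", 10)),
               ">= 2 usable types")
  expect_warning(
    mk <- derive_identity_genes(count_matrix(matrix(rpois(120, 5), 30, 4)),
                                c(rep("A", 14), rep("B", 14), "C", "C")),
    "< 3 cells")
  expect_false("C" %in% mk$type)
})
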