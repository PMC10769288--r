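test_that("identity-gene PCA yields orthonormal loadings and a full spectrum", {
  set.seed(41)
  X <- matrix(rnorm(200 * 12), 200)
  colnames(X) <- sprintf("g%02d", 1:12)
  p <- pca_identity(X, n_components = 6)
  G <- crossprod(p$loadings)
  expect_lt(max(abs(G - diag(6))), 1e-8)  # |vi . vj| = 1 iff i = j
  expect_equal(length(p$eig), 12)
  expect_true(all(diff(p$eig) <= 1e-9))
  # rank-2 planted data: third eigenvalue < 1e-8 x first
  B <- matrix(rnorm(200 * 2), 200) %*% matrix(rnorm(2 * 12), 2)
  colnames(B) <- colnames(X)
  p2 <- pca_identity(B, n_components = 5)
  expect_lt(p2$eig[3], 1e-8 * p2$eig[1])
  expect_error(pca_identity(X[1:3, ], n_components = 6), "fewer cells")
  expect_error(pca_identity(X, gene_set = "nope"), "absent")
})

test_that("top-2 PCs capture a planted 3-archetype mixture", {
  am <- simulate_archetype_mixture(n_cells = 500, n_genes = 60, seed = 42)
  X <- am$matrix$counts
  p <- pca_identity(X, n_components = 10)
  # the planted (noise-free) signal lives in the 2-D simplex spanned by the
  # archetype profiles; its variance must lie in the top-2 PC subspace
  signal <- 100 * (am$truth$weights %*% am$truth$archetype_profiles)
  sc <- sweep(signal, 2, colMeans(signal))
  proj <- sc %*% p$loadings[, 1:2]
  expect_gt(sum(proj^2) / sum(sc^2), 0.95)
})

test_that("PCHA is exact on three points and idempotent", {
  tri <- rbind(c(0, 0), c(4, 0), c(1, 3))
  f <- fit_archetypes(tri, 3)
  m <- l23continuum:::match_archetypes(f$archetypes, tri)
  expect_lt(max(m$d), 1e-6)
  expect_equal(f$sse, 0, tolerance = 1e-12)
  # refitting data already equal to three points reproduces them
  f2 <- fit_archetypes(tri[c(2, 3, 1), ], 3)
  m2 <- l23continuum:::match_archetypes(f2$archetypes, tri)
  expect_lt(max(m2$d), 1e-6)
})

test_that("PCHA recovers tight planted corners within 3%", {
  set.seed(43)
  ctr <- rbind(c(0, 0), c(10, 0), c(5, 8))
  sepmin <- min(dist(ctr))
  X <- ctr[rep(1:3, each = 150), ] +
    matrix(rnorm(900, 0, 0.01 * sepmin), ncol = 2)  # SD = 1% of separation
  f <- fit_archetypes(X, 3)
  m <- l23continuum:::match_archetypes(f$archetypes, ctr)
  expect_lt(mean(m$d) / sepmin, 0.03)
  expect_error(fit_archetypes(cbind(1:50, 2 * (1:50)), 3), "collinear")
  expect_error(fit_archetypes(X, 3, delta = 0.1), "delta")
})

test_that("the minimal enclosing triangle matches brute-force oracles", {
  # points = a triangle's own vertices: t-ratio exactly 1
  tri <- rbind(c(0, 0), c(4, 0), c(1, 3))
  expect_equal(t_ratio(tri), 1, tolerance = 1e-9)
  met <- min_enclosing_triangle(tri)
  expect_equal(met$area, 6, tolerance = 1e-9)
  # unit square: t-ratio 1/2 against the hull-edge-flush brute force
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  oracle <- brute_force_met_area(sq, n_grid = 90)
  pkg <- min_enclosing_triangle(sq)$area
  expect_lt(abs(pkg - 2), 1e-6)
  expect_lte(pkg, oracle + 1e-6)        # never worse than the brute force
  expect_equal(t_ratio(sq), 0.5, tolerance = 1e-6)
  # random cloud: package triangle no larger than brute force, and encloses
  set.seed(44)
  pts <- matrix(rnorm(60), 30)
  a_pkg <- min_enclosing_triangle(pts)
  expect_lte(a_pkg$area, brute_force_met_area(pts, n_grid = 60) + 1e-4)
  # containment of every point
  v <- a_pkg$vertices
  for (k in 1:3) {
    e1 <- v[k %% 3 + 1, ] - v[k, ]
    inside <- (pts[, 1] - v[k, 1]) * e1[2] - (pts[, 2] - v[k, 2]) * e1[1]
    expect_true(all(inside <= 1e-8) || all(inside >= -1e-8))
  }
  expect_error(min_enclosing_triangle(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("uniform disc t-ratio approaches the closed-form limit", {
  set.seed(45)
  th <- runif(2000, 0, 2 * pi); r <- sqrt(runif(2000))
  disc <- cbind(r * cos(th), r * sin(th))
  expect_lt(abs(t_ratio(disc) - pi / (3 * sqrt(3))), 0.02)
})

test_that("t-ratio test separates triangular data from its shuffle null", {
  am <- simulate_archetype_mixture(n_cells = 400, n_genes = 45, seed = 46)
  tf <- t_ratio_test(am$matrix$counts, n_shuffles = 99, seed = 46)
  expect_equal(tf$p_value, 1 / 100)  # observed beats every null draw
  expect_true(all(tf$null_t_ratios < tf$t_ratio))
  # spherical Gaussians: no triangular structure, so the p-value behaves
  # like a uniform draw; the median over replicate datasets stays large
  ps <- vapply(47:49, function(s) {
    set.seed(s)
    G <- matrix(rnorm(400 * 45), 400)
    t_ratio_test(G, n_shuffles = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.1)
  expect_error(t_ratio_test(matrix(rnorm(40), 10), n_shuffles = 0),
               "n_shuffles")
})

test_that("t-ratio p-values are super-uniform under the global-shuffle null", {
  # data already matching the null: each gene an independent permutation
  set.seed(48)
  n_rep <- 120
  p <- vapply(seq_len(n_rep), function(r) {
    X <- matrix(rnorm(40 * 8), 40)
    t_ratio_test(X, n_shuffles = 19, seed = 100 + r)$p_value
  }, numeric(1))
  # P(p <= 0.1) should not exceed 0.1 by more than binomial noise (3 SD)
  expect_lte(mean(p <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / n_rep))
})

test_that("archetypes are stable under subsampling of planted clusters", {
  set.seed(49)
  ctr <- rbind(c(0, 0), c(10, 0), c(5, 8))
  Z <- ctr[rep(1:3, each = 100), ] + matrix(rnorm(600, 0, 0.3), ncol = 2)
  X <- cbind(Z, matrix(rnorm(300 * 4, 0, 0.1), 300))  # 2-D signal + noise dims
  colnames(X) <- sprintf("g%d", 1:6)
  st <- archetype_stability(X, subsample_fraction = 0.8, n_trials = 10,
                            seed = 50)
  expect_lt(median(st$displacement, na.rm = TRUE), 0.05)
  # fraction 1.0 on cells with the fixed PCA basis: zero displacement
  st1 <- archetype_stability(X, subsample_fraction = 1, n_trials = 2,
                             over = "cells", seed = 51)
  expect_lt(max(st1$displacement), 1e-4)  # zero up to optimizer tolerance
})
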