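test_that("density difference is zero on identical samples and conserves mass", {
  set.seed(71)
  A <- matrix(rnorm(400), 200)
  dd <- density_difference(A, A, binwidth = 1.25)
  expect_true(all(dd$diff == 0))
  B <- matrix(rnorm(300, 1), 150)
  dd2 <- density_difference(A, B)
  expect_equal(sum(dd2$diff), 0, tolerance = 1e-12)
  expect_equal(sum(dd2$hist_a), 1, tolerance = 1e-12)
  # a point mass moved one bin: exactly one +mass and one -mass bin
  p1 <- matrix(c(0.5, 0.5), 1)
  p2 <- matrix(c(1.75, 0.5), 1)
  dd3 <- density_difference(p1, p2, binwidth = 1)
  expect_equal(sum(dd3$diff > 0), 1)
  expect_equal(sum(dd3$diff < 0), 1)
  expect_error(density_difference(A[0, ], B), "empty")
})

test_that("JS distance obeys its closed forms and metric properties", {
  h1 <- c(1, 0, 0, 0); h2 <- c(0, 0, 1, 0)
  expect_equal(js_divergence(h1, h1), 0)
  expect_equal(js_divergence(h1, h2), sqrt(log(2)), tolerance = 1e-12)
  expect_equal(js_divergence(h1, h2, base = 2), 1, tolerance = 1e-12)
  set.seed(72)
  for (r in 1:25) {
    a <- rexp(12); b <- rexp(12); c <- rexp(12)
    expect_equal(js_divergence(a, b), js_divergence(b, a))
    # triangle inequality of the JS distance
    expect_lte(js_divergence(a, c),
               js_divergence(a, b) + js_divergence(b, c) + 1e-12)
  }
  expect_error(js_divergence(matrix(1, 2, 2), matrix(1, 3, 3)), "grids")
  expect_error(js_divergence(c(1, -1), c(1, 1)), "negative")
})

test_that("optimal transport solves tiny instances exactly", {
  # two stacked pairs: each source matched to the target directly above
  src <- rbind(c(0, 0), c(1, 0)); tgt <- rbind(c(0, 1), c(1, 1))
  ot <- optimal_transport_map(src, tgt)
  expect_equal(ot$coupling, diag(2) / 2, tolerance = 1e-12)
  expect_equal(ot$cost_total, 1, tolerance = 1e-12)
  expect_equal(brute_force_ot_cost(src, tgt), 1)
  # identical point sets: zero cost, coupling on identical pairs
  set.seed(73)
  P <- matrix(runif(12), 6)
  ot0 <- optimal_transport_map(P, P)
  expect_equal(ot0$cost_total, 0, tolerance = 1e-12)
  expect_equal(ot0$coupling, diag(6) / 6, tolerance = 1e-12)
})

test_that("transport cost equals the exhaustive minimum for n <= 6", {
  set.seed(74)
  for (n in c(3, 4, 5, 6)) {
    S <- matrix(runif(2 * n), n); Tt <- matrix(runif(2 * n), n)
    ot <- optimal_transport_map(S, Tt)
    expect_equal(ot$cost_total, brute_force_ot_cost(S, Tt),
                 tolerance = 1e-10)
    expect_lt(max(abs(rowSums(ot$coupling) - 1 / n)), 1e-8)
    expect_lt(max(abs(colSums(ot$coupling) - 1 / n)), 1e-8)
  }
  # euclidean-cost variant agrees with its own brute force
  S <- matrix(runif(10), 5); Tt <- matrix(runif(10), 5)
  ot_e <- optimal_transport_map(S, Tt, cost = "euclidean")
  expect_equal(ot_e$cost_total, brute_force_ot_cost(S, Tt, "euclidean"),
               tolerance = 1e-10)
  expect_error(optimal_transport_map(S[0, ], Tt), "empty")
})

test_that("transport agrees with an independent Hungarian solver", {
  skip_if_not_installed("clue")
  set.seed(75)
  for (r in 1:8) {
    n <- sample(5:25, 1)
    S <- matrix(rnorm(2 * n), n); Tt <- matrix(rnorm(2 * n), n)
    ot <- optimal_transport_map(S, Tt)
    D <- as.matrix(dist(rbind(S, Tt)))[1:n, n + 1:n]^2
    lsap <- clue::solve_LSAP(D)
    expect_equal(ot$cost_total,
                 sum(D[cbind(1:n, lsap)]) / n, tolerance = 1e-9)
  }
  # unequal sizes keep exact uniform marginals
  ot2 <- optimal_transport_map(matrix(runif(14), 7), matrix(runif(22), 11))
  expect_lt(max(abs(rowSums(ot2$coupling) - 1 / 7)), 1e-10)
  expect_lt(max(abs(colSums(ot2$coupling) - 1 / 11)), 1e-10)
})

test_that("the coarse vector field is translation-equivariant", {
  set.seed(76)
  src <- cbind(runif(120), runif(120))
  tgt <- sweep(src, 2, c(2, 0), "+")
  tr <- optimal_transport_map(src, tgt)
  vf <- coarse_grained_vector_field(tr, src, tgt, grid_binwidth = 0.25)
  expect_lt(max(abs(vf$dx - 2)), 1e-6)
  expect_lt(max(abs(vf$dy)), 1e-6)
  # target = source: all vectors zero
  tr0 <- optimal_transport_map(src, src)
  vf0 <- coarse_grained_vector_field(tr0, src, src, grid_binwidth = 0.25)
  expect_lt(max(abs(c(vf0$dx, vf0$dy))), 1e-9)
  # arrows never exceed the number of occupied bins
  occupied <- length(unique(paste(floor(src[, 1] / 0.25),
                                  floor(src[, 2] / 0.25))))
  expect_lte(nrow(vf), occupied)
  expect_equal(sum(vf$n_cells), nrow(src))
})

test_that("focused K-means recovers matched planted types", {
  set.seed(77)
  ctr <- matrix(rnorm(3 * 10, sd = 4), 3)
  Z <- ctr[rep(1:3, each = 120), ] + matrix(rnorm(360 * 10, 0, 0.5), 360)
  colnames(Z) <- sprintf("id%02d", 1:10)
  cl <- focused_kmeans(Z, k = 3, seed = 7)
  truth <- rep(1:3, each = 120)
  # adjusted Rand via mclust-free contingency computation
  tab <- table(cl, truth)
  a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2)); d <- choose(sum(tab), 2)
  ari <- (a - b * c2 / d) / ((b + c2) / 2 - b * c2 / d)
  expect_gt(ari, 0.95)
  expect_identical(cl, focused_kmeans(Z, k = 3, seed = 7))  # deterministic
  expect_identical(focused_kmeans(Z, k = 1, seed = 1), rep(1L, 360))
  expect_error(focused_kmeans(Z[1:2, ], k = 5), "exceeds")
})
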