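# Shared fixtures: a reduced cortical section for fast tests, and small
# geometric helpers used as independent oracles.

tiny_section_spec <- function(seed = 1) {
  spatial_section_spec(
    n_cells_per_subclass = c(VLMC = 60, L23 = 200, L4 = 60, L5 = 60, L6 = 60),
    seed = seed)
}

# Independent brute-force minimal enclosing triangle: one side flush with a
# hull edge, the other two tangent lines on a dense angular grid (plus local
# refinement by a finer pass around the best). Used only as an oracle.
brute_force_met_area <- function(points, n_grid = 120) {
  hull <- points[grDevices::chull(points), , drop = FALSE]
  hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  hn <- nrow(hull)
  e <- hull[c(2:hn, 1), , drop = FALSE] - hull
  edge_theta <- atan2(-e[, 1], e[, 2])
  supp <- function(th) {
    H <- hull %*% rbind(cos(th), sin(th))
    apply(H, 2, max)
  }
  tri_area <- function(th) {
    h <- supp(th)
    cs <- cos(th); sn <- sin(th)
    v <- matrix(NA_real_, 3, 2)
    for (k in 1:3) {
      i <- k; j <- k %% 3 + 1
      det <- cs[i] * sn[j] - sn[i] * cs[j]
      if (abs(det) < 1e-12) return(Inf)
      v[k, ] <- c((h[i] * sn[j] - h[j] * sn[i]) / det,
                  (h[j] * cs[i] - h[i] * cs[j]) / det)
    }
    for (k in 1:3)
      if (any(cs[k] * v[, 1] + sn[k] * v[, 2] > h[k] + 1e-7)) return(Inf)
    a <- abs(v[1, 1] * (v[2, 2] - v[3, 2]) + v[2, 1] * (v[3, 2] - v[1, 2]) +
               v[3, 1] * (v[1, 2] - v[2, 2])) / 2
    if (a < 1e-12) Inf else a
  }
  gg <- seq(0.02, 2 * pi - 0.02, length.out = n_grid)
  best <- Inf
  for (t1 in edge_theta) {
    for (o2 in gg) for (o3 in gg) {
      if (o3 <= o2) next
      a <- tri_area(c(t1, t1 + o2, t1 + o3))
      if (a < best) { best <- a; bth <- c(t1, t1 + o2, t1 + o3) }
    }
  }
  # refine around the best on a 10x finer grid
  step <- diff(gg)[1]
  f2 <- seq(-step, step, length.out = 21)
  for (d2 in f2) for (d3 in f2) {
    a <- tri_area(bth + c(0, d2, d3))
    if (a < best) best <- a
  }
  best
}

# Exhaustive equal-size optimal transport cost (uniform weights) over all
# assignments; n <= 6.
brute_force_ot_cost <- function(S, Tt, cost = "sqeuclidean") {
  n <- nrow(S)
  stopifnot(n == nrow(Tt), n <= 6)
  D <- as.matrix(stats::dist(rbind(S, Tt)))[seq_len(n), n + seq_len(n),
                                            drop = FALSE]^2
  if (cost == "euclidean") D <- sqrt(D)
  perms <- permutations_of(n)
  min(apply(perms, 1, function(p) sum(D[cbind(seq_len(n), p)]))) / n
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
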