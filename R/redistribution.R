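# Quantifying condition-driven redistribution on the identity manifold:
# paired 2-D densities, Jensen-Shannon distance, exact optimal transport,
# and a coarse-grained displacement field.

#' Paired 2-D density histograms and their difference
#'
#' Bins both embeddings on a shared equal-width grid covering their union,
#' normalizes each histogram to total probability 1, and returns the
#' difference hist_a - hist_b (which sums to 0 by construction).
#'
#' @param emb_a,emb_b n x 2 embeddings on the same axes (e.g. PC1-PC2).
#' @param binwidth bin width in embedding units (1-1.5 PC units typical).
#' @return list of class `density_diff`: `hist_a`, `hist_b`, `diff`
#'   (matrices), `xbreaks`, `ybreaks`.
#' @export
density_difference <- function(emb_a, emb_b, binwidth = 1.25) {
  emb_a <- as.matrix(emb_a); emb_b <- as.matrix(emb_b)
  if (nrow(emb_a) == 0 || nrow(emb_b) == 0)
    stop("density_difference: empty input")
  all_pts <- rbind(emb_a, emb_b)
  xb <- seq(floor(min(all_pts[, 1]) / binwidth) * binwidth,
            max(all_pts[, 1]) + binwidth, by = binwidth)
  yb <- seq(floor(min(all_pts[, 2]) / binwidth) * binwidth,
            max(all_pts[, 2]) + binwidth, by = binwidth)
  hist2 <- function(e) {
    ix <- findInterval(e[, 1], xb, rightmost.closed = TRUE)
    iy <- findInterval(e[, 2], yb, rightmost.closed = TRUE)
    h <- matrix(0, length(xb) - 1, length(yb) - 1)
    for (r in seq_len(nrow(e))) h[ix[r], iy[r]] <- h[ix[r], iy[r]] + 1
    h / nrow(e)
  }
  ha <- hist2(emb_a); hb <- hist2(emb_b)
  structure(list(hist_a = ha, hist_b = hb, diff = ha - hb,
                 xbreaks = xb, ybreaks = yb),
            class = "density_diff")
}

#' Jensen-Shannon distance between histograms
#'
#' Square-root Jensen-Shannon divergence. The default uses the natural-log
#' base (the convention of the common scientific-python implementation), for
#' which the maximum — attained on disjoint supports — is sqrt(ln 2) ~
#' 0.8326; `base = 2` bounds it at 1. Histograms are normalized internally;
#' the result is symmetric and zero iff the inputs are equal.
#'
#' @param hist_a,hist_b histograms (matrices or vectors) on identical grids.
#' @param base logarithm base (exp(1) or 2).
#' @return Scalar JS distance.
#' @export
js_divergence <- function(hist_a, hist_b, base = exp(1)) {
  if (!identical(dim(hist_a), dim(hist_b)) ||
      length(hist_a) != length(hist_b))
    stop("js_divergence: histogram grids do not match")
  p <- as.vector(hist_a); q <- as.vector(hist_b)
  if (any(p < 0) || any(q < 0)) stop("js_divergence: negative mass")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log(a[nz], base = base) - log(b[nz], base = base)))
  }
  sqrt(pmax((kl(p, m) + kl(q, m)) / 2, 0))
}

# Exact solution of the transportation problem min <C, G> s.t. G 1 = a,
# G' 1 = b, G >= 0, by the transportation simplex (north-west start + MODI
# pivoting). Row/column duals are recomputed from the basis tree each
# iteration; ties broken by index for determinism.
transport_simplex <- function(C, a, b, max_iter = NULL, tol = 1e-12) {
  n <- length(a); m <- length(b)
  stopifnot(nrow(C) == n, ncol(C) == m, abs(sum(a) - sum(b)) < 1e-9)
  if (is.null(max_iter)) max_iter <- 50 * (n + m)^2
  G <- matrix(0, n, m)
  basis <- matrix(FALSE, n, m)
  # north-west corner initialization (n + m - 1 basic cells, possibly
  # degenerate with zero flows)
  i <- 1; j <- 1
  ra <- a; rb <- b
  while (i <= n && j <= m) {
    f <- min(ra[i], rb[j])
    G[i, j] <- f
    basis[i, j] <- TRUE
    ra[i] <- ra[i] - f
    rb[j] <- rb[j] - f
    if (i == n && j == m) break
    if (ra[i] <= rb[j] && i < n) i <- i + 1 else j <- j + 1
  }
  for (iter in seq_len(max_iter)) {
    # duals u, v with u[1] = 0 via BFS on the basis tree
    u <- rep(NA_real_, n); v <- rep(NA_real_, m)
    u[1] <- 0
    queue_r <- 1L; queue_c <- integer(0)
    while (length(queue_r) || length(queue_c)) {
      if (length(queue_r)) {
        r <- queue_r[1]; queue_r <- queue_r[-1]
        cols <- which(basis[r, ] & is.na(v))
        v[cols] <- C[r, cols] - u[r]
        queue_c <- c(queue_c, cols)
      } else {
        cc <- queue_c[1]; queue_c <- queue_c[-1]
        rows <- which(basis[, cc] & is.na(u))
        u[rows] <- C[rows, cc] - v[cc]
        queue_r <- c(queue_r, rows)
      }
    }
    red <- C - outer(u, v, "+")
    ent <- which.min(red)
    if (red[ent] >= -tol) break
    ei <- (ent - 1) %% n + 1
    ej <- (ent - 1) %/% n + 1
    # cycle: unique path from row ei to column ej through the basis tree;
    # the entering cell gets +theta, so path cells at odd positions (which
    # share a row/column chain starting at ei's row) get -theta
    path <- find_basis_path(basis, ei, ej)
    minus <- path[seq(1, nrow(path), by = 2), , drop = FALSE]
    theta <- min(G[minus])
    leave <- minus[which.min(G[minus]), , drop = FALSE]
    plus <- path[seq(2, nrow(path), by = 2), , drop = FALSE]
    G[plus] <- G[plus] + theta
    G[minus] <- G[minus] - theta
    G[ei, ej] <- G[ei, ej] + theta
    basis[ei, ej] <- TRUE
    basis[leave] <- FALSE
    G[leave] <- 0
  }
  list(coupling = G, cost = sum(C * G))
}

# Path of basic cells forming the cycle closed by entering cell (ei, ej):
# BFS over the bipartite basis graph from row ei to column ej. Returns a
# k x 2 matrix of (row, col) cells; cell 1 is (ei, first column on the
# path), alternating thereafter.
find_basis_path <- function(basis, ei, ej) {
  n <- nrow(basis); m <- ncol(basis)
  # nodes: rows 1..n, cols n+1..n+m
  prev <- rep(NA_integer_, n + m)
  seen <- rep(FALSE, n + m)
  seen[ei] <- TRUE
  queue <- ei
  target <- n + ej
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v <= n) {
      nbrs <- n + which(basis[v, ])
    } else {
      nbrs <- which(basis[, v - n])
    }
    nbrs <- nbrs[!seen[nbrs]]
    seen[nbrs] <- TRUE
    prev[nbrs] <- v
    if (target %in% nbrs) break
    queue <- c(queue, nbrs)
  }
  if (!seen[target]) stop("transport_simplex: basis tree disconnected")
  nodes <- target
  while (nodes[1] != ei) nodes <- c(prev[nodes[1]], nodes)
  cells <- matrix(0L, length(nodes) - 1, 2)
  for (s in seq_len(length(nodes) - 1)) {
    aa <- nodes[s]; bb <- nodes[s + 1]
    r <- min(aa, bb); cc <- max(aa, bb) - n
    cells[s, ] <- c(r, cc)
  }
  cells
}

#' Exact optimal transport between two point clouds
#'
#' Computes the exact earth-mover (Monge-Kantorovich) coupling between the
#' uniform empirical distributions of two planar point sets, under squared
#' Euclidean cost by default, by solving the transportation linear program
#' with a transportation-simplex solver. The coupling's row sums equal the
#' uniform source marginal and its column sums the target marginal.
#'
#' @param source_pts,target_pts n x 2 and m x 2 matrices (both non-empty).
#' @param cost `"sqeuclidean"` (default) or `"euclidean"`.
#' @return list of class `transport_result`: `coupling` (n x m), `cost_total`,
#'   `source_marginal`, `target_marginal`, `cost_convention`.
#' @export
optimal_transport_map <- function(source_pts, target_pts,
                                  cost = c("sqeuclidean", "euclidean")) {
  cost <- match.arg(cost)
  S <- as.matrix(source_pts); Tg <- as.matrix(target_pts)
  if (nrow(S) == 0 || nrow(Tg) == 0)
    stop("optimal_transport_map: empty point set")
  D2 <- outer(rowSums(S^2), rep(1, nrow(Tg))) +
    outer(rep(1, nrow(S)), rowSums(Tg^2)) - 2 * S %*% t(Tg)
  D2 <- pmax(D2, 0)
  C <- if (cost == "sqeuclidean") D2 else sqrt(D2)
  a <- rep(1 / nrow(S), nrow(S))
  b <- rep(1 / nrow(Tg), nrow(Tg))
  sol <- transport_simplex(C, a, b)
  err_r <- max(abs(rowSums(sol$coupling) - a))
  err_c <- max(abs(colSums(sol$coupling) - b))
  if (err_r > 1e-8 || err_c > 1e-8)
    stop(sprintf("optimal_transport_map: marginal violation (%.2e, %.2e)",
                 err_r, err_c))
  structure(list(coupling = sol$coupling, cost_total = sol$cost,
                 source_marginal = a, target_marginal = b,
                 cost_convention = cost),
            class = "transport_result")
}

#' Coarse-grained displacement field from a transport coupling
#'
#' For each source cell, the coupling-weighted mean target position defines a
#' displacement vector; source cells are binned on a regular grid and each
#' occupied bin reports the mean displacement of its members and the member
#' count (arrow length ~ mean displacement, darkness ~ count). Empty bins
#' are omitted.
#'
#' @param tr a [optimal_transport_map()] result.
#' @param source_pts,target_pts the point sets the coupling connects.
#' @param grid_binwidth bin width in embedding units.
#' @return data.frame: `bin_x`, `bin_y` (bin centers), `dx`, `dy`,
#'   `n_cells`.
#' @export
coarse_grained_vector_field <- function(tr, source_pts, target_pts,
                                        grid_binwidth = 1.25) {
  S <- as.matrix(source_pts); Tg <- as.matrix(target_pts)
  G <- tr$coupling
  stopifnot(nrow(G) == nrow(S), ncol(G) == nrow(Tg))
  dest <- (G %*% Tg) / rowSums(G)
  disp <- dest - S
  bx <- floor(S[, 1] / grid_binwidth)
  by <- floor(S[, 2] / grid_binwidth)
  key <- paste(bx, by)
  agg <- function(v) tapply(v, key, mean)
  cnt <- tapply(key, key, length)
  out <- data.frame(
    bin_x = (as.numeric(tapply(bx, key, `[`, 1)) + 0.5) * grid_binwidth,
    bin_y = (as.numeric(tapply(by, key, `[`, 1)) + 0.5) * grid_binwidth,
    dx = as.numeric(agg(disp[, 1])), dy = as.numeric(agg(disp[, 2])),
    n_cells = as.integer(cnt))
  rownames(out) <- NULL
  out
}

#' K-means on an identity-gene panel (focused clustering)
#'
#' Clusters cells using only the identity-gene features (z-scored), so that
#' matched cell types can be recovered across conditions even when
#' state-program variance dominates the highly-variable-gene space.
#'
#' @param nm a [normalized_matrix()] or z-scored matrix.
#' @param gene_set identity genes to use (default: all columns).
#' @param k number of clusters.
#' @param seed integer seed (k-means is seeded; same seed, same labels).
#' @param n_init random starts.
#' @return Integer cluster labels.
#' @export
focused_kmeans <- function(nm, gene_set = NULL, k = 3, seed = 1, n_init = 10) {
  Z <- if (inherits(nm, "normalized_matrix")) nm$z else as.matrix(nm)
  if (!is.null(gene_set)) Z <- Z[, gene_set, drop = FALSE]
  if (k > nrow(Z)) stop("focused_kmeans: k exceeds the number of cells")
  set.seed(as.integer(seed))
  if (k == 1) return(rep(1L, nrow(Z)))
  stats::kmeans(Z, centers = k, nstart = n_init, iter.max = 100)$cluster
}
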