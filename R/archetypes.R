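# Archetypal analysis (principal convex hull) of identity-gene space:
# PCA embedding, PCHA triangle fitting, minimal enclosing triangle, t-ratio
# permutation test, and subsampling stability.

#' PCA on an identity-gene panel
#'
#' Standard PCA (centering, no re-scaling — the input layer is already
#' z-scored) restricted to a gene set. Loadings are orthonormal; each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making embeddings reproducible. The eigenvalue spectrum is returned for
#' spectral-gap inspection.
#'
#' @param nm a [normalized_matrix()] or a plain cells x genes matrix.
#' @param gene_set gene ids to use (default: all columns).
#' @param n_components number of components.
#' @return list: `scores` (cells x n_components), `loadings` (genes x
#'   n_components, orthonormal), `eig` (variances), `center`.
#' @export
pca_identity <- function(nm, gene_set = NULL, n_components = 10) {
  X <- if (inherits(nm, "normalized_matrix")) nm$z else as.matrix(nm)
  if (!is.null(gene_set)) {
    missing <- setdiff(gene_set, colnames(X))
    if (length(missing))
      stop("pca_identity: genes absent from matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    X <- X[, gene_set, drop = FALSE]
  }
  n_components <- min(n_components, ncol(X))
  if (nrow(X) < n_components)
    stop("pca_identity: fewer cells than requested components")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)],
                                n_components), 2, flip, "*")
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = loadings,
       eig = sv$d^2 / (nrow(X) - 1), center = ctr)
}

# Fast PC1-PC2 scores of a cells x genes matrix (centering only).
pc_scores_2d <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 2, nv = 0)
  sv$u %*% diag(sv$d[1:2], 2)
}

# FurthestSum initialization (greedy max-min distance seeds) for PCHA.
furthest_sum <- function(X, noc) {
  n <- ncol(X)
  nrm2 <- colSums(X^2)
  idx <- which.max(nrm2)
  sumdist <- rep(0, n)
  for (k in seq_len(noc - 1)) {
    d <- sqrt(pmax(nrm2 + nrm2[idx[k]] - 2 * crossprod(X[, idx[k]], X)[1, ], 0))
    sumdist <- sumdist + d
    sumdist[idx] <- -Inf
    idx <- c(idx, which.max(sumdist))
  }
  idx
}

# Project columns of a matrix onto the probability simplex (non-negative,
# column sums 1); zero columns become uniform.
simplex_renorm <- function(M) {
  M[M < 0] <- 0
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) { M[, zero] <- 1 / nrow(M); cs[zero] <- 1 }
  sweep(M, 2, cs, "/")
}

#' Principal convex hull (archetypal) analysis
#'
#' Fits `n_archetypes` archetypes by alternating constrained least squares
#' (PCHA): archetypes are convex combinations of data points (A = X C, C
#' column-stochastic) and each point is approximated by a convex combination
#' of archetypes (X ~ A S, S column-stochastic). Updates are projected
#' gradient steps with adaptive step sizes; convergence is declared when the
#' relative loss change drops below `tol`.
#'
#' @param points n x d data matrix (rows = cells, e.g. PC1-PC2 scores).
#' @param n_archetypes number of archetypes (noc; 3 fits a triangle).
#' @param delta archetype relaxation; only the hard-constraint `delta = 0`
#'   fit is supported.
#' @param max_iter,tol outer iteration cap and relative-loss tolerance.
#' @param seed optional seed (initialization is deterministic FurthestSum;
#'   the seed only matters for the random S start).
#' @return list of class `pcha_fit`: `archetypes` (n_archetypes x d), `S`,
#'   `C`, `sse`, `varexpl`, `converged`.
#' @export
fit_archetypes <- function(points, n_archetypes = 3, delta = 0,
                           max_iter = 1000, tol = 1e-6, seed = 1) {
  points <- as.matrix(points)
  if (nrow(points) < n_archetypes)
    stop("fit_archetypes: need at least n_archetypes points")
  if (delta != 0) stop("fit_archetypes: only delta = 0 is supported")
  X <- t(points)                      # d x n
  d <- nrow(X); n <- ncol(X); noc <- n_archetypes
  set.seed(as.integer(seed))
  C <- matrix(0, n, noc)
  C[cbind(furthest_sum(X, noc), seq_len(noc))] <- 1
  S <- simplex_renorm(matrix(stats::rexp(noc * n), noc, n))
  sst <- sum(sweep(X, 1, rowMeans(X))^2)
  if (sst == 0) stop("fit_archetypes: degenerate (constant) data")
  XC <- X %*% C
  sse <- sum((X - XC %*% S)^2)
  muS <- 1; muC <- 1
  sse_old <- Inf
  iter <- 0
  while (iter < max_iter && (sse_old - sse) / max(sse, 1e-300) > tol ||
         iter < 2) {
    iter <- iter + 1
    sse_old <- sse
    # --- S update
    AtA <- crossprod(XC)              # noc x noc
    AtX <- crossprod(XC, X)           # noc x n
    for (rep in 1:10) {
      g <- AtA %*% S - AtX
      g <- sweep(g, 2, colSums(g * S), "-")
      ok <- FALSE
      for (ls in 1:20) {
        S1 <- simplex_renorm(S - muS * g)
        sse1 <- sum((X - XC %*% S1)^2)
        if (sse1 <= sse * (1 + 1e-12)) {
          S <- S1; sse <- sse1; muS <- muS * 1.2; ok <- TRUE; break
        }
        muS <- muS / 2
      }
      if (!ok) break
    }
    # --- C update
    SSt <- tcrossprod(S)              # noc x noc
    XSt <- tcrossprod(X, S)           # d x noc
    XtXSt <- crossprod(X, XSt)        # n x noc
    for (rep in 1:10) {
      XC <- X %*% C
      g <- crossprod(X, XC %*% SSt) - XtXSt   # n x noc
      g <- sweep(g, 2, colSums(g * C), "-")
      ok <- FALSE
      for (ls in 1:20) {
        C1 <- simplex_renorm(C - muC * g)
        XC1 <- X %*% C1
        sse1 <- sum((X - XC1 %*% S)^2)
        if (sse1 <= sse * (1 + 1e-12)) {
          C <- C1; XC <- XC1; sse <- sse1; muC <- muC * 1.2; ok <- TRUE
          break
        }
        muC <- muC / 2
      }
      if (!ok) break
    }
  }
  arch <- t(XC)
  if (noc == 3 && d == 2) {
    area <- polygon_area(arch)
    span <- max(stats::dist(points))
    if (!is.finite(area) || area < 1e-10 * span^2)
      stop("fit_archetypes: degenerate fit (collinear data)")
  }
  structure(list(archetypes = arch, S = S, C = C, sse = sse,
                 varexpl = 1 - sse / sst,
                 converged = iter < max_iter),
            class = "pcha_fit")
}

# Support function of a point set: max over points of <n(theta), x>, for
# outward normal angles theta (vectorized over theta).
support_fun <- function(pts, theta) {
  N <- cbind(cos(theta), sin(theta))
  H <- pts %*% t(N)
  apply(H, 2, max)
}

# TRUE when the three outward normal angles positively span the plane
# (sorted angular gaps all < pi), i.e. the three tangent half-planes
# intersect in a bounded triangle.
normals_span <- function(th1, th2, th3, eps = 1e-9) {
  n <- max(length(th1), length(th2), length(th3))
  a1 <- rep(th1 %% (2 * pi), length.out = n)
  a2 <- rep(th2 %% (2 * pi), length.out = n)
  a3 <- rep(th3 %% (2 * pi), length.out = n)
  lo <- pmin(a1, a2, a3)
  hi <- pmax(a1, a2, a3)
  mid <- a1 + a2 + a3 - lo - hi
  g1 <- mid - lo; g2 <- hi - mid; g3 <- 2 * pi - hi + lo
  g1 < pi - eps & g2 < pi - eps & g3 < pi - eps
}

# Area of the triangle formed by three tangent lines with outward normal
# angles th (length-3) and support values h (length-3); NULL if the normals
# do not positively span the plane (unbounded/invalid).
tangent_triangle <- function(th, h) {
  if (!normals_span(th[1], th[2], th[3])) return(NULL)
  cs <- cos(th); sn <- sin(th)
  vx <- numeric(3); vy <- numeric(3)
  for (k in 1:3) {
    i <- k; j <- k %% 3 + 1
    det <- cs[i] * sn[j] - sn[i] * cs[j]
    if (abs(det) < 1e-12) return(NULL)
    vx[k] <- (h[i] * sn[j] - h[j] * sn[i]) / det
    vy[k] <- (h[j] * cs[i] - h[i] * cs[j]) / det
  }
  # vertices must satisfy all three half-plane constraints (bounded triangle)
  for (k in 1:3)
    if (any(cs[k] * vx + sn[k] * vy > h[k] + 1e-6 * (1 + abs(h[k]))))
      return(NULL)
  list(vertices = cbind(vx, vy), area = polygon_area(cbind(vx, vy)))
}

# Vectorized area over grids of (th2, th3) for fixed th1 (support values
# looked up from precomputed interpolants). Returns matrix of areas.
tangent_area_grid <- function(th1, h1, th2, h2, th3, h3) {
  c1 <- cos(th1); s1 <- sin(th1)
  c2 <- cos(th2); s2 <- sin(th2)
  c3 <- cos(th3); s3 <- sin(th3)
  i2 <- rep(seq_along(th2), times = length(th3))
  i3 <- rep(seq_along(th3), each = length(th2))
  a2 <- c2[i2]; b2 <- s2[i2]; q2 <- h2[i2]
  a3 <- c3[i3]; b3 <- s3[i3]; q3 <- h3[i3]
  d12 <- c1 * b2 - s1 * a2
  d23 <- a2 * b3 - b2 * a3
  d31 <- a3 * s1 - b3 * c1
  bad <- abs(d12) < 1e-9 | abs(d23) < 1e-9 | abs(d31) < 1e-9
  x12 <- (h1 * b2 - q2 * s1) / d12; y12 <- (q2 * c1 - h1 * a2) / d12
  x23 <- (q2 * b3 - q3 * b2) / d23; y23 <- (q3 * a2 - q2 * a3) / d23
  x31 <- (q3 * s1 - h1 * b3) / d31; y31 <- (h1 * a3 - q3 * c1) / d31
  area <- abs(x12 * (y23 - y31) + x23 * (y31 - y12) + x31 * (y12 - y23)) / 2
  # containment: each vertex inside the opposite half-plane
  ok <- (c1 * x23 + s1 * y23 <= h1 + 1e-9) &
    (a2 * x31 + b2 * y31 <= q2 + 1e-9) &
    (a3 * x12 + b3 * y12 <= q3 + 1e-9) &
    normals_span(th1, th2[i2], th3[i3])
  area[bad | !ok] <- Inf
  matrix(area, nrow = length(th2))
}

#' Minimal-area enclosing triangle of a planar point set
#'
#' Computes the convex hull, then searches over triangles formed by three
#' tangent lines of the hull: every minimal enclosing triangle has all sides
#' tangent and at least one side flush with a hull edge, so candidate flush
#' angles are seeded from the hull edge normals, the other two tangent
#' angles are grid-searched, and the best candidates are polished by
#' Nelder-Mead over all three angles. Exact flush-flush-flush triples (all
#' combinations of three edge normals) are also evaluated so that a hull
#' that is itself a triangle is recovered exactly.
#'
#' @param points n x 2 matrix.
#' @param grid_n grid resolution for the tangent-angle search.
#' @return list: `vertices` (3 x 2), `area`.
#' @export
min_enclosing_triangle <- function(points, grid_n = 60) {
  points <- as.matrix(points)
  hull <- points[grDevices::chull(points), , drop = FALSE]
  if (nrow(hull) < 3) stop("min_enclosing_triangle: degenerate point set")
  # chull returns clockwise order; reverse for counterclockwise
  hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  hn <- nrow(hull)
  e <- hull[c(2:hn, 1), ] - hull
  edge_theta <- atan2(-e[, 1], e[, 2])  # outward normal angle (ccw polygon)
  area_of <- function(th) {
    th <- th %% (2 * pi)
    tri <- tangent_triangle(th, support_fun(hull, th))
    if (is.null(tri)) Inf else tri$area
  }
  best <- list(area = Inf, th = NULL)
  consider <- function(th) {
    a <- area_of(th)
    if (a < best$area) best <<- list(area = a, th = th)
  }
  # flush-flush-flush candidates (exact when the hull is a triangle)
  if (hn <= 24) {
    cmb <- utils::combn(seq_len(hn), 3)
    for (c_i in seq_len(ncol(cmb))) consider(edge_theta[cmb[, c_i]])
  }
  # one flush side + grid over the other two tangent angles
  gg <- seq(0.05, 2 * pi - 0.05, length.out = grid_n)
  for (t1 in edge_theta) {
    th2 <- t1 + gg
    h1 <- support_fun(hull, t1)
    h2 <- support_fun(hull, th2)
    A <- tangent_area_grid(t1, h1, th2, h2, th2, h2)
    j <- arrayInd(which.min(A), dim(A))
    if (is.finite(A[j])) consider(c(t1, th2[j[1]], th2[j[2]]))
  }
  if (!is.finite(best$area))
    stop("min_enclosing_triangle: search failed")
  # polish with Nelder-Mead over the three tangent angles
  opt <- stats::optim(best$th, area_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (is.finite(opt$value) && opt$value < best$area)
    best <- list(area = opt$value, th = opt$par)
  tri <- tangent_triangle(best$th %% (2 * pi), support_fun(hull, best$th))
  list(vertices = unname(tri$vertices), area = tri$area)
}

#' t-ratio: convex hull area over enclosing-triangle area
#'
#' The ratio of the area of the data's convex hull to that of its bounding
#' triangle. With the minimal-area enclosing triangle (the default), the
#' ratio lies in (0, 1] and equals 1 exactly when the hull is itself a
#' triangle; values near 1 indicate genuinely triangular data.
#'
#' @param points n x 2 matrix (n >= 3, not all collinear).
#' @param triangle optional 3 x 2 triangle vertices; defaults to
#'   [min_enclosing_triangle()] of the points.
#' @return Scalar t-ratio.
#' @export
t_ratio <- function(points, triangle = NULL) {
  points <- as.matrix(points)
  hull <- points[grDevices::chull(points), , drop = FALSE]
  if (nrow(hull) < 3) stop("t_ratio: fewer than 3 hull points")
  hull_area <- polygon_area(hull)
  if (hull_area <= 0) stop("t_ratio: collinear points (zero-area hull)")
  tri_area <- if (is.null(triangle)) {
    min_enclosing_triangle(points)$area
  } else {
    polygon_area(as.matrix(triangle))
  }
  if (tri_area <= 0) stop("t_ratio: zero-area triangle")
  hull_area / tri_area
}

#' Permutation test for triangular structure (t-ratio test)
#'
#' Computes the observed t-ratio on PC1-PC2 of the matrix, then builds a null
#' by permuting each gene's values independently across all cells — which
#' preserves marginal gene distributions while destroying gene-gene
#' correlations — refitting the PCA for every shuffle. The p-value uses the
#' add-one estimator p = (1 + #\{null >= observed\}) / (1 + n_shuffles), so
#' the smallest attainable p is 1/(1 + n_shuffles). PCHA supplies the
#' reported archetype coordinates; the minimal enclosing triangle drives the
#' t-ratio and p-value.
#'
#' @param X cells x genes matrix (typically the z-scored layer), or a
#'   [normalized_matrix()].
#' @param gene_set optional gene subset.
#' @param n_shuffles number of per-gene permutations (>= 1).
#' @param seed integer seed.
#' @return list of class `triangle_fit`: `archetypes` (PCHA, 3 x 2),
#'   `enclosing_triangle`, `t_ratio`, `null_t_ratios`, `p_value`,
#'   `n_shuffles`, `scores` (PC1-PC2).
#' @export
t_ratio_test <- function(X, gene_set = NULL, n_shuffles = 1000, seed = 1) {
  if (inherits(X, "normalized_matrix")) X <- X$z
  X <- as.matrix(X)
  if (!is.null(gene_set)) X <- X[, gene_set, drop = FALSE]
  if (n_shuffles < 1) stop("t_ratio_test: n_shuffles must be >= 1")
  scores <- pc_scores_2d(X)
  tri <- min_enclosing_triangle(scores)
  obs <- t_ratio(scores, tri$vertices)
  arch <- fit_archetypes(scores, 3, seed = seed)
  set.seed(as.integer(seed))
  null_t <- vapply(seq_len(n_shuffles), function(b) {
    Xs <- apply(X, 2, sample)
    sc <- pc_scores_2d(Xs)
    t_ratio(sc)
  }, numeric(1))
  p <- (1 + sum(null_t >= obs)) / (1 + n_shuffles)
  structure(list(archetypes = arch$archetypes,
                 enclosing_triangle = tri$vertices,
                 t_ratio = obs, null_t_ratios = null_t, p_value = p,
                 n_shuffles = n_shuffles, scores = scores),
            class = "triangle_fit")
}

#' @export
print.triangle_fit <- function(x, ...) {
  cat(sprintf("triangle_fit: t-ratio %.4f, p = %.4g (%d shuffles)\n",
              x$t_ratio, x$p_value, x$n_shuffles))
  invisible(x)
}

# Match archetype rows of `a` to rows of `ref` minimizing total displacement
# over the 6 permutations of 3 labels. Returns the permuted `a` and the
# per-archetype distances.
match_archetypes <- function(a, ref) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  best <- NULL; best_tot <- Inf
  for (p in perms) {
    d <- sqrt(rowSums((a[p, , drop = FALSE] - ref)^2))
    if (sum(d) < best_tot) { best_tot <- sum(d); best <- list(a = a[p, ], d = d) }
  }
  best
}

#' Stability of the archetype triangle under subsampling
#'
#' Refits the archetypes on random subsamples of cells (or genes) and reports
#' each trial's archetype displacement as a fraction of the full fit's
#' minimum inter-archetype distance, after matching archetypes over the six
#' label permutations. For cell subsampling the full-data PCA basis is
#' reused; for gene subsampling the PCA is refit on the gene subset (with the
#' deterministic sign convention), since the full loadings do not exist
#' there.
#'
#' @param X cells x genes matrix (z-scored layer) or [normalized_matrix()].
#' @param gene_set optional gene subset.
#' @param subsample_fraction fraction of cells (or genes) per trial.
#' @param n_trials number of trials.
#' @param over subsample `"cells"` or `"genes"`.
#' @param seed integer seed.
#' @return list: `displacement` (per trial, fraction of the minimum
#'   inter-archetype distance), `archetypes` (full fit), `trials` (list of
#'   matched archetype matrices).
#' @export
archetype_stability <- function(X, gene_set = NULL, subsample_fraction = 0.8,
                                n_trials = 10, over = c("cells", "genes"),
                                seed = 1) {
  if (inherits(X, "normalized_matrix")) X <- X$z
  X <- as.matrix(X)
  if (!is.null(gene_set)) X <- X[, gene_set, drop = FALSE]
  over <- match.arg(over)
  full_pca <- pca_identity(X, n_components = 2)
  full_fit <- fit_archetypes(full_pca$scores, 3, seed = seed)
  ref <- full_fit$archetypes
  min_dist <- min(stats::dist(ref))
  set.seed(as.integer(seed))
  trials <- vector("list", n_trials)
  disp <- rep(NA_real_, n_trials)
  for (b in seq_len(n_trials)) {
    res <- tryCatch({
      if (over == "cells") {
        idx <- sample(nrow(X), max(4, round(subsample_fraction * nrow(X))))
        sc <- sweep(X[idx, , drop = FALSE], 2, full_pca$center) %*%
          full_pca$loadings
        fit <- fit_archetypes(sc, 3, seed = seed + b)
      } else {
        idx <- sample(ncol(X), max(2, round(subsample_fraction * ncol(X))))
        pca <- pca_identity(X[, idx, drop = FALSE], n_components = 2)
        fit <- fit_archetypes(pca$scores, 3, seed = seed + b)
      }
      match_archetypes(fit$archetypes, ref)
    }, error = function(e) {
      warning("archetype_stability: trial ", b, " skipped: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      trials[[b]] <- res$a
      disp[b] <- mean(res$d) / min_dist
    }
  }
  list(displacement = disp, archetypes = ref, trials = trials,
       min_interarchetype_dist = min_dist)
}
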