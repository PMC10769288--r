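# Diffusion pseudotime of cells and expression-weighted pseudotime of genes.

#' Diffusion pseudotime of cells
#'
#' Builds a kNN graph in the top-`n_pcs` PC space of the (z-scored)
#' identity-gene matrix, forms a locally-scaled Gaussian kernel with
#' anisotropic (density-corrected) normalization, eigendecomposes the
#' diffusion operator, and computes the diffusion pseudotime of each cell as
#' its diffusion distance to the root cell, using the standard
#' sum_l (lambda_l / (1 - lambda_l))^2 (phi_l(x) - phi_l(root))^2 form over
#' the non-trivial eigenpairs. The root is the cell with the smallest PC1;
#' pseudotime is min-max rescaled to \[0, 1\] (root at 0). If the graph is
#' disconnected, the largest component is used and the rest get NA with a
#' flag.
#'
#' @param nm a [normalized_matrix()] or z-scored matrix.
#' @param gene_set optional gene subset (e.g. type-identity genes).
#' @param n_pcs number of PCs (capped at the data rank).
#' @param k neighbours for the graph (>= k + 1 cells required).
#' @param n_dcs diffusion components used for the DPT distance.
#' @return list of class `pseudotime_result`: `tc` (per-cell pseudotime in
#'   \[0, 1\], NA off the main component), `root_cell_id`, `in_main_component`,
#'   `eigenvalues`.
#' @export
cell_pseudotime <- function(nm, gene_set = NULL, n_pcs = 50, k = 50,
                            n_dcs = 15) {
  Z <- if (inherits(nm, "normalized_matrix")) nm$z else as.matrix(nm)
  if (!is.null(gene_set)) Z <- Z[, gene_set, drop = FALSE]
  n <- nrow(Z)
  if (n < k + 1) stop("cell_pseudotime: need at least k + 1 cells")
  n_pcs <- min(n_pcs, ncol(Z), n - 1)
  emb <- pca_identity(Z, n_components = n_pcs)$scores
  root <- which.min(emb[, 1])

  nnd <- knn_dist(emb, emb, k + 1)
  idx <- nnd$nn.index[, -1, drop = FALSE]
  dst <- nnd$nn.dist[, -1, drop = FALSE]
  sigma <- pmax(dst[, ncol(dst)] / 2, .Machine$double.eps)
  i <- rep(seq_len(n), times = k)
  j <- as.vector(idx)
  w <- exp(-as.vector(dst)^2 / (sigma[i] * sigma[j]))
  K <- matrix(0, n, n)
  K[cbind(i, j)] <- w
  K <- pmax(K, t(K))  # symmetrize (union of directed kNN edges)

  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    Matrix::Matrix(K > 0, sparse = TRUE), mode = "undirected"))
  main <- which.max(comp$csize)
  in_main <- comp$membership == main
  if (!in_main[root]) root <- which(in_main)[which.min(emb[in_main, 1])]

  Km <- as.matrix(K[in_main, in_main])
  # anisotropic normalization (alpha = 1) removes density effects
  q <- rowSums(Km)
  Km <- Km / outer(q, q)
  d <- rowSums(Km)
  A <- Km / outer(sqrt(d), sqrt(d))
  eg <- eigen(A, symmetric = TRUE)
  m <- min(n_dcs, ncol(eg$vectors) - 1)
  lam <- eg$values[2:(m + 1)]
  lam <- pmin(lam, 1 - 1e-10)
  phi <- eg$vectors[, 2:(m + 1), drop = FALSE] / sqrt(d)
  root_m <- match(root, which(in_main))
  wgt <- lam / (1 - lam)
  dpt <- sqrt(colSums((wgt * t(phi - matrix(phi[root_m, ], nrow(phi),
                                            ncol(phi), byrow = TRUE)))^2))
  tc <- rep(NA_real_, n)
  tc[in_main] <- (dpt - min(dpt)) / (max(dpt) - min(dpt))
  structure(list(tc = stats::setNames(tc, rownames(Z)),
                 root_cell_id = rownames(Z)[root],
                 in_main_component = in_main,
                 eigenvalues = eg$values[seq_len(m + 1)]),
            class = "pseudotime_result")
}

#' Expression-weighted pseudotime of genes
#'
#' The pseudotime of a gene is the weighted average of cell pseudotime,
#' T_g = sum_c w_gc t_c with weights w_gc = x_gc / sum_c' x_gc' proportional
#' to the gene's (non-negative, size- and log-normalized) expression, summing
#' to 1 per gene. Gene pseudotimes computed on a reference condition can be
#' held fixed to give a consistent gene ordering across comparisons.
#'
#' @param expr_nonneg cells x genes matrix with non-negative entries (the
#'   `lognorm` layer, not z-scores).
#' @param tc per-cell pseudotime (length = cells; NA cells are dropped from
#'   the weights).
#' @return Named numeric vector T_g; genes with all-zero expression get NA
#'   (attribute `undefined_genes` lists them).
#' @export
gene_pseudotime <- function(expr_nonneg, tc) {
  X <- as.matrix(expr_nonneg)
  if (any(X < 0)) stop("gene_pseudotime: expression must be non-negative")
  stopifnot(length(tc) == nrow(X))
  ok <- !is.na(tc)
  X <- X[ok, , drop = FALSE]
  tot <- colSums(X)
  tg <- as.vector(crossprod(X, tc[ok])) / tot
  tg[tot == 0] <- NA_real_
  names(tg) <- colnames(X)
  if (any(tot == 0))
    attr(tg, "undefined_genes") <- colnames(X)[tot == 0]
  tg
}
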