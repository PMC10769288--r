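# Hybrid spatial + expression graph clustering and kNN label transfer.

# Shared-nearest-neighbour (Jaccard) weighted kNN graph on the rows of X.
# Neighbourhoods include the cell itself; edges exist where either endpoint
# is in the other's kNN list; weight = |N(i) & N(j)| / |N(i) | N(j)|.
snn_graph <- function(X, k) {
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- knn_index(X, X, k + 1)  # includes self as first neighbour
  N <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(N)                 # |N(i) & N(j)|
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1) - jac@x)          # Jaccard
  adj <- (N + Matrix::t(N)) > 0                   # kNN union edge set
  w <- jac * adj
  Matrix::diag(w) <- 0
  Matrix::drop0(w)
}

#' Build a hybrid spatial + expression cell graph
#'
#' Builds shared-neighbour-weighted kNN graphs in expression space and in
#' physical space and blends them edge-wise on the union of their edge sets:
#' w_hybrid = blend_weight * w_expr + (1 - blend_weight) * w_spatial.
#' `blend_weight = 0.5` gives equal weighting; 1 returns the expression graph
#' exactly and 0 the spatial graph.
#'
#' @param expr_embedding cells x D matrix (e.g. top PCs).
#' @param coords cells x 2 spatial coordinates (same cell order).
#' @param k neighbours per cell (k < n).
#' @param blend_weight real in \[0, 1\].
#' @return A `hybrid_graph` list: `adjacency` (symmetric sparse, no
#'   self-loops), `k`, `blend_weight`.
#' @export
build_hybrid_graph <- function(expr_embedding, coords, k = 15,
                               blend_weight = 0.5) {
  stopifnot(nrow(expr_embedding) == nrow(coords),
            blend_weight >= 0, blend_weight <= 1)
  ge <- snn_graph(as.matrix(expr_embedding), k)
  gs <- snn_graph(as.matrix(coords), k)
  adj <- blend_weight * ge + (1 - blend_weight) * gs
  structure(list(adjacency = Matrix::drop0(adj), k = k,
                 blend_weight = blend_weight),
            class = "hybrid_graph")
}

#' Leiden community detection on a hybrid graph
#'
#' @param g a [build_hybrid_graph()] result (or any symmetric sparse
#'   adjacency in `g$adjacency`).
#' @param resolution Leiden resolution parameter (modularity objective).
#' @param seed integer seed (mandatory; Leiden refinement is stochastic).
#' @param n_iterations Leiden iterations.
#' @return Integer vector of community labels, one per cell.
#' @export
cluster_domains <- function(g, resolution = 1, seed, n_iterations = 5) {
  if (missing(seed)) stop("cluster_domains: a seed is required")
  adj <- if (inherits(g, "hybrid_graph")) g$adjacency else g
  if (nrow(adj) == 0) stop("cluster_domains: empty graph")
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  as.integer(igraph::membership(cl))
}

#' Transfer labels from a reference to query cells by kNN vote
#'
#' Each query cell takes the modal label of its `k` nearest reference cells
#' in the shared embedding (ties broken by the nearest neighbour's label).
#' A query abstains (label NA) when at most `min_ref_neighbors` of its `k`
#' nearest neighbours *in the joint reference + query pool* are reference
#' cells — the signature of a failed integration for that cell.
#'
#' @param ref_embedding,query_embedding matrices in a shared space.
#' @param ref_labels per-reference-cell labels.
#' @param k neighbours for the vote (100 for class-level, 30 for
#'   subclass-level assignment).
#' @param min_ref_neighbors abstain when <= this many reference cells are
#'   among the k joint-pool neighbours.
#' @return Character labels per query cell, NA for abstentions.
#' @export
transfer_labels <- function(ref_embedding, ref_labels, query_embedding,
                            k = 100, min_ref_neighbors = 2) {
  ref_embedding <- as.matrix(ref_embedding)
  query_embedding <- as.matrix(query_embedding)
  nr <- nrow(ref_embedding)
  if (nr == 0) stop("transfer_labels: empty reference")
  stopifnot(length(ref_labels) == nr)
  k_ref <- min(k, nr)
  nn_ref <- knn_index(ref_embedding, query_embedding, k_ref)
  joint <- rbind(ref_embedding, query_embedding)
  k_joint <- min(k + 1, nrow(joint))
  nn_joint <- knn_index(joint, query_embedding, k_joint)
  labels <- character(nrow(query_embedding))
  ref_labels <- as.character(ref_labels)
  for (i in seq_len(nrow(query_embedding))) {
    self_id <- nr + i
    pool <- setdiff(nn_joint[i, ], self_id)[seq_len(min(k, k_joint - 1))]
    if (sum(pool <= nr) <= min_ref_neighbors) {
      labels[i] <- NA_character_
      next
    }
    votes <- ref_labels[nn_ref[i, ]]
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    labels[i] <- if (length(top) == 1) top else votes[votes %in% top][1]
  }
  labels
}
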