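# Continuum-vs-discrete shuffling test: permuting each gene within each
# labelled group preserves per-(gene, type) value multisets exactly while
# destroying within-type gene-gene correlations. A genuine continuum then
# fractures into discrete clusters; already-discrete types are unaffected.

#' Shuffle each gene independently within each label group
#'
#' @param X cells x genes matrix (any expression layer) or a
#'   [normalized_matrix()] (its `z` layer is shuffled and returned as a
#'   matrix).
#' @param labels per-cell group labels (every cell labelled).
#' @param seed integer seed.
#' @return A matrix of the same shape and dimnames.
#' @export
shuffle_within_types <- function(X, labels, seed = 1) {
  if (inherits(X, "normalized_matrix")) X <- X$z
  X <- as.matrix(X)
  stopifnot(length(labels) == nrow(X), !anyNA(labels))
  set.seed(as.integer(seed))
  out <- X
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1)
      out[idx, ] <- apply(X[idx, , drop = FALSE], 2, sample)
  }
  out
}

# Mean silhouette width of K-means labels in an embedding.
mean_silhouette <- function(emb, cl) {
  mean(cluster::silhouette(cl, stats::dist(emb))[, "sil_width"])
}

# K-means over a k range in PC space, selecting k by max mean silhouette.
silhouette_kmeans <- function(X, k_range, n_pcs = 10, seed = 1,
                              nstart = 10) {
  emb <- pca_identity(X, n_components = min(n_pcs, ncol(X), nrow(X) - 1))$scores
  set.seed(as.integer(seed))
  sil <- vapply(k_range, function(k) {
    cl <- stats::kmeans(emb, centers = k, nstart = nstart,
                        iter.max = 100)$cluster
    mean_silhouette(emb, cl)
  }, numeric(1))
  list(k = k_range[which.max(sil)], silhouette = max(sil),
       per_k = data.frame(k = k_range, silhouette = sil))
}

#' Continuum versus discrete-types verdict by within-type shuffling
#'
#' Clusters both the original matrix and its within-type-shuffled version
#' with K-means over `k_range` (k selected by maximum mean silhouette in PC
#' space). If the labels cover a genuine continuum, shuffling breaks the
#' within-group gene correlations and crystallizes the groups into discrete
#' clusters: the silhouette rises by more than `margin` and the selected k
#' matches the number of label groups — verdict `"continuum"`. If the types
#' are already discrete, shuffling changes nothing within the margin —
#' verdict `"discrete"`. Anything else is `"ambiguous"`.
#'
#' @param X cells x genes matrix (z-scored layer) or [normalized_matrix()].
#' @param labels per-cell group labels (>= 2 groups).
#' @param k_range candidate cluster numbers (within \[2, n - 1\]).
#' @param seed integer seed.
#' @param margin silhouette-increase margin for the continuum call.
#' @param n_pcs PCs used for clustering and silhouettes.
#' @return list of class `continuum_verdict`: `verdict`, `original`,
#'   `shuffled` (each with `k`, `silhouette`, `per_k`), `silhouette_change`,
#'   `n_groups`, `margin`.
#' @export
continuum_vs_discrete_test <- function(X, labels, k_range = 2:6, seed = 1,
                                       margin = 0.05, n_pcs = 10) {
  if (inherits(X, "normalized_matrix")) X <- X$z
  X <- as.matrix(X)
  groups <- unique(labels)
  if (length(groups) < 2)
    stop("continuum_vs_discrete_test: labels must define >= 2 groups")
  if (min(k_range) < 2 || max(k_range) > nrow(X) - 1)
    stop("continuum_vs_discrete_test: k_range outside [2, n - 1]")
  orig <- silhouette_kmeans(X, k_range, n_pcs, seed)
  Xs <- shuffle_within_types(X, labels, seed)
  shuf <- silhouette_kmeans(Xs, k_range, n_pcs, seed)
  k_sel <- shuf$k
  delta <- shuf$per_k$silhouette[shuf$per_k$k == k_sel] -
    orig$per_k$silhouette[orig$per_k$k == k_sel]
  verdict <- if (delta > margin && k_sel == length(groups)) {
    "continuum"
  } else if (abs(delta) <= margin) {
    "discrete"
  } else {
    "ambiguous"
  }
  structure(list(verdict = verdict, original = orig, shuffled = shuf,
                 silhouette_change = delta, n_groups = length(groups),
                 margin = margin),
            class = "continuum_verdict")
}

#' @export
print.continuum_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (k_orig = %d sil %.3f; k_shuf = %d sil %.3f; delta %.3f)\n",
              x$verdict, x$original$k, x$original$silhouette,
              x$shuffled$k, x$shuffled$silhouette, x$silhouette_change))
  invisible(x)
}
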