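#' Simulate a 1-D transcriptomic continuum
#'
#' Cells and genes carry latent normalized rankings p_i = i/Nc and p_j = j/Ng
#' (1-based ranks, values in (0, 1]). The expected expression of gene j in
#' cell i is a Gaussian ridge along the diagonal,
#' lambda_ij = exp(-((p_i - p_j)/epsilon)^2), and counts are drawn from a
#' scaled Poisson, c_ij = scale * Poisson(lambda_ij), i.e. counts are integer
#' multiples of `scale`.
#'
#' @param n_cells,n_genes number of cells (Nc >= 2) and genes (Ng >= 2).
#' @param epsilon positive kernel width; small epsilon gives a sharp continuum.
#' @param scale positive Poisson scale s.
#' @param seed integer RNG seed.
#' @return A list with `matrix` (a [count_matrix()]) and `truth`, a list with
#'   `cell_ranking`, `gene_ranking`, `expected_rates` (lambda, in \[0, 1\]),
#'   `type_labels = NULL` and `planted_effects`.
#' @export
simulate_continuum <- function(n_cells = 600, n_genes = 60, epsilon = 0.2,
                               scale = 100, seed = 1) {
  if (n_cells < 2 || n_genes < 2) stop("n_cells and n_genes must be >= 2")
  if (epsilon <= 0 || scale <= 0) stop("epsilon and scale must be positive")
  set.seed(as.integer(seed))
  p_cell <- seq_len(n_cells) / n_cells
  p_gene <- seq_len(n_genes) / n_genes
  lambda <- exp(-(outer(p_cell, p_gene, "-") / epsilon)^2)
  counts <- matrix(scale * stats::rpois(length(lambda), lambda),
                   nrow = n_cells,
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                                   sprintf("gene%03d", seq_len(n_genes))))
  truth <- list(cell_ranking = p_cell, gene_ranking = p_gene,
                expected_rates = lambda, type_labels = NULL,
                planted_effects = list(epsilon = epsilon, scale = scale))
  list(matrix = count_matrix(counts), truth = truth)
}

#' Simulate discrete cell types with leaky marker expression
#'
#' Each type has its own marker genes: lambda_ij = 1 when cell i's type equals
#' gene j's type, else `epsilon` (leaky expression). To impose an order among
#' types, the first `shared_markers` markers of each type are additionally
#' expressed (lambda = 1) in the next type; the last type shares forward with
#' none. Counts are scale * Poisson(lambda).
#'
#' @param n_types integer >= 2.
#' @param markers_per_type,cells_per_type positive integers.
#' @param shared_markers integer in \[0, markers_per_type\].
#' @param epsilon leaky-expression level in \[0, 1\].
#' @param scale positive Poisson scale.
#' @param seed integer RNG seed.
#' @return A list with `matrix` (a [count_matrix()]; `cell_meta$type` holds the
#'   planted labels) and `truth` (`type_labels`, per-gene `gene_type`,
#'   `expected_rates`, `planted_effects`).
#' @export
simulate_discrete_types <- function(n_types = 3, markers_per_type = 20,
                                    cells_per_type = 200, shared_markers = 6,
                                    epsilon = 0.1, scale = 100, seed = 1) {
  if (n_types < 2) stop("n_types must be >= 2")
  if (markers_per_type < 1 || cells_per_type < 1)
    stop("markers_per_type and cells_per_type must be positive")
  if (shared_markers < 0 || shared_markers > markers_per_type)
    stop("shared_markers must be in [0, markers_per_type]")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (scale <= 0) stop("scale must be positive")
  set.seed(as.integer(seed))
  type_names <- LETTERS[seq_len(n_types)]
  cell_type <- rep(type_names, each = cells_per_type)
  gene_type <- rep(type_names, each = markers_per_type)
  lambda <- matrix(epsilon, nrow = length(cell_type), ncol = length(gene_type))
  for (t in seq_len(n_types)) {
    own <- which(gene_type == type_names[t])
    lambda[cell_type == type_names[t], own] <- 1
    if (shared_markers > 0 && t < n_types) {
      shared <- own[seq_len(shared_markers)]
      lambda[cell_type == type_names[t + 1], shared] <- 1
    }
  }
  counts <- matrix(scale * stats::rpois(length(lambda), lambda),
                   nrow = nrow(lambda),
                   dimnames = list(sprintf("cell%04d", seq_len(nrow(lambda))),
                                   sprintf("%s_mk%02d", gene_type,
                                           sequence(rep(markers_per_type, n_types)))))
  meta <- data.frame(cell_id = rownames(counts), type = cell_type,
                     stringsAsFactors = FALSE)
  truth <- list(cell_ranking = NULL, gene_ranking = NULL,
                type_labels = cell_type, gene_type = gene_type,
                expected_rates = lambda,
                planted_effects = list(epsilon = epsilon, scale = scale,
                                       shared_markers = shared_markers))
  list(matrix = count_matrix(counts, meta), truth = truth)
}

#' Simulate cells as convex mixtures of three archetypal profiles
#'
#' Draws per-cell mixture weights from a uniform Dirichlet over the 2-simplex,
#' forms expected rates scale * (W A) from three archetype expression profiles
#' over the genes, and adds Poisson noise. In PC1-PC2 such data fill a
#' triangle whose vertices are the archetypes; it is the positive control for
#' the t-ratio permutation test.
#'
#' @param n_cells,n_genes dimensions (genes are split into three archetype
#'   blocks).
#' @param scale positive Poisson scale for the archetype-high expression level.
#' @param background low expression level (fraction of `scale`) outside each
#'   archetype's gene block.
#' @param seed integer RNG seed.
#' @return A list with `matrix` (a [count_matrix()]) and `truth` (`weights`:
#'   cells x 3 Dirichlet weights, `archetype_profiles`: 3 x genes).
#' @export
simulate_archetype_mixture <- function(n_cells = 600, n_genes = 60,
                                       scale = 100, background = 0.05,
                                       seed = 1) {
  if (n_cells < 3 || n_genes < 3) stop("need at least 3 cells and 3 genes")
  set.seed(as.integer(seed))
  block <- cut(seq_len(n_genes), 3, labels = FALSE)
  profiles <- matrix(background, nrow = 3, ncol = n_genes)
  for (k in 1:3) profiles[k, block == k] <- 1
  w <- matrix(stats::rgamma(n_cells * 3, shape = 1), ncol = 3)
  w <- w / rowSums(w)
  lambda <- scale * (w %*% profiles)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = n_cells,
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                                   sprintf("gene%03d", seq_len(n_genes))))
  truth <- list(weights = w, archetype_profiles = profiles,
                planted_effects = list(scale = scale, background = background))
  list(matrix = count_matrix(counts), truth = truth)
}
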