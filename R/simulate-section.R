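#' Specification for the synthetic cortical section emulator
#'
#' Collects the planted structure of the synthetic MERFISH-like section: a
#' quartic pial curve, per-subclass cell numbers and laminar depth ranges,
#' overlapping Gaussian depth gradients for the A/B/C identity-gene sets, a
#' tangential V1 marker interval, per-sample batch factors, and a planted IEG
#' log2 fold-change under dark rearing. Coordinates are in microns with depth
#' (y) increasing away from the pia.
#'
#' @param pial_curve_coeffs polynomial coefficients (c0..c4) of the pial curve
#'   y = f(x).
#' @param x_domain tangential extent of the section in x (microns).
#' @param n_cells_per_subclass named integer vector, cells per subclass per
#'   sample. `VLMC` are pial anchor cells.
#' @param layer_depth_ranges named list, subclass -> c(depth_min, depth_max).
#' @param abc_gradient_centers depths (microns) of the A/B/C identity-gene
#'   density peaks, strictly increasing (upper < middle < lower).
#' @param abc_gradient_width Gaussian width (microns) of the identity profiles.
#' @param v1_interval c(tm, tl), V1 extent in tangential (arc-length) microns.
#' @param ieg_logfc_dr planted IEG log2 fold-change in DR samples.
#' @param samples data.frame with columns `sample`, `condition` ("NR"/"DR").
#' @param anchor_jitter_sd SD (microns) of anchor-cell displacement off the
#'   pial curve.
#' @param batch_sdlog SD of per-sample log-normal efficiency factors.
#' @param genes_per_identity_set identity genes per archetype set.
#' @param n_iegs,n_filler IEG and background gene counts.
#' @param seed integer RNG seed.
#' @return A validated list of class `section_spec`.
#' @export
spatial_section_spec <- function(
    pial_curve_coeffs = c(150, -0.12, 6e-5, -8e-9, 4e-13),
    x_domain = c(0, 4000),
    n_cells_per_subclass = c(VLMC = 120, L23 = 450, L4 = 150, L5 = 150, L6 = 150),
    layer_depth_ranges = list(L23 = c(100, 350), L4 = c(350, 500),
                              L5 = c(500, 700), L6 = c(700, 900)),
    abc_gradient_centers = c(150, 225, 300),
    abc_gradient_width = 60,
    v1_interval = c(1000, 3000),
    ieg_logfc_dr = 2,
    samples = data.frame(sample = c("NR1", "NR2", "DR1", "DR2"),
                         condition = c("NR", "NR", "DR", "DR")),
    anchor_jitter_sd = 4,
    batch_sdlog = 0.05,
    genes_per_identity_set = 10,
    n_iegs = 8,
    n_filler = 10,
    seed = 1) {
  spec <- list(pial_curve_coeffs = pial_curve_coeffs, x_domain = x_domain,
               n_cells_per_subclass = n_cells_per_subclass,
               layer_depth_ranges = layer_depth_ranges,
               abc_gradient_centers = abc_gradient_centers,
               abc_gradient_width = abc_gradient_width,
               v1_interval = v1_interval, ieg_logfc_dr = ieg_logfc_dr,
               samples = samples, anchor_jitter_sd = anchor_jitter_sd,
               batch_sdlog = batch_sdlog,
               genes_per_identity_set = genes_per_identity_set,
               n_iegs = n_iegs, n_filler = n_filler, seed = seed)
  if (length(pial_curve_coeffs) > 5)
    stop("pial curve degree must be <= 4")
  if (is.unsorted(abc_gradient_centers, strictly = TRUE))
    stop("abc_gradient_centers must be strictly increasing with depth")
  if (diff(v1_interval) <= 0) stop("v1_interval must have positive width")
  if (nrow(samples) < 1) stop("sample list must be non-empty")
  if (!all(c("sample", "condition") %in% names(samples)) ||
      any(is.na(samples$condition)))
    stop("every sample needs a condition")
  class(spec) <- "section_spec"
  spec
}

#' Gene sets planted by the cortical section emulator
#'
#' @param spec a [spatial_section_spec()].
#' @return Named list of gene-id vectors: `identity_A/B/C`, `iegs`,
#'   `subclass_markers`, `v1_on`, `v1_off`, `anchor`, `filler`.
#' @export
section_gene_sets <- function(spec) {
  gi <- seq_len(spec$genes_per_identity_set)
  list(identity_A = sprintf("idA%02d", gi),
       identity_B = sprintf("idB%02d", gi),
       identity_C = sprintf("idC%02d", gi),
       iegs = c("Fos", "Junb", "Egr4", "Nr4a2", "Arc", "Egr1", "Npas4",
                "Fosb")[seq_len(spec$n_iegs)],
       subclass_markers = c(L23 = "Cux2", L4 = "Rorb", L5 = "Fezf2",
                            L6 = "Foxp2"),
       v1_on = "Scnn1a", v1_off = "Igfbp4", anchor = "Slc6a13",
       filler = sprintf("bg%02d", seq_len(spec$n_filler)))
}

#' Simulate a curved cortical section with MERFISH-like counts
#'
#' Emits cells placed under the planted pial curve: anchor (VLMC-like) cells
#' on the curve with small jitter; laminar subclasses in their depth ranges;
#' A/B/C identity genes following overlapping Gaussian depth profiles; a V1
#' enrichment/depletion marker pair along the tangential axis; a planted IEG
#' upshift in DR samples; per-sample batch factors; and per-cell volumes and
#' blank counts (including planted QC failures) so the QC thresholds are
#' exercised. Expected counts scale with cell volume.
#'
#' @param spec a [spatial_section_spec()].
#' @return A list with `matrix` (a [count_matrix()]; `cell_meta` has
#'   `cell_id, x_um, y_um, volume, blanks, sample, condition, subclass`),
#'   `cells` (the same metadata with `anchor_flag`, a SpatialCellTable), and
#'   `truth` (per-cell latent `depth_um`, `tangent_um`, `type_labels`, and
#'   `planted_effects` with the curve, IEG effect, V1 interval, gradient
#'   centers and batch factors).
#' @export
simulate_cortical_section <- function(spec = spatial_section_spec()) {
  stopifnot(inherits(spec, "section_spec"))
  set.seed(as.integer(spec$seed))
  gs <- section_gene_sets(spec)
  genes <- c(gs$anchor, unname(gs$subclass_markers), gs$v1_on, gs$v1_off,
             gs$identity_A, gs$identity_B, gs$identity_C, gs$iegs, gs$filler)
  arc <- arc_length_fun(spec$pial_curve_coeffs, spec$x_domain)
  batch <- stats::rlnorm(nrow(spec$samples), 0, spec$batch_sdlog)
  names(batch) <- spec$samples$sample

  one_sample <- function(si) {
    sname <- spec$samples$sample[si]
    cond <- spec$samples$condition[si]
    per <- spec$n_cells_per_subclass
    subclass <- rep(names(per), per)
    n <- length(subclass)
    x <- stats::runif(n, spec$x_domain[1], spec$x_domain[2])
    depth <- numeric(n)
    for (sc in names(per)) {
      idx <- subclass == sc
      if (sc == "VLMC") {
        depth[idx] <- abs(stats::rnorm(sum(idx), 0, spec$anchor_jitter_sd))
      } else {
        rng <- spec$layer_depth_ranges[[sc]]
        depth[idx] <- stats::runif(sum(idx), rng[1], rng[2])
      }
    }
    base <- cbind(x, polyval(spec$pial_curve_coeffs, x))
    nrm <- curve_normal(spec$pial_curve_coeffs, x)
    pos <- base + nrm * depth
    tangent <- arc(x)
    in_v1 <- tangent >= spec$v1_interval[1] & tangent <= spec$v1_interval[2]

    # expected rate per gene (at reference volume 300 um^3)
    rate <- matrix(0.05, nrow = n, ncol = length(genes),
                   dimnames = list(NULL, genes))
    rate[, gs$filler] <- 2
    rate[subclass == "VLMC", gs$anchor] <- 25
    for (sc in names(gs$subclass_markers))
      rate[subclass == sc, gs$subclass_markers[[sc]]] <- 20
    rate[, gs$v1_on] <- ifelse(in_v1, 8, 1)
    rate[, gs$v1_off] <- ifelse(in_v1, 1, 8)
    is_l23 <- subclass == "L23"
    idsets <- list(gs$identity_A, gs$identity_B, gs$identity_C)
    for (k in 1:3) {
      prof <- 8 * exp(-((depth - spec$abc_gradient_centers[k]) /
                          spec$abc_gradient_width)^2)
      rate[is_l23, idsets[[k]]] <- prof[is_l23]
    }
    ieg_rate <- ifelse(subclass == "VLMC", 0.1, 2.5)
    if (cond == "DR") ieg_rate <- ieg_rate * 2^spec$ieg_logfc_dr
    rate[, gs$iegs] <- ieg_rate

    volume <- stats::rlnorm(n, log(300), 0.35)
    out <- stats::runif(n) < 0.015
    volume[out] <- ifelse(stats::runif(sum(out)) < 0.5,
                          stats::runif(sum(out), 10, 45),
                          stats::runif(sum(out), 2100, 3000))
    lam <- rate * (volume / 300) * batch[[sname]]
    counts <- matrix(stats::rpois(length(lam), lam), nrow = n,
                     dimnames = dimnames(lam))
    blank_rate <- 0.012 * rowSums(lam)
    noisy <- stats::runif(n) < 0.02
    blank_rate[noisy] <- blank_rate[noisy] * 8
    blanks <- stats::rpois(n, blank_rate)

    # latent A/B/C label for L2/3 cells: nearest gradient center
    type <- rep(NA_character_, n)
    type[is_l23] <- c("A", "B", "C")[
      apply(abs(outer(depth[is_l23], spec$abc_gradient_centers, "-")), 1,
            which.min)]
    data.frame(x_um = pos[, 1], y_um = pos[, 2], volume = volume,
               blanks = blanks, sample = sname, condition = cond,
               subclass = subclass, depth_true = depth,
               tangent_true = tangent, in_v1_true = in_v1, type_true = type,
               stringsAsFactors = FALSE) -> meta
    list(meta = meta, counts = counts)
  }

  parts <- lapply(seq_len(nrow(spec$samples)), one_sample)
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  counts <- do.call(rbind, lapply(parts, `[[`, "counts"))
  meta$cell_id <- sprintf("cell%05d", seq_len(nrow(meta)))
  rownames(counts) <- meta$cell_id

  public <- meta[, c("cell_id", "x_um", "y_um", "volume", "blanks",
                     "sample", "condition", "subclass")]
  m <- count_matrix(counts, public)
  cells <- data.frame(cell_id = meta$cell_id, x_um = meta$x_um,
                      y_um = meta$y_um,
                      anchor_flag = meta$subclass == "VLMC",
                      sample = meta$sample, condition = meta$condition,
                      stringsAsFactors = FALSE)
  truth <- list(
    cell_table = meta,
    type_labels = meta$type_true,
    planted_effects = list(pial_curve_coeffs = spec$pial_curve_coeffs,
                           ieg_logfc_dr = spec$ieg_logfc_dr,
                           v1_interval = spec$v1_interval,
                           abc_gradient_centers = spec$abc_gradient_centers,
                           batch_factors = batch),
    gene_sets = gs)
  list(matrix = m, cells = cells, truth = truth)
}

#' Build a spatial cell table from a count matrix
#'
#' Flags pial anchor cells by expression of an anchor marker gene.
#'
#' @param m a [count_matrix()] whose metadata has `x_um`, `y_um`.
#' @param anchor_gene gene id of the pial (VLMC) marker.
#' @param min_counts anchor flag threshold on raw counts.
#' @return data.frame with `cell_id, x_um, y_um, anchor_flag, sample,
#'   condition`.
#' @export
spatial_cell_table <- function(m, anchor_gene = "Slc6a13", min_counts = 5) {
  stopifnot(inherits(m, "count_matrix"))
  md <- m$cell_meta
  if (!all(c("x_um", "y_um") %in% names(md)))
    stop("cell_meta needs x_um and y_um")
  if (!anchor_gene %in% m$gene_ids) stop("anchor gene not in matrix")
  data.frame(cell_id = md$cell_id, x_um = md$x_um, y_um = md$y_um,
             anchor_flag = m$counts[, anchor_gene] >= min_counts,
             sample = if ("sample" %in% names(md)) md$sample else "all",
             condition = if ("condition" %in% names(md)) md$condition else NA,
             stringsAsFactors = FALSE)
}
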