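# Curved cortical coordinates: pial curve fitting, depth/tangent assignment,
# V1 localization along the tangential axis.

# Nearest point on y = f(x) for each (px, py): coarse 5-um grid over the
# domain, then a fine 0.05-um local grid. Returns x*, distance.
nearest_on_curve <- function(px, py, coeffs, domain, coarse = 5, fine = 0.05) {
  xs <- seq(domain[1], domain[2], by = coarse)
  ys <- polyval(coeffs, xs)
  n <- length(px)
  best_x <- numeric(n)
  chunk <- 1000
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    d2 <- outer(px[idx], xs, "-")^2 + outer(py[idx], ys, "-")^2
    best_x[idx] <- xs[max.col(-d2, ties.method = "first")]
  }
  off <- seq(-coarse, coarse, by = fine)
  xf <- outer(best_x, off, "+")
  xf <- pmin(pmax(xf, domain[1]), domain[2])
  d2f <- (xf - px)^2 + (polyval(coeffs, xf) - py)^2
  d2f <- matrix(d2f, nrow = n)
  j <- max.col(-d2f, ties.method = "first")
  pick <- cbind(seq_len(n), j)
  list(x = xf[pick], dist = sqrt(d2f[pick]))
}

#' Fit the pial surface as a quartic through anchor cells
#'
#' Iterative robust fit: a fourth-order polynomial y = f(x) is fitted to the
#' anchor (pial-marker-positive) cells by least squares; anchor depths
#' (distances to the curve) are computed; anchors deeper than
#' `prune_fraction` times the robust maximum depth (the 95th percentile) are
#' dropped; the curve is refitted. Iteration stops when the retained anchor
#' set is unchanged or after `max_iter` rounds. Sections must be oriented so
#' the pia is single-valued in x (y increasing away from the pia).
#'
#' @param cells data.frame with `x_um`, `y_um`, `anchor_flag` (>= 10 anchors).
#' @param max_iter maximum refinement rounds.
#' @param prune_fraction fraction of the robust maximum depth beyond which
#'   anchors are pruned (0.5 = "deeper than half the maximum").
#' @param stable_tol stop when the refitted curve moves less than this
#'   (microns, max over the domain) — the "reference line is stable"
#'   criterion that ends the pruning once only honest anchor jitter remains.
#' @param min_prune_depth never prune anchors within this depth (microns) of
#'   the curve; keeps sub-resolution jitter from triggering pruning on
#'   near-exact fits.
#' @return Numeric coefficients c0..c4 with attributes `domain` (x-range of
#'   anchors) and `n_anchors_retained`.
#' @export
fit_pial_surface <- function(cells, max_iter = 10, prune_fraction = 0.5,
                             stable_tol = 1, min_prune_depth = 1) {
  stopifnot(all(c("x_um", "y_um", "anchor_flag") %in% names(cells)))
  ax <- cells$x_um[cells$anchor_flag]
  ay <- cells$y_um[cells$anchor_flag]
  if (length(ax) < 10) stop("fit_pial_surface: need >= 10 anchor cells")
  keep <- rep(TRUE, length(ax))
  coeffs <- NULL
  grid <- seq(min(ax), max(ax), length.out = 200)
  prev_y <- NULL
  for (it in seq_len(max_iter)) {
    coeffs <- poly_fit(ax[keep], ay[keep], deg = 4)
    cur_y <- polyval(coeffs, grid)
    if (!is.null(prev_y) && max(abs(cur_y - prev_y)) < stable_tol) break
    prev_y <- cur_y
    domain <- range(ax[keep])
    d <- nearest_on_curve(ax[keep], ay[keep], coeffs, domain)$dist
    thr <- max(prune_fraction * stats::quantile(d, 0.95, names = FALSE),
               min_prune_depth)
    drop_now <- d > thr
    if (!any(drop_now)) break
    keep[which(keep)][drop_now] <- FALSE
    if (sum(keep) < 5) stop("fit_pial_surface: fewer than 5 anchors left")
  }
  structure(coeffs, domain = range(ax[keep]), n_anchors_retained = sum(keep))
}

#' Assign curved cortical coordinates (depth and tangential arc length)
#'
#' Depth is the Euclidean distance from a cell to its nearest point on the
#' pial curve; the tangential coordinate is the arc length from the start of
#' the curve's x-domain to that nearest point (trapezoidal integration at 1-um
#' steps). Cells whose x falls outside the fitted domain by more than 10% of
#' the domain width are flagged `extrapolated`.
#'
#' @param cells data.frame with `cell_id`, `x_um`, `y_um` (plus `sample`,
#'   `condition` carried through if present).
#' @param curve_coeffs output of [fit_pial_surface()] (or raw coefficients
#'   plus a `domain` attribute).
#' @return A `cortical_frame` data.frame: `cell_id, depth_um, tangent_um,
#'   extrapolated`, with the curve and domain as attributes.
#' @export
assign_cortical_coordinates <- function(cells, curve_coeffs) {
  domain <- attr(curve_coeffs, "domain")
  if (is.null(domain)) domain <- range(cells$x_um)
  np <- nearest_on_curve(cells$x_um, cells$y_um, as.numeric(curve_coeffs),
                         domain)
  arc <- arc_length_fun(as.numeric(curve_coeffs), domain)
  width <- diff(domain)
  extrap <- cells$x_um < domain[1] - 0.1 * width |
    cells$x_um > domain[2] + 0.1 * width
  out <- data.frame(cell_id = cells$cell_id, depth_um = np$dist,
                    tangent_um = arc(np$x), extrapolated = extrap,
                    stringsAsFactors = FALSE)
  for (col in c("sample", "condition"))
    if (col %in% names(cells)) out[[col]] <- cells[[col]]
  attr(out, "curve_coeffs") <- as.numeric(curve_coeffs)
  attr(out, "domain") <- domain
  class(out) <- c("cortical_frame", "data.frame")
  out
}

#' Locate V1 along the tangential axis from an on/off marker pair
#'
#' Both marker profiles are smoothed along the tangential coordinate with a
#' Gaussian kernel of width `smoothing_um` (Nadaraya-Watson, evaluated on a
#' regular grid). V1 is the maximal contiguous interval where the smoothed
#' enrichment marker is at or above its tangential median and the depletion
#' marker at or below its own. The median-threshold rule is this module's
#' reconstruction of a qualitative marker-based localization.
#'
#' @param frame a `cortical_frame`.
#' @param expr_on,expr_off per-cell levels of the enriched / depleted marker
#'   (any monotone expression scale).
#' @param smoothing_um Gaussian kernel width in microns.
#' @param grid_um evaluation grid step.
#' @return c(tm, tl): the V1 interval endpoints in tangential microns.
#' @export
locate_v1 <- function(frame, expr_on, expr_off, smoothing_um = 100,
                      grid_um = 25) {
  t <- frame$tangent_um
  stopifnot(length(expr_on) == length(t), length(expr_off) == length(t))
  grid <- seq(min(t), max(t), by = grid_um)
  smooth_at <- function(v) {
    vapply(grid, function(g) {
      w <- exp(-((t - g) / smoothing_um)^2)
      sum(w * v) / sum(w)
    }, numeric(1))
  }
  on_s <- smooth_at(expr_on)
  off_s <- smooth_at(expr_off)
  eps_on <- 1e-9 * max(1, abs(stats::median(on_s)))
  eps_off <- 1e-9 * max(1, abs(stats::median(off_s)))
  ok <- on_s >= stats::median(on_s) - eps_on &
    off_s <= stats::median(off_s) + eps_off
  if (!any(ok)) stop("locate_v1: no qualifying tangential interval")
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(tm = grid[starts[best]], tl = grid[ends[best]])
}

#' Normalize tangential coordinates to the V1 interval
#'
#' Adds `tangent_norm` = (t - tm) / (tl - tm): 0 and 1 are the two ends of
#' V1; values < 0 or > 1 are flanking regions (preserved, not clipped).
#'
#' @param frame a `cortical_frame`.
#' @param v1_interval c(tm, tl) from [locate_v1()].
#' @return The frame with a `tangent_norm` column and a `v1_interval`
#'   attribute.
#' @export
normalize_tangential <- function(frame, v1_interval) {
  tm <- v1_interval[1]; tl <- v1_interval[2]
  if (tl == tm) stop("normalize_tangential: degenerate V1 interval (tl == tm)")
  frame$tangent_norm <- (frame$tangent_um - tm) / (tl - tm)
  attr(frame, "v1_interval") <- c(tm = unname(tm), tl = unname(tl))
  frame
}

#' Mean expression profile along cortical depth
#'
#' Bins cells by depth and reports, per bin, the mean of the gene-set-averaged
#' expression, first within sample, then averaged across samples with the SEM
#' over samples. Bins with no cells yield NA (not zero).
#'
#' @param frame a `cortical_frame` with a `sample` column.
#' @param nm a [normalized_matrix()] (the `lognorm` layer is used).
#' @param gene_set character vector of gene ids.
#' @param n_bins number of equal-width depth bins.
#' @param depth_range c(lo, hi) in microns; cells outside are ignored.
#' @param baseline optional scalar to divide the profile by (e.g. the mean
#'   level over V1 in reference-condition samples, for fold-change profiles).
#' @return data.frame: `bin_mid_um`, `mean`, `sem`, `n_cells`.
#' @export
depth_expression_profile <- function(frame, nm, gene_set, n_bins = 20,
                                     depth_range = NULL, baseline = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  gene_set <- intersect(gene_set, colnames(nm$lognorm))
  if (!length(gene_set)) stop("depth_expression_profile: no genes found")
  idx <- match(frame$cell_id, rownames(nm$lognorm))
  if (anyNA(idx)) stop("depth_expression_profile: frame cells not in matrix")
  score <- rowMeans(nm$lognorm[idx, gene_set, drop = FALSE])
  if (is.null(depth_range)) depth_range <- range(frame$depth_um)
  sel <- frame$depth_um >= depth_range[1] & frame$depth_um <= depth_range[2]
  breaks <- seq(depth_range[1], depth_range[2], length.out = n_bins + 1)
  bin <- cut(frame$depth_um[sel], breaks, include.lowest = TRUE, labels = FALSE)
  smp <- if ("sample" %in% names(frame)) frame$sample[sel] else rep("all", sum(sel))
  per_sample <- tapply(score[sel], list(bin = factor(bin, levels = seq_len(n_bins)),
                                        sample = smp),
                       mean)
  mn <- rowMeans(per_sample, na.rm = TRUE)
  nsamp <- rowSums(!is.na(per_sample))
  sem <- apply(per_sample, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(nsamp, 1))
  mn[nsamp == 0] <- NA
  if (!is.null(baseline)) { mn <- mn / baseline; sem <- sem / baseline }
  data.frame(bin_mid_um = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mean = unname(mn), sem = unname(sem),
             n_cells = as.integer(tabulate(bin, n_bins)))
}
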