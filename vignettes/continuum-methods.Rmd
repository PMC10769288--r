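---
title: "Archetypal continuum analysis of cortical cell types: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetypal continuum analysis of cortical cell types: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l23continuum)
```

## The scientific question

Upper-layer (L2/3) glutamatergic neurons of mouse visual cortex vary in a
graded way: their transcriptomes can be clustered into three types (A, B, C)
that occupy overlapping sublayers along the pial-ventricular axis, yet the
underlying gene expression looks more like a continuum than like three
separated islands. Two questions follow. First, is the continuum *genuine*,
or is it three discrete types blurred together by measurement noise? Second,
when the input to the circuit changes — dark rearing during the critical
period — does the continuum itself move: do archetypes shift, does the
distribution of cells along the manifold change, or do individual
type-identity genes change?

This package implements the complete analysis chain for those questions and
ships generative simulators for every input, so the chain can be exercised
and tested end to end with known ground truth. Nothing here requires an
external download; the simulators *are* the study system.

## The models

### The continuum simulator

Cells and genes carry latent normalized rankings $p_i = i/N_c$ and
$p_j = j/N_g$ (1-based ranks; both in $(0, 1]$ — the index origin is fixed
here because it matters for small $N_g$). Expected expression is a Gaussian
ridge along the diagonal,

$$\lambda_{ij} = \exp\!\left(-\left(\frac{p_i - p_j}{\varepsilon}\right)^2\right),
\qquad c_{ij} \sim s \cdot \mathrm{Poisson}(\lambda_{ij}),$$

with defaults $N_c = 600$, $N_g = 60$, $s = 100$ and $\varepsilon$ between
0.1 and 1. Two readings of "scaled Poisson" exist; counts here are integer
multiples of $s$ (the scale multiplies the draw, not the rate), matching the
formula as written. The alternative $\mathrm{Poisson}(s\lambda)$ reading
would change the noise-to-mean ratio.

### The discrete-type simulator

Three types, each with 20 marker genes and 200 cells:
$\lambda_{ij} = 1$ when cell $i$'s type matches gene $j$'s type and
$\varepsilon$ (leaky expression, in $[0,1]$) otherwise. To give the types an
order, the first 6 markers of each type are also expressed in the *next*
type (A markers leak into B, B into C); the chain does not wrap around from
the last type. Counts again are $s \cdot \mathrm{Poisson}(\lambda)$.

### The archetype mixture

For the triangularity test we also simulate cells as convex combinations of
three archetypal profiles with uniform Dirichlet weights plus Poisson noise.
Because the planted structure is *linear in count space*, the t-ratio test
is run on raw counts for this dataset: a log transform would curve the
simplex and blunt its corners, which is a property of the transform, not of
the data.

### The cortical-section emulator

The spatial emulator generates what the downstream geometry needs and no
more: a quartic pial curve with anchor (VLMC-like) cells jittered around it
(SD 4 µm); laminar subclasses placed uniformly in depth ranges
(L2/3 100–350 µm, L4 350–500, L5 500–700, L6 700–900); A/B/C identity-gene
sets with overlapping Gaussian depth profiles centered at 150/225/300 µm
(width 60 µm); a V1 marker pair (one enriched, one depleted) over a 2000-µm
tangential interval — the reported V1 scale; a panel of 8 IEGs upshifted by
a planted log2 fold-change of 2 in dark-reared samples; 4 samples (2 NR,
2 DR) with log-normal efficiency factors (SD 0.05 on the log); per-cell
volumes (log-normal around 300 µm³) that *scale the expected counts*, plus
~1.5% planted volume outliers and ~2% blank-heavy cells so the QC rules have
something to remove. Coordinates are microns with depth increasing away from
the pia.

What it does **not** emulate: optics, barcode decoding, segmentation errors,
ambient RNA, doublets, or realistic correlation structure among the
background genes. Passing tests therefore demonstrate that the *methods*
recover planted structure through the full pipeline — not that real tissue
satisfies the generative assumptions.

## The pipeline, stage by stage

### QC and normalization

QC keeps cells with volume in [50, 2000], total counts strictly above the
threshold (10 first pass; 50 for type-level analyses), and blank rate below
5%. The blank-rate denominator is blanks + gene transcripts (the convention
is ours; the rate is a ratio of detected events). MERFISH-style
normalization divides by volume, rescales per sample so the mean per-cell
total over the *non-excluded* genes equals 250 exactly, applies
log10(x + 1), and z-scores each gene across all cells pooled over samples.
The IEG panel is excluded from the size factors because a condition-driven
IEG upshift would otherwise deflate every other gene in the affected
condition — exactly the confound the exclusion removes. Whether z-scoring
should be within-sample instead of pooled is a genuinely open choice;
pooled is implemented because the downstream PCA pools conditions by design.
snRNA-seq-style normalization rescales cells to 10,000, then log10(x + 1)
(the log base is fixed to 10 for both modalities so the two layers are
comparable).

### HVGs and identity genes

Highly variable genes: on CP10k values, genes seen in ≥ 10 cells are binned
into mean-expression deciles (equal gene counts per bin, ties to the lower
bin) and the top 30% by variance/mean ratio are kept per bin — under Poisson
sampling that ratio is flat in the mean, so the binning removes the
mean-dependence of the selection. Identity genes: per type, one-vs-rest
Wilcoxon rank-sum (mid-ranks for ties; exact null below 25 per group,
normal approximation with tie and continuity corrections otherwise),
BH-FDR within type, and a marker requires FDR < 0.05, fold change > 2 on
CP10k means (pseudo-count 1 on both sides, so empty denominators cannot
occur), and expression in > 30% of the up-regulated type.

### Curved cortical coordinates

The pial surface is fitted as $y = f(x)$, a fourth-order polynomial through
the anchor cells (computed on centered/scaled $x$ and expanded back, since a
raw quartic over thousands of microns is numerically ill-conditioned).
Anchors deeper than half the robust maximum depth (the 95th percentile) are
pruned and the curve refitted, stopping when the anchor set is unchanged,
when the refitted line moves less than 1 µm anywhere (the "stable reference
line" criterion — without it the pruning rule would keep eating into honest
jitter forever), or after 10 rounds; anchors within 1 µm of the curve are
never pruned. Depth is the Euclidean distance to the nearest curve point
(coarse 5-µm grid then 0.05-µm local refinement), the tangential coordinate
is the arc length to that point (trapezoidal integration at 1-µm steps).
The single-valued parameterization is a documented precondition: sections
must be oriented (rotated) so the pia does not fold back in $x$.

V1 is located by smoothing an enrichment and a depletion marker along the
tangent (Gaussian kernel, 100 µm) and taking the longest contiguous interval
where the on-marker is at or above its tangential median and the off-marker
at or below its own. The median-threshold rule is this package's
reconstruction — the source analyses describe the marker-based localization
only qualitatively — and the recovered boundary is accurate to about one
kernel width. Tangential coordinates are then normalized,
$\tilde t = (t - t_m)/(t_l - t_m)$, so 0 and 1 are the two ends of V1 and
values outside $[0, 1]$ are flanking cortex (preserved, not clipped).

### Spatial domains and label transfer

Whole-section clustering uses a hybrid graph: shared-nearest-neighbour
(Jaccard) weighted kNN graphs in expression-PC space and in physical space,
blended edge-wise with equal weighting (0.5) on the union of edge sets, then
Leiden with the modularity objective (resolution 1, seeded). The SNN kernel
is our choice where the source delegates to library defaults. Label
transfer assigns each query cell the modal label of its k nearest reference
cells (k = 100 at class level, 30 at subclass level; ties to the nearest
neighbour), abstaining with NA when at most 2 of its k nearest neighbours
*in the joint reference + query pool* are reference cells — the signature
of a cell the integration failed to mix.

### Archetypes, the t-ratio, and the two shuffling tests

PCA on the z-scored identity genes (deterministic sign convention: each
component's largest-magnitude loading is positive). The archetypes are
fitted with principal convex hull analysis (PCHA): archetypes are convex
combinations of cells, cells are approximated by convex combinations of
archetypes, alternating projected-gradient least squares with adaptive step
sizes, FurthestSum initialization, delta = 0, three archetypes, and a
relative-loss convergence tolerance of 1e-6.

The *t-ratio* is the area of the data's convex hull divided by the area of
its bounding triangle. PCHA archetypes are inscribed in the data, so the
PCHA triangle can be smaller than the hull and the ratio would not be
bounded by 1; the t-ratio here uses the **minimal-area enclosing triangle**
of the hull, under which the ratio lies in (0, 1] and equals 1 exactly when
the hull is a triangle. Both triangles are reported. The minimal triangle is
found over triangles formed by three tangent lines of the hull (every
minimal enclosing triangle is of that form, with at least one side flush
with a hull edge): flush candidates seed a vectorized grid over the other
two tangent angles, exact flush-flush-flush triples are enumerated, and the
best candidate is polished by Nelder-Mead. The implementation is checked
against a brute-force flush-edge oracle, the closed forms for a triangle
(ratio 1) and the unit square (ratio 1/2), and the uniform-disc limit
$\pi/(3\sqrt 3) \approx 0.6046$.

Significance: each gene is permuted independently across *all* cells
(destroying gene-gene correlation, preserving marginals), PCA is refit per
shuffle (the conservative choice; reusing fixed loadings is the other
reading and would only shrink the null), and the p-value uses the add-one
estimator $p = (1 + \#\{t_{null} \ge t_{obs}\})/(1 + B)$ with $B = 1000$,
so the smallest attainable p is 1/1001.

The *within-type* shuffle permutes each gene within each labelled group,
exactly preserving every per-(gene, type) value multiset. Applied to a
genuine continuum it crystallizes the groups into discrete clusters
(silhouette-selected K-means then picks k = number of groups with a higher
silhouette); applied to already-discrete types it changes nothing. The
verdict margin on the silhouette change defaults to 0.05.

Stability: archetypes are refit on 80% subsamples (10 trials), matched to
the full fit by exhaustive minimization over the 6 label permutations, and
displacement is reported relative to the minimum inter-archetype distance.
For cell subsamples the full-data PCA basis is reused (so displacements are
measured in a common frame); for gene subsamples the PCA must be refit on
the subset, with the sign convention keeping the frames comparable. This is
a package choice; the alternative (refitting PCA for cell subsamples too)
conflates archetype movement with basis rotation.

### ABC scores

Per cell, the mean z-score over each identity set ($z_a, z_b, z_c$) is
rescaled against its own distribution across cells,
$s_a = \mathrm{clip}\big((z_a - P_{40})/(P_{95} - P_{40}),\, 0,\, 1\big)$,
and normalized to probabilities $p_a + p_b + p_c = 1$; cells above 0.6 in
some $p$ are "archetypal". Values below the 40th percentile clip to zero
rather than reflecting: a reflected |·| reading of the rescaling would give
strongly *anti*-correlated cells high scores, contradicting the bounded
[0, 1] intent, so the absolute value in the source formula is treated as a
typographical artifact. Cells with all three rescaled scores zero get the
uninformative (1/3, 1/3, 1/3).

### Pseudotime

Diffusion pseudotime: kNN graph (k = 50) in the top-50-PC space of the
z-scored identity genes, locally-scaled Gaussian kernel, anisotropic
(density-removing) normalization, and the DPT distance from the root cell
(the cell with the smallest PC1) over the non-trivial eigenpairs with
weights $\lambda/(1-\lambda)$; min-max rescaled so the root is 0.
Disconnected cells (off the largest component) get NA and a flag. Gene
pseudotime is the expression-weighted mean of cell pseudotime,
$T_g = \sum_c w_{gc} t_c$ with $w_{gc} = x_{gc}/\sum_{c'} x_{gc'}$ computed
on the non-negative log-normalized layer — weights require non-negative
expression, which is why the z-scored layer is not eligible. $T_g$ is
defined on a reference condition and held fixed across comparisons.

### Redistribution and vision-dependent genes

Condition comparisons on the identity-gene PC1-PC2 plane: shared-grid 2-D
probability histograms (bin width 1.25 PC units, inside the 1–1.5 range the
density estimates are robust to) and their difference; the Jensen-Shannon
*distance* (square root of the divergence, natural-log base — the convention
of the implementation the field commonly cites; a base-2 variant is a flag
away). Optimal transport between the uniform empirical distributions is
solved *exactly* — transportation simplex (north-west start, MODI pivoting)
under squared-Euclidean cost — rather than by an entropic approximation;
with a few hundred points per side the LP is well within reach, and the
analysis driver subsamples to 150 per condition, where the solve takes
seconds. The coupling is summarized as a coarse-grained vector field: mean
coupling-weighted displacement per source-grid bin with the member count.

Pseudo-bulk differential expression treats biological samples, not cells,
as replicates: counts are summed per (type, sample), CPM-normalized, genes
filtered at mean CPM > 10 in at least one (type, condition) stratum, tested
per type with a two-sided pooled-variance t-test across samples, BH-FDR
within type (per-type correction matches the per-type calling; a pooled
option exists but is off by default), and called at FDR < 0.05 and
|log2FC| > 1 (pseudo-count 1 CPM on both sides of the fold change). Overlap
enrichment between gene lists uses the Fisher exact test over an explicit
background with the sample odds ratio ad/bc (Haldane 0.5 correction,
flagged, when a cell is empty). Identity genes are finally grouped by their
regulation pattern across types A/B/C; the six-group mapping (up in
all/two/one, down in all/two/one, with no-change and mixed categories) is a
reconstruction of a figure-level grouping the source text does not
enumerate, and is overridable by an explicit pattern → group rule table.

## Numerical choices and degenerate inputs

* Permutation p-values are never exactly zero (add-one estimator).
* PCA/PCHA sign and initialization are deterministic; all stochastic
  operations take explicit seeds and the clustering entry points refuse to
  run without one.
* Collinear embeddings: PCHA raises a degenerate-fit error; the minimal
  enclosing triangle and t-ratio reject hulls with fewer than 3 points or
  zero area.
* Zero-variance genes z-score to 0 rather than NaN; all-zero cells are
  dropped with a warning during CP10k normalization; all-zero genes get
  undefined (NA) gene pseudotime, flagged.
* Ties: Wilcoxon uses mid-ranks; K-means silhouette selection takes the
  first maximum; label-transfer votes break ties by the nearest neighbour.
* The transportation simplex breaks pivot ties by index, making couplings
  reproducible; marginal feasibility is verified to 1e-8 on exit.

## Problem sizes

The shipped analyses and tests run at deliberately desk-size scales chosen
once: 600 x 60 for the simulators (the published simulation configuration),
~4,000 cells x 55 genes for the section emulator, 1000 permutations for the
t-ratio test, 150 points per side for the transport LP, and 20 replicates
x 1000 genes for the null-calibration suite of the pseudo-bulk test. At
these sizes the full test suite and the analysis chain each complete in a
few minutes on a single core.

## Known limitations

* The t-ratio convention (minimal enclosing vs PCHA triangle) changes the
  numeric value of the ratio; conclusions from the permutation test are
  insensitive to the choice because observed and null use the same
  convention, but reported t-ratios should not be compared across
  conventions.
* The V1 boundary rule and the six-group regulation mapping are documented
  reconstructions (see above), not transcriptions.
* The emulator's background genes are independent Poisson; it cannot be
  used to study correlated technical noise.
* The transportation simplex is exact but dense; beyond ~500 points per
  side it becomes the bottleneck and subsampling is the intended usage.
* `cell_pseudotime` computes a dense eigendecomposition; it is meant for
  10^3–10^4 cells, not 10^6.
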