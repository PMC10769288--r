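# l23continuum

Tools for asking whether a neuronal population is a *genuine* transcriptomic
continuum bounded by archetypes, how that continuum maps onto curved
cortical tissue, and how a perturbation (e.g. dark rearing during the visual
critical period) redistributes cells along it. The package targets the
kind of data produced by imaging-based spatial transcriptomics (MERFISH)
and snRNA-seq of mouse visual cortex L2/3 glutamatergic neurons, and ships
generative simulators for every input so the whole chain runs — and is
tested — without any external data.

## The methods at its core

* **Archetypal analysis (PCHA).** Cells in the PC1–PC2 plane of the
  type-identity genes are modelled as convex combinations of three
  archetypes, themselves convex combinations of cells: minimize
  ‖X − XCS‖² over column-stochastic C and S (alternating projected
  gradient, delta = 0, noc = 3).
* **t-ratio permutation test.** t = area(convex hull) / area(minimal-area
  enclosing triangle) ∈ (0, 1]; the null permutes each gene independently
  across all cells (1000 shuffles, PCA refit per shuffle), p by the
  add-one estimator. Near-1 observed ratios that beat every shuffle mean
  the triangle is real, not a covariance accident.
* **Within-type shuffling.** Permuting each gene within each cluster
  preserves per-(gene, type) marginals exactly; it splits a true continuum
  into discrete silhouette-selected K-means clusters, while leaving
  already-discrete types unchanged — a test that distinguishes "continuum"
  from "noisy discrete types".
* **Curved cortical coordinates.** Iterative robust quartic fit of the pial
  surface through anchor (VLMC) cells; per-cell depth (distance to curve)
  and tangential arc length; V1 located from an enrichment/depletion marker
  pair; tangential coordinates normalized so V1 spans [0, 1].
* **ABC scores.** Per-cell probabilities (p_a, p_b, p_c), p_a + p_b + p_c
  = 1, from percentile-rescaled mean z-scores of the three identity-gene
  sets; max p > 0.6 flags archetypal cells.
* **Diffusion pseudotime** of cells (root = smallest PC1) and genes
  (T_g = Σ_c w_gc t_c, expression-weighted).
* **Redistribution under perturbation.** Shared-grid 2-D densities,
  Jensen–Shannon distance, *exact* optimal transport (transportation
  simplex) with a coarse-grained displacement field, focused K-means to
  match types across conditions, pseudo-bulk differential expression with
  samples as replicates, Fisher overlap enrichment, and regulation-pattern
  grouping of identity genes.

## Worked example

```r
library(l23continuum)

# 600 cells as uniform-Dirichlet mixtures of three archetype profiles
mix <- simulate_archetype_mixture(n_cells = 600, n_genes = 60, seed = 7)
fit <- t_ratio_test(mix$matrix$counts, n_shuffles = 1000, seed = 8)
print(fit)
#> triangle_fit: t-ratio 0.9812, p = 0.000999 (1000 shuffles)

# a 1-D expression continuum, cut into 3 contiguous latent groups
sim <- simulate_continuum(epsilon = 0.2, seed = 7)
nm  <- normalize_snrnaseq(sim$matrix)
lab <- cut(sim$truth$cell_ranking, 3, labels = c("T1", "T2", "T3"))
verdict <- continuum_vs_discrete_test(nm$z, lab, k_range = 2:6, seed = 9)
print(verdict)
#> verdict: continuum (k_orig = 2 sil 0.339; k_shuf = 3 sil 0.399; delta 0.061)

pt <- cell_pseudotime(nm$z, n_pcs = 50, k = 50)
cor(pt$tc, sim$truth$cell_ranking, method = "spearman")
#> [1] 0.943
```

Reading the output: the mixture's convex hull fills 98% of its minimal
enclosing triangle and no shuffled dataset comes close (p = 1/1001, the
smallest value 1000 permutations can give) — the triangle is genuine
structure. On the continuum, within-type shuffling *raises* the silhouette
(0.34 → 0.40) and crystallizes exactly k = 3 clusters, the signature of a
true continuum rather than three noisy types; and diffusion pseudotime
recovers the planted latent ordering (Spearman ≈ 0.94–0.97 across seeds).

## The analysis chain

`analysis/01_simulate.R` … `analysis/06_deprivation.R` run the full study
on synthetic data: simulators → QC/normalization/HVGs/markers → pial curve,
depth/tangent coordinates and V1 → hybrid-graph spatial domains and label
transfer → archetypes, shuffling verdicts, ABC scores and pseudotime →
NR-vs-DR redistribution, optimal transport, pseudo-bulk DEG and regulation
groups. Each script narrates what it finds and writes small summary tables
under `results/`; regenerable raw matrices live under `scratch/` (run the
scripts in order).

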