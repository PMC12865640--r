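---
title: "Methods: directional spatial proximity, ligand–receptor scoring and niche analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional spatial proximity, ligand–receptor scoring and niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaxtalk)
```

spaxtalk quantifies directional cell–cell communication in imaging-based
spatial transcriptomics data: which cell types sit next to which, which
ligand–receptor (LR) pairs are expressed across those contacts, and how
the tissue organizes into neighborhoods (niches). This vignette is the
package's own account of the statistical machinery: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate about real data.

## The data model

The unit of analysis is a segmented cell with a centroid in a global
micrometer frame, a field-of-view (FOV) id, and a cell-type label, plus
a cells × genes count matrix. Two assumptions are load-bearing:

* **FOVs are spatially incomparable.** Imaging tiles are acquired
  separately; coordinates are only meaningful within a tile. Every
  spatial computation in the package therefore conditions on FOV:
  cross-FOV kernel weights are exactly 0, nearest-landmark searches stay
  within the FOV, and permutation nulls shuffle labels within FOV only.
* **Expression needs library-size correction, nothing more.** Counts
  are divided by the per-cell total and scaled to 10,000
  (counts-per-10k). The LR score multiplies ligand and receptor values,
  and products of log-transformed values have no natural interpretation,
  so scoring uses linear (not log) normalized expression. A `log1p`
  transform can be applied by the caller, but it is deliberately not the
  default. Cells with zero total counts cannot be normalized; they are
  flagged and excluded from all scoring sums rather than silently
  treated as biological zeros.

## Directional spatial proximity

For source cell $i$ and any other cell $j$ in the same FOV,

$$w_{ij} = \exp\!\left(-\frac{d_{ij}^2}{2\sigma^2}\right),$$

with $w_{ii} = 0$ and $\sigma$ the bandwidth. The cell-type score is the
mean over source cells of the (optionally per-cell normalized) weight
mass landing on each target type. Averaging over *source* cells is what
makes the matrix directional: a rare type surrounded by an abundant one
concentrates its weight on that neighbor, while the abundant type
spreads its weight over its own kind.

Choices worth knowing about:

* **Bandwidth default 20 µm.** This matches the only spatial scale the
  direct-contact analyses use (counts of neighbors within a 20 µm
  radius, roughly one to two cell diameters). At $d = \sigma$ a pair
  retains 61% weight, at $3\sigma$ 1.1% — the score reads as "weighted
  contact likelihood" rather than long-range correlation.
* **The kernel is not truncated.** Within-FOV distance matrices at
  CosMx FOV sizes are small enough to compute densely, so the
  implementation is the definition — it agrees with an independent
  double-loop reference to 10⁻¹² relative tolerance in the test suite,
  with no approximation layer to reason about.
* **Normalization mode.** Per-source-cell normalization (the default)
  makes each row of the matrix a composition (rows sum to 1), so scores
  are comparable across source types with different abundances. The
  unnormalized mode is exposed (`normalize = FALSE`) for density-style
  readings; under it, uniformly scaling all distances up can only
  decrease scores.
* **Isolated cells.** A source cell whose total kernel weight
  underflows to zero cannot be normalized; it is dropped from the
  average and counted, and a fully isolated source type yields an `NA`
  row rather than a fabricated zero.

## Spatially weighted LR scoring

For a one-to-one pair $(L, R)$ and direction $S \to T$:

$$\mathrm{score} =
  \frac{\sum_{i \in S}\sum_{j \in T} x_{iL}\, x_{jR}\, w_{ij}}
       {\sum_{i \in S}\sum_{j \in T} w_{ij}},$$

the kernel-weighted mean of the ligand × receptor product over
source–target cell pairs, pooled across FOVs. Dividing by the total
weight makes the score an average rather than a mass, so directions with
very different cell counts remain comparable; the score is bilinear in
expression (doubling ligand expression doubles it) and invariant to
adding cells of uninvolved types. Self-self cell-type requests are
rejected outright — the scientific target is intercellular signaling,
and autocrine signal would otherwise dominate any abundant type.

Rankings within a direction sort by score with ties broken by `pair_id`
lexicographically, so top-20 tables are reproducible to the byte.

### Permutation significance and its honest limits

The null shuffles cell-type labels within each FOV, keeping coordinates
and expression fixed, and recomputes the score; the p-value uses the
add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$
and the z-score standardizes against the null mean and SD (a degenerate
zero-SD null returns `NA` for z while the p-value remains valid).

This null is exact when type labels are exchangeable across cell
positions. It is **anti-conservative when the tested types are spatially
zonated**: if, say, the target type clusters around portal tracts, the
observed label configuration concentrates kernel weight on fewer,
closer pairs than any shuffled configuration, inflating the variance of
the observed score relative to the null. On simulated data with the
tested types placed uniformly, the test rejects at close to the nominal
5% rate (the 400-dataset calibration experiment in
`scripts/acceptance.R` recomputes this); with a zonated target type the
rejection rate is visibly inflated. Interpret small p-values for
strongly zonated type pairs as "spatial co-expression given the observed
geometry", not as calibrated frequentist error — or verify with the
planted-effect-size machinery of the simulator. Permutations are
restricted within FOV precisely so that FOV-composition differences do
not masquerade as signal.

## Landmark distances and radius counts

`nearest_landmark_distance()` reports, per query cell, the Euclidean
distance to the nearest landmark-type cell in the same FOV (cells in
FOVs lacking landmarks are `NA` and excluded from summaries, with a
message). `neighbors_within_radius()` counts neighbor-type cells within
the radius, self excluded. Both are contractually *exact*: the test
suite holds them to equality with brute-force double loops, and both are
invariant under rigid transforms of the coordinate frame to 10⁻⁹.
Querying a type against itself as landmark is rejected as ill-posed
(the answer is identically zero).

## Niche analysis

The niche model is a two-stage construction:

1. **Neighborhood composition** — for each cell, the cell-type
   frequency vector of its $k$ nearest same-FOV neighbors (self
   excluded; default $k = 30$, a neighborhood of roughly 50–100 µm at
   typical CosMx densities). Distance ties break by `cell_id` so the
   result is deterministic; in FOVs with fewer than $k+1$ cells, $k$ is
   truncated with a warning.
2. **Centroid clustering** — k-means on the composition vectors into at
   most `n_niches` clusters (default 6). Initialization is
   deterministic and row-order-invariant: the initial centers are
   evenly spaced rows of the lexicographically sorted distinct
   compositions. Random restarts were rejected because they make the
   partition depend on the order cells happen to arrive in — with a
   fixed RNG seed, permuting the input rows changes which rows seed the
   clusters and can flip the local optimum. With the deterministic
   initialization, the assignment is a pure function of the composition
   values, so it is invariant to row permutations and to rigid motions
   of the tissue. Empty clusters are dropped, never re-seeded, and
   niches are labeled `niche_1, niche_2, …` by descending size.

Per-niche summaries report cell-type proportions, mean distance to the
nearest landmark-type cell, and mean normalized expression of a gene
panel (default: the inflammation/fibrosis transcripts CCL2, CXCL10,
ITGAM, CCR2, COL1A1 plus IL1B and IL1R1). The number of niches and the
neighborhood size are genuinely free parameters — there is no canonical
tissue-intrinsic value — so both are exposed and recorded in the run
manifest.

## The synthetic-data generator

`generate_dataset()` draws CosMx-like datasets with known ground truth:

* **Geometry.** FOVs tile a global grid of 500 µm squares (300 cells
  per FOV by default, a realistic segmented-cell density). One anchor
  point per FOV emulates a portal tract: the landmark type
  (cholangiocyte-like, 5% abundance) scatters around it with σ = 25 µm.
  Under `radial_gradient`, the periportal type's placement density
  decays exponentially from the anchor (scale 50 µm); all other types
  are uniform. Under `two_block`, two lateral blocks (x in [0, 0.45]
  and [0.55, 1] of the FOV, with an unpopulated margin that keeps the
  ground-truth boundary identifiable) receive portal-associated and
  other types with probability 0.9 each — the block is the ground-truth
  zone label.
* **Counts.** Poisson with rate (per-cell log-normal library factor,
  log-sd 0.3) × (per-gene baseline). The baseline default of 2.5
  counts/gene over a 120-gene panel gives median per-cell totals near
  300, the scale of a 1000-plex panel. Mixing Poisson over a log-normal
  factor yields negative-binomial-like overdispersion at the gene level
  while keeping the generator seedable and transparent.
* **Planted interactions** act multiplicatively on the *rate*: the
  ligand rate in source-type cells and the receptor rate in target-type
  cells are multiplied by `effect_size` whenever the cell lies within
  `interaction_range_um` of a partner-type cell (default: effect 5
  within 30 µm). Planting on rates rather than editing counts means
  library-size normalization interacts with the effect exactly as it
  would with a real signal. Setting every effect to 1 provably returns
  the generator to the null — planting consumes no random numbers, so
  the output is bit-identical regardless of what was "planted".

**What the generator does not emulate**, and hence what passing tests do
not show about real data: segmentation errors and transcript
misassignment, gene–gene correlation beyond the library factor,
macrophage enrichment near portal tracts (macrophages are uniform, so
the 20 µm macrophage-count contrast between periportal and distal ECs is
flat in simulation — that analysis is validated by exact oracle
equivalence instead), multi-subunit receptor complexes, and any form of
tumor/non-tumor architecture (the `region` column and `drop_tumor` flag
exercise the filtering path only).

## Validation design and problem sizes

The test suite validates three distinct ways:

* **Oracle equivalence** — every spatial statistic (landmark distances,
  radius counts, k-NN compositions, proximity matrices, LR scores) is
  checked against an independent brute-force double-loop implementation
  on 20 random instances of 50–300 cells: exact equality for distances
  and counts, 10⁻¹⁰–10⁻¹² relative tolerance for kernel quantities.
* **Planted-truth recovery** — with effect 5 within 30 µm among 50
  decoy pairs (600 cells, 2 FOVs), the planted pair ranks first in its
  planted direction in 20/20 seeds and essentially never in the reverse
  direction, confirming that the score is genuinely directional.
* **Statistical calibration** — type-I error of the permutation test
  measured over 400 null datasets (150 cells each, n_perm = 99), power
  over 20 planted datasets (n_perm = 199); niche recovery as adjusted
  Rand index against ground-truth zones over 10 two-block datasets.

These sizes were chosen as the smallest at which the effects under test
are comfortably resolved; all of them re-run from scratch in the
package's test suite and in `scripts/acceptance.R`.

## Known limitations

* The permutation null's anti-conservativeness under zonation, above.
* Proximity and LR scores depend on a single global bandwidth; tissues
  with cell-type-specific contact scales would need per-pair bandwidth
  sweeps (cheap, but not automated here).
* Niche clustering is purely compositional — it does not enforce
  spatial contiguity, so a fragmented niche with a consistent
  microenvironment is one niche, by design.
* Coordinates are 2-D centroids; no account is taken of cell size,
  shape, or 3-D section geometry.
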