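# spaxtalk

Directional cell–cell communication analysis for imaging-based spatial
transcriptomics (CosMx-style single-cell data), written for tissue
biologists asking *which cell type is signaling to which, through which
ligand–receptor pair, and where in the tissue*. The motivating use case
is inflamed liver: macrophage-derived IL1B acting on IL1R1-expressing
sinusoidal endothelial cells in periportal zones, with cholangiocytes as
the spatial landmark for portal tracts. The toolkit is general — it
works on any per-cell table with coordinates, field-of-view (FOV) ids,
cell-type labels and a cells × genes expression matrix.

Every user-facing function takes a data frame first and returns a tidy
tibble, so analyses chain with the pipe; results carry `tidy()`,
`glance()` and `autoplot()` methods.

## What it computes

**Directional spatial proximity.** For source cell *i* and every other
cell *j* in the same FOV, a Gaussian kernel weight

    w_ij = exp( − d_ij² / (2 σ²) )        (σ = bandwidth, default 20 µm)

with the self weight removed and cross-FOV weights fixed at 0 (imaging
tiles are not spatially contiguous). With per-source-cell normalization,
each cell's weights become a composition over its neighborhood, and the
type-level score

    prox(S → T) = mean over cells i of type S of Σ_{j ∈ T} w̃_ij

is directional: averaging over source cells makes prox(S→T) ≠ prox(T→S)
whenever abundances or spatial arrangements differ.

**Spatially weighted ligand–receptor (LR) scores.** For a one-to-one
pair (L, R) and direction S → T,

    score = Σ_i Σ_j  x_iL · x_jR · w_ij  /  Σ_i Σ_j  w_ij

over source cells *i* and target cells *j* in the same FOV — the
kernel-weighted mean of the ligand × receptor expression product, with
expression library-normalized (counts-per-10k). Self-self cell-type
combinations are excluded throughout: the statistic targets
intercellular, not autocrine, signaling. Significance comes from a
within-FOV cell-type label permutation null.

**Distance and neighborhood analyses.** Per-cell shortest distance to
the nearest landmark-type cell (e.g. EC → nearest cholangiocyte),
counts of neighbor-type cells within a radius (default 20 µm), k-nearest-
neighbor niche composition with deterministic k-means clustering into
tissue niches, and per-niche summaries (cell-type proportions, mean
landmark distance, mean expression of an inflammation/fibrosis gene
panel).

**Synthetic data with planted truth.** `generate_dataset()` simulates
FOV-mosaic point patterns with a clustered landmark type, a periportally
zonated type, log-normal library-size variation, Poisson counts, and
planted LR interactions (multiplicative rate boosts within an
interaction range), so the whole stack is testable without external
data.

## Worked example

```r
library(spaxtalk)

sim   <- generate_dataset(sim_config(seed = 42))   # 600 cells, 2 FOVs,
sim                                                # 1 planted pair + 50 decoys
#> <spax_sim> 600 cells, 120 genes, 2 FOV(s), 51 LR pairs (1 planted)

norm   <- normalize_expression(sim$expr)
scores <- spatial_lr_scores(norm, sim$cells, sim$lr_pairs)
rank_lr_pairs(scores, "Macrophages", "ECs_and_LSECs_1", top_n = 5)[, c("pair_id", "score", "rank")]
#> # A tibble: 5 × 3
#>   pair_id           score  rank
#>   <chr>             <dbl> <int>
#> 1 IL1B_IL1R1      148206.     1
#> 2 GENE066_GENE048  11110.     2
#> 3 GENE037_GENE034   9260.     3
#> 4 GENE076_GENE019   8437.     4
#> 5 GENE081_ITGAM     8296.     5
```

The planted macrophage → periportal-EC IL1B–IL1R1 interaction tops the
ranking by more than a factor of 10 over the best decoy pair. The
periportal EC subset sits an order of magnitude closer to cholangiocytes
(portal landmarks) than the distal subset:

```r
glance(nearest_landmark_distance(sim$cells, "ECs_and_LSECs_1", "Cholangiocytes"))
#>   measure              mean median     n
#> 1 nearest_landmark_um  28.8   19.3    89
glance(nearest_landmark_distance(sim$cells, "ECs_and_LSECs_3", "Cholangiocytes"))
#>   measure              mean median     n
#> 1 nearest_landmark_um  160.   173.   103
```

and the planted interaction is highly significant against the
label-permutation null (p = 0.005 is the smallest value attainable with
199 permutations):

```r
lr_permutation_test(norm, sim$cells, "IL1B", "IL1R1",
                    "Macrophages", "ECs_and_LSECs_1", n_perm = 199, seed = 1)
#>   observed perm_z perm_p n_perm
#> 1  148206.   32.4  0.005    199
```

`run_pipeline(run_config(sim = sim_config(seed = 1), seed = 1), "out/")`
executes the whole chain — simulate/read, validate, proximity, LR
scoring, permutations, distances, niches, signatures — and writes TSV
tables plus a JSON run manifest; reruns with the same config are
byte-identical. A YAML-driven shell wrapper lives in
`inst/scripts/spaxtalk.R`.

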