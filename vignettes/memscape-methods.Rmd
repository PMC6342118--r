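---
title: "Methods: partitioning spatial drivers of genetic variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning spatial drivers of genetic variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Continuously distributed populations rarely satisfy the island-model
picture behind discrete clustering. Genetic similarity decays smoothly
with distance (isolation by distance, IBD) because dispersal is
distance-limited, and landscape features — roads, water bodies, recent
burns — can depress gene flow further (isolation by resistance, IBR).
`memscape` treats the individual, not a pre-defined population, as the
unit of analysis, and asks three questions: how much genetic variation is
spatially organized, how much of that spatial signal is attributable to
landscape resistance beyond plain geography, and which candidate
management-unit (MU) boundaries capture the dominant spatial genetic
pattern best.

## Data model

Diploid codominant genotypes (microsatellites) at `L` loci, projected
planar coordinates in meters, optional sex and group labels. Missing data
is a fully missing genotype (`NA` in both slots); half-called genotypes
are rejected at load time. Because repeat sampling of the same animal is
the norm in non-invasive studies, `match_duplicates()` collapses samples
whose unordered allele pairs agree at `min_matching_loci` (default 8 of
9) or more loci. Loci missing in either sample count as non-matching by
default — the conservative choice; `ignore_missing = TRUE` treats them as
uninformative instead. Chained near-matches are resolved by connected
components; the representative is the member with fewest missing loci
(ties: lowest input index), placed at the centroid of the member
coordinates.

A practical caveat established with the simulator: exact recovery of
planted duplicates requires a polymorphic background. Under very strong
IBD with small neighborhood sizes, close kin genuinely share 8 of 9 loci
and the 8-of-9 rule will (correctly, by its own definition) merge them —
a real ambiguity of threshold matching in inbred systems, not an artifact
of this implementation.

## Spatial genetic regression

The chain is: genetic distance → principal coordinates → MEM basis →
forward selection → redundancy analysis.

* **Genetic distance.** `D_ps = 1 −` proportion of shared alleles: per
  pair, the multiset intersection of allele pairs summed over loci
  complete in both, divided by twice that locus count. Configurable: any
  user dissimilarity can be supplied to `mgquick(D = ...)`.
* **Response.** Gower-centered `−D²/2` is eigen-decomposed; all axes with
  positive eigenvalues (relative tolerance `1e-10`) are retained and
  scaled by `sqrt(eigenvalue)`. No axis cap is applied by default, so the
  response carries the full Euclidean part of the dissimilarity.
* **MEM basis.** The PCNM construction: distances above a truncation `t`
  are replaced by `4t`, the modified matrix is Gower-centered and
  eigen-decomposed. `t` defaults to the longest edge of the minimum
  spanning tree — the smallest value keeping the neighbor graph
  connected. Positive-eigenvalue vectors model positive spatial
  autocorrelation (broad to fine scales); negative-eigenvalue vectors
  model negative autocorrelation.
* **Forward selection.** Stepwise selection over ~n/2 near-saturated
  candidate sets is notoriously anticonservative, so selection is gated
  and corrected: (i) a class-level global permutation test must pass
  (when both sign classes are eligible each gate runs at `alpha/2`);
  (ii) each step tests the best remaining candidate against the
  permutation distribution of the *maximum* marginal fit over all
  remaining candidates. The max-statistic builds the "best of many" bias
  into the null, so once true structure is exhausted the step test stops
  with probability `1 − alpha`. We preferred this to the classical
  cumulative-adjusted-R² cap: the cap's reference value (the adjusted R²
  of the full class regression) is unbiased but extremely noisy when the
  candidate count approaches `n` (standard deviation ≈ 0.09 at `n = 100`,
  `k ≈ 60` in our calibration runs), and in that regime it erratically
  truncates genuinely informative vectors; the max-statistic test
  addresses the same pathology without that variance. Orthonormality of
  the MEM basis makes marginal contributions additive, which keeps the
  permutation loops to one matrix product each.
* **RDA.** Fitted values of the (centered) response on the selected
  vectors; spatial genetic axes are the SVD axes of the fitted matrix,
  ordered by their eigenvalues. Explained variation is reported as
  Ezekiel-adjusted R², `1 − (1 − R²)(n − 1)/(n − m − 1)` with `m` the
  selected-vector count, with the raw R² alongside. Overall significance
  permutes response rows.

Under panmixia this pipeline reports an empty selection, `adjR2 = 0`,
`p = 1` in ≥ 92% of simulated null datasets (`n = 150`, 9 loci) — the
type-I calibration enforced by the test suite.

## Landscape models and the IBD/IBR partition

Vector features become a resistance raster: background cells cost 1,
feature cells the layer cost, overlaps take the maximum cost (a sum rule
is available). Roads are buffered by 500 m (radius); fire polygons are
filtered to ignition years 1964–2013 (a 50-year window). The default
resolution sets the cell size to 1/200 of the larger bounding-box
dimension and is overridable everywhere. Least-cost distances run over
the 8-connected cell graph with edge weights
`mean(cost_i, cost_j) × cell size` (×√2 diagonal); a 16-neighbor stencil
(knight moves, ×√5) is available where grid-metric anisotropy matters —
it tightens the worst-case overestimate from ~8% to ~2.8%. Two exactness
choices keep the partition's degenerate case honest: a *uniform* surface
short-circuits to the exact continuum solution (cost × straight-line
length — the raster only ever approximates that limit), and within one
`mg_landscape()` call both blocks' forward selections consume a common
random-number stream, so identical distance structures yield identical
selections rather than Monte-Carlo-divergent ones. Together these make
the flat cost-1 control literally the `X1 = X2` case: its landscape-unique
fraction is zero by construction, as a pure-IBD control should be. Costs
are relative: scaling all costs by a constant scales distances uniformly
and leaves every eigenvector, selection and fraction unchanged.

`mg_landscape()` builds one MEM basis from the cost distances (block X1)
and one from Euclidean distances (block X2), forward-selects each, and
partitions the adjusted R²:
`[abc] = adjR²(Y ~ X1∪X2)`, `[a] = [abc] − adjR²(Y ~ X2)` (landscape
beyond geography), `[c] = [abc] − adjR²(Y ~ X1)` (geography beyond
landscape), `[b] = adjR²(X1) + adjR²(X2) − [abc]` (confounded),
`[d] = 1 − [abc]`. The identities `a + b + c = abc` and `abc + d = 1`
hold exactly by construction; small negative adjusted fractions are
reported as computed. Partial significance tests permute the
residualized response. `model_search()` runs each feature class at costs
{10, 50, 100}, keeps the cost maximizing `[a]` (flag: `[abc]`), then runs
the four combinations plus the flat cost-1 surface, the pure-IBD control
described above.

## Management-unit comparison

`mu_varpart()` partitions the first spatial genetic axis (option: all
axes) between dummy-coded unit membership (treatment coding,
lexicographic reference) and spatial proximity. The spatial-proximity
block is a linear coordinate trend by design: the selected MEM
eigenvectors themselves span the response axis exactly — the axis is a
linear combination of them — so using them as the spatial block
(`space = "mem"`, kept for completeness) forces every scenario's unique
fraction `[a]` to zero and makes scenarios indistinguishable. A linear
trend captures "being nearby explains similarity" without that
degeneracy and keeps `[d] > 0` interpretable. Scenarios are ranked by
`[a]` (boundary-specific signal), ties by `[a] + [c]`; because added
dummy columns inflate explained variance and no penalty exists,
`compare_scenarios()` refuses scenarios with unequal unit counts unless
forced.

## The simulator

`simulate_population()` is a forward-time model at fixed uniform-random
sites: each generation, every site draws two parents with probability
∝ `exp(−d_eff²/2σ²)`, where `d_eff` multiplies the Euclidean distance by
the barrier multiplier when the straight segment crosses the barrier
(IBR), or uniformly at random (panmixia). One allele per parent per
locus, stepwise mutation ±1 repeat at rate μ with reflecting bounds at
repeat sizes [5, 50], founders at Hardy–Weinberg with 10 equifrequent
alleles. Defaults: 200 individuals, 9 loci, σ = 5% of a 100-km extent,
μ = 5 × 10⁻⁴, 100 non-overlapping generations — a regime that produces
clear clinal autocorrelation while keeping per-locus diversity in the
range typical of wildlife microsatellite panels. Individual movement is
not modeled (sampling, not tracking, is emulated), generations do not
overlap, and there is no selection or sex-biased dispersal; planted
duplicates are copies with a single perturbed locus.

What the simulator does *not* emulate — genotyping error, null alleles,
allele-size homoplasy beyond the stepwise model, non-equilibrium range
expansion — bounds what green tests mean for field data: they validate
the statistical machinery under the stated processes, not robustness to
laboratory artifacts.

Two regime notes established during design and enforced in the tests:

* **Mantel r vs dispersal.** The Mantel correlation declines with σ only
  while the smallest σ stays at or above the inter-individual spacing;
  below it, mating collapses onto isolated families, genetic distance
  saturates within a short range and the *linear* correlation fades even
  though local structure is extreme. The monotonicity checks therefore
  sample densely (n = 1000, 150 generations), where the σ grid {2%, 5%,
  20% of extent} is strictly ordered.
* **Duplicate identifiability.** Dedup recovery tests run on short
  panmictic histories (20 generations), where founder diversity is
  intact and the only 8-of-9 matches are the planted ones (see above).
* **Boundary discrimination.** The two-deme studies behind the MU
  comparison use σ = 10% of the extent with the barrier multiplier at
  10. At σ = 5%, within-side clines frequently dominate the first
  spatial genetic axis (axis-to-deme correlations as low as 0.03 in
  calibration runs), so "the" true boundary is not the dominant pattern
  and a first-axis comparison cannot be expected to single it out;
  milder within-deme autocorrelation restores the premise of the study.

## Numerical choices

Eigenvalue retention tolerances are relative (`1e-10` × leading
eigenvalue). Permutation p-values always carry the `(k+1)/(n_perm+1)`
correction and respect its lower bound. Permutation counts default to
999 (1000 for forward selection in `mgquick`); the heavy simulation
tests use 99–199 to keep suite runtimes reasonable, which only coarsens
p-value granularity, not the statistics. Distance-class construction in
the correlogram is equal-frequency by default (equal-width optional);
classes under 20 pairs merge downward with a warning, and a
single-degenerate-class correlation is reported as `NA`. Ties in forward
selection break by larger |eigenvalue|, then lower eigenvector index;
boundary points in polygon assignment go to the lowest-index polygon.
Least-cost solver output is symmetrized (averaging the two directions)
to remove floating-point asymmetry before eigen-decomposition. The
Weir–Cockerham estimator is reported as computed — including its small
negative values when differentiation is absent (with `s² = 0` the
among-population component is `−(p̄q̄ − h̄/4)/(n̄ − 1)`); it is unbiased,
not zero-valued, under identity.

## Problem sizes used by the test suite

Oracle equivalences run on ≤ 25-point fixtures. Type-I calibration: 200
panmictic replicates (n = 150) through the full regression, 500 null
Mantel replicates (n = 30). IBD monotonicity: 3 × 30 replicates at
n = 1000. IBR recovery: 100 replicates (n = 100, barrier multiplier 10,
model cost 100, rasters at 1/100 of extent, flat-surface control). MU
discrimination: 100 replicates (σ = 10% of extent) over three
equal-count candidate boundaries. Adjusted-R² recovery: 100 replicates
of a two-eigenvector construction at R² = 0.5.

## Known limitations

Polygon holes are unsupported in GeoJSON input. Circuit-theory
(commute-time) resistance and isolation-by-barrier models are out of
scope, as are Bayesian assignment and estimation of the number of
clusters — cluster labels enter as data. The MU comparison inherits the
first-axis convention; patterns concentrated on later axes need the
all-axes mode. Resistance rasterization by cell-center containment can
miss features narrower than a cell unless buffered.
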