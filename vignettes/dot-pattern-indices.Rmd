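---
title: "Graph-theoretic and occupancy indices for random dot patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic and occupancy indices for random dot patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numgraph)
```

## The problem

Numerosity-perception experiments present observers with random
configurations of dots and ask how many there are. Perceived numerosity is
known to depend not only on the true count but on *how the dots are
arranged* — clustered configurations are systematically underestimated.
`numgraph` quantifies arrangement. Every configuration of `n` dots inside a
circular aperture of radius `R`, together with a connectivity distance `d`,
induces a random geometric graph `G_d`: two dots are joined iff their
Euclidean distance is at most `d`. Varying `d` from the minimum dot spacing
to the aperture diameter turns one static pattern into a one-parameter
family of graphs, and graph indices computed along that family profile the
pattern's spatial structure at every scale.

The package computes eleven normalized indices, sweeps them over a grid of
connectivity distances, finds for each index the distance at which it is
most informative (the maximum-standard-deviation distance), and summarizes
the relationships between indices with significance-masked Pearson
correlation matrices and a varimax-rotated PCA.

## The stimulus model

`generate_pattern()` draws candidate points uniformly in the bounding
square `[-R, R]²`, rejecting candidates that fall outside the aperture or
within `delta` of an already-placed point. Defaults are the study
conditions: `R = 160` px (about 5° of visual angle at 57 cm on a 32 px/cm
display), `delta = R/16 = 10` px, numerosities `{22, 28, 34, 40}`, 1000
patterns per numerosity for the full study and 200 for the scaled-down
mode. The spacing constraint is cheap because two uniform disk points fall
within `delta` of each other with probability ≈ 0.0038
(`pair_proximity_probability()` checks this against a Monte-Carlo
estimate).

Sequential rejection sampling with a spacing constraint is *not* exactly a
uniform sample conditioned on all spacings holding (it is the "random
sequential adsorption" distribution), but at these densities — at most 40
disks of radius 5 px in an 80,425 px² aperture — the two are
indistinguishable in practice. A `max_attempts` cap (default 10⁵ candidate
draws per pattern) turns infeasible `n/delta/R` requests into an explicit
packing error; at the study parameters the cap is never approached.

Every pattern's sub-seed is derived from the master seed, the numerosity
and the replicate index by a fixed congruential rule (`derive_seed()`), so
any single pattern — and any stochastic sweep cell — can be regenerated in
isolation.

## The indices

All indices are normalized by their maximum possible value for fixed `n`
(occasionally the normalizer also involves `d`), so that the seven
combinatorial indices lie in [0, 1]:

* **TD** — total degree `2|E| / n(n-1)`, i.e. graph density.
* **TL** — total edge length `Σ_{(u,v) ∈ E} dist(u,v)` divided by its
  maximum possible value `2d · n(n-1)/2` (all possible edges present at
  the maximal length `d`); range [0, 0.5].
* **CC** — number of connected components over `n`.
* **CL** — clique number `ω(G)/n`, computed exactly (igraph's
  branch-and-bound), never by a heuristic.
* **DN** — domination number `γ(G)/n`, exact branch-and-bound over closed
  neighbourhoods (see *Numerical choices*).
* **IN** — independence number `α(G)/n`, exact.
* **LC** — mean local clustering coefficient with `lc_v = 0` for vertices
  of degree < 2 (the usual library convention: the defining ratio
  `2e(N(v)) / deg v (deg v - 1)` is undefined there).
* **GC** — global clustering (transitivity) `3T/P₂`, 0 when there are no
  connected triplets.
* **RW** — random-walk cover time: the mean number of steps `T̄` over
  1000 simulated walks (uniform random start, uniform random neighbour
  hops, stop when all vertices are visited), reported as `n ln n / T̄` so
  that values near 1 mean near-optimal cover. Disconnected graphs score
  0 — their cover time is infinite.
* **EG** — eigenvector centrality: power iteration on the adjacency
  matrix, initialized with the degree sequence, renormalized to unit
  Euclidean length every step; on convergence (successive iterates within
  `10⁻⁶` in max-norm, at most 1000 iterations) the index is the mean
  component of the dominant eigenvector, and 0 if the iteration does not
  converge. EG is *missing* (`NA`) for disconnected graphs — see below.
* **OC** — occupancy: the area of the union of disks of radius `r = d/2`
  centred on the dots, divided by `nπ(d/2)²`. This is the classic
  region-of-influence model of perceived numerosity: overlapping regions
  of influence reduce the total occupied area, which tracks
  underestimation of clustered patterns.

RW and EG values can exceed 1 on very small graphs (e.g. a single edge has
`T̄ = 1` and RW `= 2 ln 2 ≈ 1.39`); no clamping is applied, and the [0, 1]
range contract covers the seven combinatorial indices only.

### Why TL is normalized by the maximum edge count

The natural per-edge normalization `Σ length / (2d|E|)` makes TL a noisy
measure of *mean relative edge length* at small `d`: with one or two edges
just above `delta` the value jumps between 0 (no edges) and ≈ 0.4, and its
across-pattern standard deviation peaks trivially at the smallest grid
distance. Normalizing by the maximum possible value `2d · n(n-1)/2`
instead makes TL a length-weighted density whose variability peaks near
`d ≈ R` — the scale at which patterns genuinely differ in their long-range
structure, and the behaviour that places TL with the other density-type
indices. The degenerate edgeless case needs no convention (the sum is 0).

### Why EG is gated on connectivity

On a disconnected graph, power iteration settles on the dominant
component's eigenvector: the "average centrality" then measures little
more than the size of whichever component happens to have the largest
leading eigenvalue, and its across-pattern spread is pure
component-bookkeeping noise. Under that reading EG's most-variable
distance lands at the smallest grid distances and the index decouples from
everything else. Treating EG as defined only for connected graphs — the
same gate the cover-time index uses, with the difference that EG cells are
recorded as *missing* rather than zero — makes its most-variable distance
land just below the connectivity threshold and aligns EG with the density
indices, which is both the behaviourally meaningful reading (centrality as
information spread over one connected arrangement) and the one consistent
with the reproduced study tables. RW keeps explicit zeros because those
zeros are part of the index's definition (and of the documented CC–RW
correlation pathology); EG missingness is instead excluded pairwise from
standard deviations and correlations.

## Occupancy: analytic and raster

`occupancy_analytic()` computes the exact union area: for each disk, the
angular intervals of its boundary circle covered by neighbouring disks are
merged, and Green's theorem `A = ½∮(x dy - y dx)` is integrated along the
uncovered arcs. Arcs bounding interior holes are traversed with exactly
the orientation that subtracts the hole, so no special casing is needed;
coincident duplicate points are dropped (their disk adds nothing to the
union). The result is exact to floating-point rounding (validated against
an independent computational-geometry engine to 10⁻⁶ relative error, and
against the two-circle lens formula to 10⁻¹⁰).

`occupancy_raster()` mirrors a screen-capture procedure: disks are
rendered onto a pixel grid (default 1 px, cells counted when their centre
is covered) and the covered-cell area is normalized the same way. It
exists to validate the pipeline against the way occupancy is measured in
practice; the analytic method is the default everywhere else because it
removes resolution as a nuisance parameter. The raster error is bounded by
(union perimeter) × (cell size), so halving the cell size roughly halves
the error. Across generated patterns the two methods correlate above
0.998 for `d ≥ 3δ`; at `d = 2δ` the across-pattern signal is so small
(most disks still disjoint) that 1-px discretization noise pulls the
correlation to ≈ 0.997, and the bound is recovered at a finer raster
resolution. Disks are *not* clipped to the aperture: the aperture confines
dot centres, not regions of influence.

## The sweep and the max-SD selection

`sweep_indices()` evaluates the indices over the grid
`d ∈ {δ, δ+step, ..., 2R}` (step 5 px in the full study, 10 px in the
scaled-down mode). Per-cell failures and EG-missingness are flagged in the
table, never dropped silently. `max_sd_distance()` then selects, per
index, the grid distance `d_m` maximizing the across-pattern *sample*
standard deviation (ties, which have probability zero in practice, break
to the smallest distance). The values of all indices, each taken at its
own `d_m`, form the max-SD dataset: the most informative snapshot of each
index.

Two derived distances matter when interpreting correlations:
`connectivity_threshold()` — the smallest grid distance connecting every
pattern (computed per pattern as the longest edge of the Euclidean minimum
spanning tree), above which CC has zero variance — and
`index_floor_distance()` — the distance at which any index's variance
saturates to zero (the domination number saturates at `γ = 1` by
`d = 3R/2` at every study numerosity). Saturated indices must be excluded
from correlation matrices, and `pearson_with_mask()` enforces this with an
explicit zero-variance error rather than a silent `NA`.

## Correlations and PCA

`pearson_with_mask()` computes Pearson coefficients with two-tailed
p-values from the t-distribution on `n_pair - 2` degrees of freedom
(pairwise-complete where EG is missing) and masks — but keeps — entries
with `p > 0.05`. `pca_varimax()` decomposes the *correlation* matrix of
the max-SD dataset, retains two components by default, and applies varimax
rotation with Kaiser row normalization; each rotated component is oriented
so its largest-magnitude loading is positive, and loadings at or below 0.3
in magnitude are flagged for display suppression (full precision is always
kept). The random-walk index is excluded from the PCA by default: it
correlates with nothing except through the connectivity pathology.

The PCA operates on standardized variables even though the indices are
already normalized: their max-SD standard deviations differ by an order of
magnitude (GC ≈ 0.3 vs TL ≈ 0.02), and a covariance-matrix PCA would
simply rank indices by variance. The reproduced eigenvalue structure
(first eigenvalue ≈ 4.2–4.6 of 10, two components ≈ 66–72% of variance)
only arises on the correlation matrix; a covariance mode is available
behind `use_correlation = FALSE`.

The reproduced structure, stable across numerosities, is two orthogonal
groups: a *clustering* component (OC, DN, IN, CC positively; LC, GC
negatively) living at small `d_m ≈ 0.2–0.4R`, and a *spread* component
(TD, TL, CL, EG) living at `d_m ≈ R` and above. OC loads ≈ 0.9 on the
clustering component — the occupancy model is, to first order, a clustering
measure, and CC is its cheap surrogate.

## Numerical choices

* Edge rule: closed threshold (`distance ≤ d`). The boundary case has
  probability zero for continuous coordinates; the closed rule matches the
  tangency convention of the occupancy model (`d = 2r`).
* Distances in double precision, no spatial indexing: `O(n²)` is
  instantaneous at `n ≤ 40` and removes a dependency.
* Exact domination number: branch-and-bound over 64-bit closed-
  neighbourhood masks, branching on the undominated vertex with the fewest
  candidate dominators, pruned by a greedy upper bound and the counting
  lower bound `⌈undominated / max coverage⌉`. Milliseconds at `n = 40`
  across the whole sweep; `n ≤ 64` by construction.
* RW's "theoretical minimum" is taken as `n ln n` (natural log). Any fixed
  constant rescales RW identically across graphs and cannot affect a
  correlation; the closed-form oracle used in tests is the exact
  coupon-collector mean cover time of the complete graph,
  `(n-1)·H_{n-1}`.
* Cover-time walks are simulated in compiled code under R's RNG, so
  results are bit-reproducible given a seed.
* Interval merging in the occupancy computation uses a `10⁻¹⁴` angular
  tolerance; the raster grid is aligned to integer multiples of the cell
  size.
* Sample (not population) standard deviations throughout.

## Problem sizes and what the tests show

The package's own test suite regenerates the study at reduced sizes chosen
for quick iteration: 200 patterns per numerosity and a 10-px grid step for
the PCA-level checks (the quantities asserted there — max-SD locations,
eigenvalues, loadings — are stable at these sizes), 1000 patterns where
the quantity is a maximum over patterns (the connectivity threshold). The
acceptance script uses the same sizes and recomputes everything from
scratch at a caller-supplied seed.

The synthetic generator emulates exactly the documented stimulus
distribution — uniform positions, hard spacing, circular aperture. It does
not emulate dot size or contrast (the model is location-only), grid-based
or density-yoked generators used elsewhere in the numerosity literature,
or any observer model: passing tests show that the *indices and their
statistical machinery* behave as documented on the stated stimulus
distribution, not that any perceptual claim holds.

## Known limitations

* Two connectivity-linked reference values do not reproduce from the
  documented generator: the distance connecting *all* 1000 patterns at
  `n = 40` lands at ≈ 0.60–0.72R across seeds (reference: 0.56R, which sits
  near the 98–99th percentile, not the maximum, of the per-pattern
  connecting distance), and the CC–RW correlation at `n = 40, d = R/2`
  lands at ≈ −0.65 to −0.73 (reference: −0.816). Both
  depend on the extreme upper tail of the connecting-distance
  distribution, where the regenerated patterns are heavier-tailed than the
  original set; the bulk statistics (max-SD distances, thresholds'
  ordering across `n`, the PCA structure) reproduce well.
* GC's most-variable distance lands at `d ≈ 2–3δ` (a near-binary
  triangle/no-triangle regime at those distances), earlier than its
  reference position next to LC; its clustering-component loading is
  correspondingly weaker in the reproduction.
* The domination solver requires `n ≤ 64`; the exact clique and
  independence solvers are exponential in the worst case but instantaneous
  on geometric graphs at study sizes.
* `d_m` is selected on the discrete grid only; no continuous optimization
  between grid points.
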