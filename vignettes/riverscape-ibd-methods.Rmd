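---
title: "Methods: riverscape isolation by distance, from distance models to parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: riverscape isolation by distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverIBD)
```

## The problem

Species confined to streams experience the landscape as a tree: two
populations a few kilometers apart overland may be hundreds of kilometers
apart along the water, or entirely disconnected if they drain to different
outlets. Under isolation by distance (IBD), genetic differentiation grows
with the distance organisms actually traverse. Comparing how well
alternative geographic distance models explain genetic distances is
therefore a test of *how the species moves*: along rivers only, overland
with terrain resistance, or effectively as the crow flies.

The package implements that comparison — three geographic distance
engines, patristic genetic distances, Mantel permutation tests, one-way
AMOVA over basins, and windowed nucleotide-diversity mapping — together
with a synthetic riverscape generator that provides data with *known*
generating distance, so the full pipeline can be validated by parameter
recovery rather than by eye.

## Distance models

All coordinates are WGS84 lon/lat degrees and all distances meters on a
sphere of radius 6,371,008.8 m (IUGG mean radius; fixed constant for bit
reproducibility).

**Great-circle.** Haversine distance between sample points. By default it
is computed on *snapped* coordinates (samples moved to the nearest river
point) so that all three models see the same set of positions; the
alternative (`euclidean_on = "original"`) is a configuration switch, since
with field-collected coordinates either convention is defensible.

**Altitude least-cost path.** The altitude raster becomes an 8-connected
cell graph. A transition between neighboring cells `i, j` carries a
conductance `c_ij = f(h_i, h_j)`; the default
`f = 1/mean(h_i, h_j)` (altitudes floored at 1 m) makes high terrain
resistant, which is the natural prior for a low-altitude semi-aquatic
disperser. Published analyses of this kind rarely name their transition
function, so it is pluggable (`transition_spec()`); any positive,
altitude-decreasing function preserves the qualitative behavior, and the
monotonicity property (raising a cell never shortens a path) is tested.
Geo-correction divides the conductance by the great-circle distance
between cell centers, so accumulated costs have length units: on flat
terrain of altitude equal to the floor, the least-cost distance reduces
exactly to along-path length. Sample points resolve to the center of their
containing cell; sub-cell offsets are ignored, matching raster-graph
semantics. An 8-connected lattice can elongate straight lines by at most
`1/cos(22.5°) ≈ 1.082`, a bound the tests assert.

**River network.** Arc polylines are converted to a weighted graph (nodes
at arc endpoints, junctions matched within 1e-6°, a documented tolerance
because vector-hydrography dialects vary in coordinate precision). Each
sample is snapped to its nearest point on any arc — nearest computed by
planar projection in a local equirectangular frame centered on the point,
which is accurate to well under a meter at these scales — and inserted as
a graph node by splitting the arc. Entries are shortest-path lengths;
pairs in different connected components (different basins) are missing
data, and stay missing through every downstream statistic.

## Genetic distances

Genetic distance is patristic: the sum of branch lengths between two tips
of a phylogenetic tree. The pipeline accepts any externally inferred tree
as Newick (maximum-likelihood inference is deliberately out of scope); when
none is supplied it builds a neighbor-joining tree from pairwise
p-distances with pairwise deletion of ambiguous sites (`N`, `-`), clamping
negative NJ branch lengths to zero. Pairwise deletion is the default for
nucleotide diversity too: noninvasively collected material is typically
N-rich, and complete deletion can discard most of the alignment. Both
conventions are available (`deletion = "pairwise" | "complete"`) since
published values rarely state which was used.

Haplotype collapsing is strict string identity after uppercasing — gaps
and Ns are ordinary characters. Looser conventions (treating N as a
wildcard) make haplotype counts depend on the comparison order; strictness
is reproducible.

## Inference

**Mantel.** Pearson correlation over valid (jointly non-missing)
off-diagonal pairs; each permutation relabels rows and columns of the
second matrix jointly, missing entries travel with it, and the valid pair
set is recomputed per permutation. The p-value is two-tailed with add-one
smoothing, `p = min(1, 2·min(#[r* ≥ r]+1, #[r* ≤ r]+1)/(n_perm+1))`, whose
floor at 9,999 permutations is 0.0002 — the granularity at which
permutation results of this size are conventionally reported. An
exhaustive mode enumerates all `n!` relabelings for small `n` and is used
as the oracle for the sampled mode.

**AMOVA.** One-way decomposition of squared pairwise distances with basins
as the factor. `σ²_a` is *not* truncated at zero: truncation would break
the exact SSD decomposition and biases small positive structure upward.
Significance comes from permuting group labels (999 by default — a
conventional count; the statistic is cheap, so raising it is free).

**Diversity mapping.** Per sampling point, nucleotide diversity over all
samples within a 10 km great-circle radius (the focal sample included —
"all samples within the radius around the point" naturally includes the
point itself); windows with fewer than two samples are undefined. Values
are interpolated to a ~1 km grid by inverse distance weighting with power
2 (the default of the common geostatistics implementations); a cell within
1 m of a sample returns that sample's value exactly. Per-basin summaries
default to the mean of per-point window values (`mode = "mean_window"`),
with pooled per-basin diversity (`mode = "pooled"`) as the alternative —
the two differ when diversity varies along a basin, and published per-basin
averages do not always state which was used.

## The synthetic riverscape

The generator is a stand-in, not a hydrological model: it reproduces the
*statistical structure* the analysis assumes, with every output a pure
function of its arguments including the seed.

* **Networks** are planar binary trees grown upstream from each outlet: a
  trunk heading north, two children per junction at random angles 30–60°
  off the parent heading, arc lengths decaying by 0.6 per level, so
  headwaters cluster near the divide. Basin outlets sit 0.4° apart along a
  parallel — close enough that the headwaters of adjacent basins
  interdigitate near the shared divide, as real neighboring drainages do.
  That adjacency is the phenomenon of interest: short overland hops across
  the divide correspond to enormous along-river separations.
* **Altitude** is `base + gain × (network distance from the outlet)` at
  each cell's nearest river point (defaults 400 m + 0.04 m/m, giving
  realistic 400–2,300 m relief at these network sizes), plus a 500 m
  Gaussian ridge midway between adjacent outlets.
* **Samples** are placed length-uniformly over the network, so arc length
  is the sampling measure.
* **Genetic targets.** Pairwise target distances are
  `G_ij = α · geo_ij · ε_ij` with `ε` lognormal(0, σ²), symmetrized by
  averaging — multiplicative noise keeps distances positive — and a
  neighbor-joining tree is built from `G`. With `σ = 0` and additive `geo`
  the construction is exact: patristic distances equal `α·geo`.
* **Sequences** evolve site-independently down that tree under HKY, using
  exact transition probabilities from the spectral decomposition of the
  rate matrix (scaled to one expected substitution per site per unit
  branch length) — no Gillespie simulation, so long branches cost nothing
  and the per-branch distribution is exact.

Defaults (2 basins, depth 4, 40 samples, α = 1e-6 substitutions/site per
meter, σ = 0.2, L = 1,066 bp, κ = 2, equal base frequencies) mirror the
scale of a regional mtDNA study: within-basin river distances up to tens
of kilometers yield p-distances of a few percent, comfortably above the
binomial noise floor of a 1 kb fragment.

One rule needs stating: when divergence is generated from *river*
distance across more than one basin, the generative matrix must be
complete, but river distance between basins is undefined. The generator
completes those pairs as *own outlet + great-circle between outlets +
other outlet* — basins joined at the sea. This is purely generative; the
analysis side still treats cross-basin river pairs as missing.

What the generator does **not** emulate: real drainage geometry (no
meanders, no flow accumulation), coalescent genealogies with migration,
recombination, selection, sampling biased toward accessible sites, or
sequencing error. Passing the recovery test therefore shows the *pipeline*
can discriminate distance models under clean IBD — not that any particular
empirical dataset will.

## Numerical choices and degenerate inputs

* Junction matching 1e-6°; snapped nodes inserted by arc splitting.
* NJ ties and negative branches: delegated to the standard NJ
  implementation, negatives clamped to 0 afterward; output is
  bit-reproducible across runs.
* Mantel refuses matrices with zero variance among valid pairs (r is
  undefined) — this happens honestly, e.g. when the IBD slope is zero and
  all sequences coincide.
* Shortest-path matrices are symmetrized by averaging with their
  transpose to absorb float asymmetry of the search, and validated
  (symmetric, zero diagonal, non-negative) on construction.
* Least-cost endpoints in the same raster cell give exactly 0.
* One global seed is split per stage (network, placement, tree, sequences,
  each Mantel, AMOVA), so changing the permutation count of one stage
  never perturbs another.

## Problem sizes in the shipped tests

The test suite validates engines on 5–12 taxa matrices against exhaustive
oracles, least-cost paths on rasters up to 10×10 cells against brute-force
Dijkstra, p-value uniformity on 500 null replicates at 99 permutations,
and the headline recovery contrast on 20 seeds × 40 samples × 1,066 bp in
each generating direction with 49 permutations per Mantel test (the
contrast uses r, not p). These sizes were chosen so the whole suite runs
in about a minute on one core while keeping every Monte-Carlo check at 3
standard errors or better; the same functions scale to hundreds of samples
and national-scale rasters, where the Mantel permutation count (9,999)
dominates runtime.

## Known limitations

* Projected CRSs are not supported; everything is spherical lon/lat.
  At continental latitudes the equirectangular snapping frame is exact to
  centimeters over the few-kilometer offsets involved.
* The least-cost engine resolves endpoints to cell centers, so distances
  between nearby points quantize at the cell size.
* The river engine requires the network to be topologically clean at the
  stated tolerance; no automatic gap-bridging is attempted.
* AMOVA is one-way only (basins); hierarchical designs and partial Mantel
  tests are out of scope.
* The Mantel test's validity under strong autocorrelation of both
  matrices is the subject of a long methodological debate; the package
  implements the conventional test and leaves the epistemics to the user.
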