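---
title: "Measuring the extent and equality of protected-area networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the extent and equality of protected-area networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equirep)
```

## The problem and the model

A protected-area network can cover a large fraction of a territory and still
leave whole classes of natural conditions unrepresented: parks concentrated on
high mountains protect a lot of *area* but only a narrow slice of the
territory's climatic, topographic and edaphic variety. `equirep` quantifies
the two dimensions separately:

* **Protection extent** — the percentage of a territory's land inside strict
  protected areas (IUCN categories I–IV analogues).
* **Protection equality (G′)** — how evenly that protection is spread across
  natural conditions.

Natural conditions are described in two complementary ways: *physically*, by
binning each of five continuous gradients (temperature, precipitation,
elevation, terrain slope, soil fertility) into `n = 10` classes and computing
the per-bin protection percentage

\[
\mathrm{PEx}_{ij} = 100 \cdot \frac{\text{protected area in bin } j \text{ of
variable } i}{\text{land area in bin } j},
\]

and *biogeographically*, by the same percentage per ecoregion. Equality is one
minus the Gini coefficient of the PEx vector. With values sorted ascending and
\(j\) the rank,

\[
G_i = \frac{2}{n}\,\frac{\sum_j j\,\mathrm{PEx}_{ij}}{\sum_j \mathrm{PEx}_{ij}}
      - \frac{n+1}{n}, \qquad G_i' = 1 - G_i .
\]

This rank form is algebraically identical to the mean-absolute-difference form
\(\sum_{a,b}|x_a-x_b| / (2n^2\bar x)\); the test suite asserts the equivalence
to `1e-12` on random vectors. A constant positive PEx vector gives \(G' = 1\)
regardless of its level — equality measures evenness, not amount. Two
boundary conventions deserve note:

* When all protection sits in a single bin the formula gives \(G' = 1/n\)
  (0.1 for ten bins), not 0. The informal description of this case as "equality
  zero" is only the \(n \to \infty\) limit; `equirep` follows the formula and
  the acceptance tests assert 0.1 exactly.
* An all-zero PEx vector raises an error instead of returning a value: "no
  protection at all" and "maximally unequal protection" are different findings
  and must not be conflated downstream.

A territory-level G′ is the mean of the per-variable \(G_i'\) after
*collinearity pruning*: a single left-to-right pass over the variables in
their fixed order drops the earlier variable of any consecutive active pair
with \(|\tau| > 0.55\) (Kendall's tau-b). The pass is deterministic and every
decision is recorded in a report; an iterative variant that re-scans until
stable is available behind `iterative = TRUE`. Variables that are constant
within a territory are degenerate gradients (their histogram and tau are both
undefined) and are set aside up front, recorded in the same report.

## Binning

Histograms have a fixed number of bins (default 10) with equal widths between
the area-weighted 2.5% and 97.5% quantiles of the variable; the outer edges
are then extended to the data minimum and maximum, so tail observations are
*grouped* into the first and last bins, never discarded. Bin intervals are
half-open \([lo, hi)\) with the last closed. The weighted quantile generalises
the type-7 rule (linear interpolation between order statistics): sorted values
\(x_{(k)}\) with weights \(w_{(k)}\) sit at plotting positions
\((C_k - w_k)/(S - w_k)\), which reduces exactly to type 7 under equal
weights; positions are forced non-decreasing before interpolation. Note that
the *edges* are therefore not exactly invariant to splitting a cell into two
half-area copies (the histogram masses, and PEx under fixed edges, are —
that invariance is tested). Whether the trimming should weight cells by area
or count them equally is ambiguous in the field; both are supported and
area-weighting is the default, since the sampling unit is an area.

As a robustness alternative the Sturges rule (`ceiling(1 + log2(N))` bins,
same trimming) is available; an acceptance test checks that territory rankings
by G′ are strongly concordant between the two binnings on a synthetic
ensemble (Kendall \(\tau \ge 0.7\)).

Empty interior bins carry PEx = 0 and are *included* in the equality
computation: an environmental condition with no protected representation is
maximal inequality, which is exactly what the index should register. They are
flagged in the histogram output for transparency.

## The grid and the geometry engine

All statistics run on a regular lon/lat lattice (0.1° cells by default) with
geodesic cell areas from an authalic-sphere approximation (cell area ∝
cos(latitude); R = 6371.0088 km). Protected-area vectors are reduced to
per-cell, per-territory protected km² by a latitude-scanline integrator: at a
fixed latitude the union of polygons and circles is a union of longitude
intervals whose length is exact, and the latitude integral is evaluated by
Gauss–Legendre quadrature between geometry breakpoints. Consequences of this
design:

* unions never double-count overlapping units (dissolving is implicit);
* axis-aligned geometry (the synthetic networks) integrates essentially
  exactly; circles carry a relative area error around \(10^{-5}\), far below
  the 1% buffering tolerance and the 0.5% area-conservation check;
* quadrature pieces narrower than 1e-9 degrees are dropped and gridded areas
  below 1e-9 km² suppressed, so geometry aligned on cell boundaries
  contributes exact zeros to neighbouring cells (floating-point slivers would
  otherwise break exactness tests);
* geometry features narrower than ~1e-7 degrees are below the engine's
  resolution guarantees.

Ingest rules mirror the standard protected-area workflow: only strict
categories are analysed (with an optional recode map applied first, for
national re-categorisations); point records become circles of area equal to
their reported extent and are discarded if they intersect an existing
*polygon* (the rule is deliberately not applied point-vs-point — the literal
reading of the source rule); records with missing establishment years are
included in every cumulative snapshot by default (`"exclude"` is available).
Cells shared by two territories attribute protection to each territory's own
share. Partial-sea cells weight histograms by their land share only
(`land_frac`), the package's resolution of an ambiguity in the field's
practice.

## Priority mapping

The per-cell conservation priority is the mean shortfall from complete
protection over the m retained variables,

\[
\mathrm{Pr}_k = \frac{1}{m} \sum_{i=1}^{m} (100 - \mathrm{PEx}_i),
\]

where \(\mathrm{PEx}_i\) is the protection of the bin cell \(k\) occupies
along variable \(i\). Scores are classified into quartiles or deciles of equal
cell count (±1), ties broken by cell id so maps are reproducible; an all-equal
score vector is classified anyway and flagged degenerate. National maps use
territory-scope histograms; continental maps recompute histograms and pruning
over the whole extent as one unit, which is why a condition that is ordinary
inside one country but rare continentally can rank much higher on the
continental map. Pruning is recomputed per scope rather than inherited from
the equality analysis.

## Drivers of placement

Protection placement is related to five human factors (tourism attractiveness,
distance to frontiers, population, distance to roads, cropland suitability)
with a regression random forest: response = per-cell protected fraction
(continuous; a binary presence mode is available behind `response =
"binary"`), ntree = 500, nodesize = 1, and mtry chosen to minimise the
out-of-bag MSE (ties to the smallest candidate). Variable importance is the
OOB permutation increase in MSE, computed per tree and averaged. Because no
random-forest implementation ships with this environment, the forest is
implemented in compiled code inside the package (exhaustive CART splits,
bootstrap per tree, R's RNG throughout for reproducibility).

Uncertainty comes from bootstrapping the cells 1000 times (reducible) and
refitting; reported VI is normalised to sum to 100 within a territory —
published driver tables have exactly this row structure — with the raw MSE
increases kept alongside. Two estimator properties matter for interpretation:

* With nodesize 1 a tree memorises its in-bag cells, and a bootstrap
  duplicate of an OOB cell lets the tree "look up" its twin. Permutation then
  breaks the lookup, so *all* variables carry a small positive importance
  offset even when the response is pure noise (measured directly in the test
  suite). VI is therefore interpretable as a *ranking* and relative share,
  not as an absolute effect size — which matches its explanatory, not
  predictive, purpose here.
* A predictor duplicating another shares importance with it rather than
  doubling; the suite asserts that both copies stay above the noise floor.

## The synthetic world

`generate_landscape()` produces smooth autocorrelated fields (white noise
smoothed by an edge-renormalised Gaussian kernel, plus a linear large-scale
trend per variable) over the lattice, Voronoi territories and finer Voronoi
ecoregions from random seed cells, and geodesic cell areas. Nonnegative
quantities are shifted, not clamped, so no artificial constant plateaus arise;
population is log-normal (exponentiated smooth field); distance-to-frontiers
is the actual distance to the extent edge plus noise. Everything is a pure
function of `(spec, seed)` and the defaults are chosen to be realistic for a
subtropical study region (e.g., a 15 °C meridional temperature trend with
1.5 °C local noise over a 5-cell correlation length).

`generate_protected_network()` plants protection with known structure and
emits the ground truth alongside:

* `"uniform"` — the idealised completely balanced network: every cell holds
  the same protected fraction of its area as a centred sub-rectangle, so each
  bin's PEx equals the target fraction by construction. This is the
  benchmark network against which the equality index's maximum is defined,
  and it is what the 10⁴-cell acceptance check uses.
* `"single_bin"` — all protection inside cells of one bin of one variable;
  the planted G′ on that variable is exactly 1/n.
* `"biased"` — cells sampled without replacement with log-odds weight
  `-bias_strength` per standard deviation of the *rank* of a driver variable.
  Acting on ranks makes the planted bias transform-invariant, exactly like
  the rank-based splits of the forest that must recover it; `bias_strength =
  0` is unbiased random placement (the noisy counterpart of `"uniform"`).

A configurable fraction of units (default 5%) are emitted as point-plus-extent
records to exercise the buffering path, and a `nonstrict_fraction` adds
excluded-category decoys to exercise filtering. Establishment years follow a
configurable distribution over decades (default uniform 1930–2010, capped at
2016), which drives the decadal trajectory analysis: per cutoff year the
cumulative network's extent and mean G′, plus the decade-to-decade efficiency
\(\Delta G' / \Delta \mathrm{extent}\) (undefined when the network did not
grow).

What the generator does **not** emulate: coastlines and partial-sea cells
(all land), real climate physics or cross-variable dependence structures,
WDPA-style attribute noise, or polygon shapes more intricate than cell-aligned
blocks and circles. A green test therefore establishes the correctness of the
*method* on a known world, not the realism of any particular continental
number; the published real-data figures require the real databases and are
out of scope.

## Numerical and design choices, collected

* Quantile rule: weighted type-7 generalisation, documented above, fixed for
  bit-reproducibility.
* Bin assignment: half-open intervals, last closed; values clamped to the
  edge range (tails were grouped by construction).
* Pruning: single pass, earlier variable dropped, fixed variable order;
  `iterative` flag for the re-scanning variant.
* Quantile classes: ties broken by cell id; class 1 = lowest priority.
* Missing establishment year: included in all snapshots by default.
* Buffering exclusion: against polygons only.
* RF: mtry ties to the smallest candidate; bootstrap resamples at full size
  with replacement; the RNG seed fixes the whole computation.
* Raster interfaces use the plain-text ESRI ASCII grid; vector interfaces use
  GeoJSON. (No binary geospatial formats are read or written.)
* Kendall's tau is the tie-corrected tau-b of `stats::cor`.

## Known limitations

* The scanline engine targets analysis-grid workloads: very large vector
  datasets (10⁵+ vertices per scan row) would be slow in pure R.
* Holes in polygons are supported through the even-odd rule, but
  self-intersecting rings are not validated.
* The weighted-quantile trimming is one of several defensible conventions;
  switching conventions moves bin edges by a fraction of a cell's worth of
  area and leaves G′ rankings intact (the Sturges concordance test bounds the
  sensitivity to a much larger binning change).
* Permutation VI carries the positive offset discussed above; compare ranks,
  not magnitudes, across studies.
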