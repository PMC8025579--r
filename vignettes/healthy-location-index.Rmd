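---
title: "The healthy location index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The healthy location index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hli)
```

## The index

Many features of the residential environment plausibly push health in
opposite directions: green and blue space, physical-activity facilities,
supermarkets and fruit/vegetable outlets are *health-promoting* ("goods"),
while fast-food, takeaway, dairy/convenience, alcohol and gaming outlets are
*health-constraining* ("bads").  Because goods and bads co-occur in space —
both concentrate where people and shops concentrate — studying them one at a
time misstates the environment a population actually lives in.  The healthy
location index summarises both sides at once for small census areas
("meshblocks", around 60–120 residents).

The construction is deliberately rank-based and unweighted:

1. **Access per domain.** For the eight point domains, the road-network
   distance (km) from the meshblock's population-weighted centroid to the
   nearest facility.  For green and blue space — area phenomena without a
   meaningful entrance point — the median, over the meshblock's 50 m raster
   cells, of the Euclidean distance to the nearest covered cell.
2. **Ranks.** Each domain's distances are ranked 1..N (1 = closest), ties
   broken by meshblock id so ranks are an exact permutation.
3. **Composites.** The five goods ranks are summed and the sums re-ranked;
   likewise the five bads.  No domain weights are used: there is no
   unequivocal theoretical basis for any weighting.
4. **Deciles and categories.** Composite ranks map to deciles by
   `ceiling(10 r / N)` (decile 1 = best access), and deciles collapse to
   three categories: 1 = deciles 1–3, 2 = deciles 4–7, 3 = deciles 8–10.
5. **Nine classes.** The goods category crossed with the bads category gives
   the `goods–bads` label.  "1–3" (best goods access, worst bads access) is
   the healthiest class and "3–1" the unhealthiest.  Between the anchored
   extremes, classes are ordered by goods category minus bads category, ties
   by goods category — a package convention for sorting and plotting, not a
   substantive claim.

Because every stage is rank-based, the output is invariant to any strictly
increasing transform of a domain's distances, and all distributional
assumptions are avoided — distances are strongly right-skewed.

```{r quick-tour, eval = FALSE}
region <- generate_region(generator_config(n_meshblocks = 500, seed = 1))
index  <- hli(region)          # access table + full nine-class index
index                          # class counts, healthiest to unhealthiest
summary(index)                 # gradient table, shares, rank correlation
plot(index, by = "dep_quintile")
```

## Distance semantics

Points are snapped to the nearest edge by perpendicular projection (ties:
lexicographically smallest node pair).  Reported network distances are
*access leg + shortest path along the network (edges split at snap offsets)
+ facility access leg*.  Including the access legs prevents zero-cost
teleportation onto the network; an exactly coincident origin–facility pair
short-circuits to 0 km, since no walking is required at all.  If a
user-supplied network leaves some facilities unreachable (disconnected
components), the straight-line distance is used for that cell and flagged
`euclidean_fallback`, so the access table never has missing values.

Raster proximity uses the exact Euclidean distance transform between cell
centres, with cell membership decided by the centre-in-polygon rule.  A
meshblock too small to contain any cell centre receives the value of the
cell holding its centroid.  Green/blue distance is measured to the nearest
covered cell of the merged layer, not per-feature: "distance to the nearest
green space" is the natural reading for access, and per-feature medians
would be dominated by far-away features.

Distances are kept at full precision internally and only rounded for
display.

## The synthetic geography

The generator exists so that every downstream stage — access, index,
socio-spatial summaries — can be tested end-to-end with known ground truth.
It emulates the *structure* of a national small-area analysis at a
compressed, city-like scale:

* **Meshblocks**: convex quadrilaterals on a jittered lattice (default
  300 m pitch), populations uniform on 60–120, centroid = resident-weighted
  mean of simulated dwellings.
* **Deprivation**: a smooth Gaussian-bump field plus a small meshblock-level
  nugget (10% of variance), ranked into equal-count deciles.  Bump centres
  are drawn in a 25%-expanded window so the field is stationary across the
  study area (no systematic boundary artefact).  The nugget reflects the
  strong block-to-block variation real deprivation indices show and keeps
  deciles from forming solid spatial blocks.
* **Road network**: nodes at meshblock centroids, edges between
  lattice-adjacent meshblocks plus a random quarter of diagonals; always a
  single connected component.  Edge length is Euclidean.
* **Facilities**: each meshblock receives `floor(mu)` facilities plus one
  more with probability `frac(mu)`, placed uniformly in its polygon and
  projected onto the nearest road edge (premises face streets).  Intensity
  follows `mu ~ exp(4.5 * strength * (q - 1))`, where `q` is the
  meshblock's deprivation-score quantile: a geometric intensity law (ratio
  roughly 37 between the most and least deprived areas at full strength)
  whose planted gradient is graded between *every* pair of adjacent
  deciles, not only at the extremes.  The full strength applies to the five
  bads, 0.4 of it to supermarkets and physical-activity facilities (some
  goods are also closer in deprived areas), and none to fruit/vegetable
  outlets.  `gradient_strength = 0` makes placement independent of
  deprivation; negative values reverse the gradient.
* **Density**: 1.2 facilities per meshblock per domain by default.  This
  dense, inner-city-like provisioning makes the nearest-facility distance a
  property of the meshblock's own neighbourhood; with sparse facilities the
  distance field is long-range correlated, which both blurs the planted
  gradient and invalidates naive group tests (observations are then far
  from exchangeable).
* **Green/blue cover**: circular green patches and lakes rasterised at
  50 m; all window-boundary cells are marked blue (coastline).
* **Urban/rural**: six classes assigned by quantiles of a settlement
  intensity field, with `urban_fraction` controlling the urban share.

Every layer draws from its own seeded substream, so regenerating with the
same configuration is bit-identical and adding one layer never perturbs
another.

### Design choices that were genuinely open

* Variance-reduced ("balanced") facility allocation was chosen over global
  rejection sampling.  Both realise the same intensity law; the balanced
  form removes Poisson clumping, which otherwise leaves decile medians
  wobbling by a couple of standard errors and obscures the planted
  gradient at realistic sample sizes.
* The jittered-lattice tessellation (with 0.2-cell jitter, keeping every
  quadrilateral convex) stands in for irregular administrative polygons;
  it is space-filling, cheap, and guarantees the centroid-inside-polygon
  invariant.
* Deciles are meshblock-count based, not population-weighted; medians in
  the gradient table are meshblock-weighted.  Both follow the per-area-unit
  reading of the summaries this package reproduces.
* The group-difference test is Kruskal–Wallis (chi-square approximation,
  optional seeded permutation p-value), consistent with the rank-based
  construction and skewed distances.
* Quintiles used in graphical summaries derive from deciles as
  `ceiling(decile / 2)`.

### What the generator does and does not emulate

The synthetic region reproduces the *relational* structure the method needs
— a deprivation gradient in facility access, co-occurring goods and bads,
spatially coherent deprivation, connected road topology — but not the
magnitudes of a national geography: distances here are a few hundred metres
(dense miniature), real national medians are kilometres; real road networks
have hierarchy and dead ends; real green cover is not circular.  Passing
tests therefore demonstrate correctness of the pipeline and recoverability
of planted structure, not calibration to any real country's numbers.

## Numerical choices

* Rank ties break by ascending meshblock id everywhere (stable, total
  order), so each domain's ranks span exactly 1..N.
* Decile formula `ceiling(10 r / N)`: equal counts up to one meshblock,
  endpoints forced to 1 and 10.
* Snapping tolerance 1e-9 m for tie detection; network–oracle agreement is
  asserted to 1e-6 km.
* Degenerate inputs error early and name the offending field or ids:
  all-zero dwelling weights, deciles outside 1..10, empty facility layers,
  rasters with no covered cell, N < 10 for deciles.

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance script run the full pipeline at
n = 2000 meshblocks for gradient analyses, n = 500 for structural and
determinism checks, 100-region ensembles at n = 200 for null calibration
of the group test, and n = 100 for cell-by-cell oracle comparisons —
sizes at which the planted effects are statistically unambiguous while a
complete run stays interactive on one CPU.

## Known limitations

* The nine-class ordering between the anchored extremes is a convention;
  alternative orderings are defensible.
* Count-based deciles weight areas, not people; a population-weighted
  variant would shift decile boundaries in dense regions.
* The median-proximity measure for green/blue space ignores entrances and
  barriers; it is a proximity, not an accessibility, model.
* Road distances start at the population-weighted centroid, not at
  dwellings; within-meshblock heterogeneity is invisible.
* The urban/rural classification is an intensity-quantile stand-in, not an
  official classification.
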