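---
title: "Methods: reserve selection under oil-extraction scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reserve selection under oil-extraction scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservaplan)
```

This vignette documents the model implemented by **reservaplan**, the
meaning and defaults of every parameter, and the rationale behind the
numerical choices. The pipeline follows the standard systematic
conservation planning workflow for a region contested between biodiversity
protection and hydrocarbon concessions: quantify the overlap between
reserves, oil blocks and biodiversity; formulate a minimum-set reserve
selection problem; solve it under different block-exclusion scenarios; and
rank the blocks themselves by conservation importance.

## 1. Data model

All spatial layers are plain R matrices on a shared `grid_spec()` — square
cells of `cell_area` km² (default 1 km²), row 1 at the northern edge, `NA`
as no-data, in an abstract planar CRS with kilometre units. A
`landscape()` bundles:

* a logical **study mask**;
* one **suitability surface** in [0, 1] per species, with a group label
  (amphibian, bird, butterfly, mammal, plant) and a priority
  (endemic/red-listed) flag;
* a categorical **ecosystem map** that partitions the mask;
* four **zone rasters** (protected areas, untouchable areas, operative oil
  blocks, southern/biddable oil blocks), integer ids with a `labels`
  attribute;
* a logical **deforestation** layer and a list of **threat layers**
  (point, line, or field sources).

Rasters travel as single-band ESRI ASCII grids (`.asc`) written with 17
significant digits so that write/read round trips reproduce doubles
exactly; zone layers can also be rasterized from GeoJSON polygon layers by
cell-centre containment (even-odd rule, holes honoured). All I/O is plain
text: the package needs no GIS stack and its outputs diff cleanly.

## 2. Features, richness and overlap statistics

Species presence is the suitability surface thresholded at
`binarize_threshold = 0.5` (a `"continuous"` mode is available for
stacking untruncated model outputs; the thresholded form is the default
because targets and extents are defined in km² of presence). A feature's
**extent** is its presence area; ecosystems contribute their mapped area.

Richness maps are cellwise sums of presences per group
(`stack_richness()`). The **upper tertile** of a richness map flags the
top-diversity third: with `n` positive-richness cells the cut is the
`ceiling(n/3)`-th largest value and all ties at the cut are kept. The cut
is computed over positive cells only by default — with a large empty
fraction, a literal all-cells tertile would include zero-richness cells,
which cannot be "highest diversity". (For the values 1..9 this yields the
cells {7, 8, 9}.) The **richness center** is the intersection of all group
tertiles; `center_vulnerability()` reports the share of it inside
compromised land (blocks and deforestation) and inside protected zones.

Overlap accounting (`table1()`, `table2()`, `ecosystem_coverage()`) is
exact at grid resolution: areas are in-mask cell counts times the cell
area, and percentages are rounded to the precision such gap analyses print
(integers by default).

## 3. Conservation targets

Each feature's target is a fraction of its extent, interpolated linearly
from `t_max = 0.9` (ranges below 10,000 km² for species, 100 km² for
ecosystems) down to `t_min = 0.1` (above 75,000 km² / 10,000 km²), then
multiplied by a scenario factor `scale = 0.4` — yielding the 36–4% targets
that remain achievable at regional scale:

```{r targets}
sch <- target_scheme()
100 * target_fraction(c(5000, 42500, 100000), "species", sch)
```

`halve_targets()` halves the already-scaled scheme (18–2%), used to re-run
scenarios with more modest goals. Targets are seeded with the feature
amounts already inside locked-in (protected) planning units. Features keep
their full mapped extents when targets are computed — the target is a
property of the feature, not of what a scenario leaves selectable.

## 4. Environmental-risk surface and costs

Seven threats (population, agriculture, mining, oil wells, dams, roads,
airports) each produce a footprint in [0, 1]: point and line sources decay
with distance (linear `1 - d/r` by default; exponential available) and
combine by cellwise maximum; density fields pass through rescaled to
[0, 1]. The **ERS** is the weighted mean of the footprints scaled to
0–100. Defaults — equal weights, radii of 2 km (roads, mining), 1 km
(wells), 5 km (dams, airports) — are declared stand-ins exposed in
configuration, not estimated values, and are recorded as such in every run
manifest.

Cells strictly above the exclusion threshold (default 32 on the 0–100
scale) are **highly impacted**; a planning unit whose member cells are
majority-impacted is locked out. PU cost is the mean ERS over member
cells, floored at 0.01 so pristine PUs still carry cost (a zero-cost PU
would make the minimum-set objective degenerate).

## 5. The selection problem and solver

`tessellate()` divides the grid into square PUs of nominal `pu_area`
(default 3.45 km², the regional unit size), keeping clipped edge fragments
and recording rook adjacency with shared boundary lengths. Lock rules per
scenario: protected zones are locked in everywhere (taking precedence over
exclusions, because existing reserves are part of every solution even
where they overlap blocks); blocks are locked out in scenario 1 (all) and
scenario 2 (operative only); scenario 3 excludes no blocks. A PU is
"inside" a zone when more than half its in-mask cells are.

The objective is total selected cost plus, per unmet feature,
`spf * C * shortfall / target` (plus `blm` times the exterior boundary;
`blm = 0` by default). Normalizing by the target keeps small-range
features from being drowned out. The cost-scale constant `C` is the mean
available-PU cost times the estimated number of PUs a full solution needs
(total target area / mean PU area); with the default `spf = 10`, leaving
one feature entirely unmet costs roughly ten times a plausible whole
solution, so shortfalls are only tolerated when targets are genuinely
unreachable.

The annealer (`anneal()`, Rcpp core with its own deterministic
Mersenne-Twister uniform generator so results are identical across
platforms) starts from a seeded random subset, mixes single-PU flips with
selected↔unselected **swap proposals** (30%), cools geometrically from a
temperature set by sampling proposal deltas, and finishes with a greedy
polish of flips and one-for-one exchanges. Swap moves matter: at low
temperature a remove-then-add path across the penalty barrier between two
near-feasible sets is effectively frozen, and flip-only chains stall in
poor local minima. Each call is additionally a best-of-`restarts` run
(default 4) keeping the lowest objective — a cheap guard against the
remaining multi-exchange minima. On 15-PU instances the annealer matches
an exhaustive oracle (`brute_force_optimum()`, pure R, independent of the
compiled path) in ≥95% of seeded runs; the test suite enforces this.

`summed_solution()` repeats the annealer (default `n_reps = 100`, seeds
`base_seed + k`) and counts selection frequencies; PUs at or above
`priority_threshold = 75` form the **priority areas**. The headline
achievement of a scenario is reported from the **best** (lowest-objective)
replicate — the network the scenario actually proposes — because on
dispersed landscapes the frequency core can miss targets that every
individual replicate meets; the priority-area achievement is also reported
(`achievement_priority`), and priority areas drive the spatial outputs and
the southern-block overlap statistic.

## 6. Oil-block importance

For every block: species diversity (mean of min-max-normalized zonal means
of total and priority-species richness, equal weights), ecosystem count,
land preservation (non-deforested fraction), and conservation overlap
(fraction inside priority areas or protected zones). Each metric is scored
into quartiles by nearest rank — a block scores 1 plus the number of
quartile cuts it strictly exceeds, so ties share the lower score — and the
**importance index** is the sum, between 4 and 16.

## 7. Synthetic landscapes

`generate_landscape()` produces seeded landscapes with the statistical
structure the pipeline assumes: smooth anisotropic Gaussian suitability
bumps whose thresholded extents are tuned (within ~10%) to a log-uniform
range-size spectrum, placed with a north-biased density so a richness
centre exists by construction; a Voronoi ecosystem partition;
non-overlapping rectangular reserves and oil blocks (southern blocks
confined to the southern half, every block under the 2,000 km² concession
cap); point/line/field threat sources; and deforestation concentrated near
roads and wells. Every layer draws from its own hashed sub-stream, so
adding a layer never perturbs the others, and generation is fully
deterministic in the seed.

`make_paper_mimic()` instead builds the zone layout by direct cell-count
construction so the regional headline proportions (blocks ≈ 68% of the
study area, protected zones ≈ 22%, ≈ 29% of protected zones inside blocks)
hold within a few percentage points for any seed, with species hotspots
inside the operative band and a quarter of each group confined to the
southern blocks. These generators are structural caricatures, not
ecological models: ranges are unimodal, ecosystems are convex, threats are
simple kernels. They exist to make every pipeline property testable
without external geodata, including the characteristic scenario result —
achievement non-decreasing from scenario 1 to 3, and southern-confined
species unmet exactly when southern blocks are excluded.

## 8. Reproducibility

`run_pipeline()` is deterministic given a `run_config()`: replicate *k* of
scenario *s* uses seed `seed + 1000 s + k`, and all compiled randomness
uses the package's own generator. With `out_dir` set, every table, raster
and parameter (including the declared-default SPF, iteration count and ERS
weights) lands in a JSON manifest alongside the outputs. Default problem
sizes in examples and tests are deliberately small (10⁴–10⁵ proposals,
tens of replicates); production-scale analyses of ~30,000 PUs and
hundreds of features are the same code with larger `n_iter` and `n_reps`.
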