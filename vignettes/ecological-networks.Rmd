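---
title: "Building ecological networks with econetr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building ecological networks with econetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(econetr)
```

`econetr` chains six analysis stages — morphological segmentation,
connectivity screening, resistance modelling, corridor extraction, node
extraction and structural evaluation — plus a Markov–cellular-automaton
land-cover projector and a synthetic-landscape generator. This vignette is
the package's own account of the science in each stage: the model, its
assumptions, the parameters that matter, and the places where the design
was genuinely open and a choice had to be made.

## The raster substrate

Every layer is an `eco_grid`: a numeric matrix with a cell size in metres,
an origin at the outer corner of the top-left (northmost) cell and `NA`
for nodata. All layers entering a pipeline run must agree in shape, cell
size and origin; `align_stack()` snaps sub-half-cell origin jitter to the
first layer and refuses anything larger rather than resampling silently —
a deliberate guard, because silent resampling of categorical rasters
manufactures cells that never existed. I/O is the Esri ASCII grid dialect,
chosen because it is plain text, diff-able and round-trips bit-exactly;
the coordinate system is carried as an uninterpreted label (no geodesy is
performed, consistent with working in a single projected frame).

## MSPA segmentation

The binary foreground (by default the habitat classes paddy field,
woodland, grassland, water area and bottomland) is partitioned into the
seven morphological classes. The decision sequence is:

* **core**: foreground farther than the edge width `w` (default 1 cell)
  from background, with the area beyond the map edge treated as
  background. Erosion uses the Chebyshev (8-neighbourhood chamfer)
  distance rather than exact Euclidean: it is deterministic, standard in
  raster MSPA practice, and lets the test oracle state each cell's class
  by direct distance queries.
* components with no core are **islet** whole;
* non-core cells within `w` of core are boundary: **edge** if the nearby
  background connects to the outside, **perforation** if it is an enclosed
  hole (edge wins when both are within reach — the outer boundary reading);
* remaining connector components are **bridge** (contacting ≥ 2 core
  components), **loop** (the same core at ≥ 2 disjoint contact zones) or
  **branch** (one contact). A connector "contacts" a core of its own
  foreground component when it comes within `w + 1` cells of it: connectors
  are separated from core by a boundary zone at most `w` wide, so `w + 1`
  is the smallest radius that sees through the zone without jumping
  unrelated gaps.

Two published-settings questions were genuinely open. The source workflow
reports foreground connection 4 in its tool settings yet describes an
eight-neighbourhood analysis; `foreground_connectivity` is therefore a
parameter, defaulting to 8 (the stated analysis method and the common
default), and the tests exercise both. The settings "conversion rate 1"
and "opening 1" are display/transition flags of the original GUI tool
with no algorithmic counterpart here; they are not modelled.

Properties enforced by tests: the seven classes exactly partition the
foreground; growing `w` never grows core; classification commutes with
rotation and mirroring; and on grids up to 15×15 the classifier agrees
cell-for-cell with an independent per-cell exhaustive oracle.

## Connectivity screening and source selection

Core components (≥ `min_core_area_cells`, default 4) become patches.
Inter-patch distance is the minimum boundary-cell centre distance minus
one cell size, floored at 0 — a cheap edge-to-edge proxy that is exact for
cardinally adjacent patches and at most half a cell optimistic diagonally.
Patches are linked when the distance is at or below the dispersal
threshold (default 1000 m from a 100–2000 m sweep), and the direct
dispersal probability is negative-exponential, calibrated so that
p = 0.5 exactly at the threshold — the standard way to turn a single
(distance, probability) statement into a kernel.

The indices: LCP sums squared component area fractions; IIC discounts
patch-pair area products by topological link count; PC replaces the link
count with the maximum product of direct probabilities over paths,
computed as a shortest path on −log p weights. The denominator SL defaults
to the summed patch area of the analysis set (so a single connected patch
set scores 1); the full study area may be passed instead — importance
percentages are invariant to the choice, only absolute index values
rescale. Removal importance dΦ holds SL fixed and reports
100·(Φ − Φ₋ₓ)/Φ in percent; the percent convention is what makes the
"dPC > 1" source rule meaningful. Selection is strictly greater than the
bound.

The threshold sweep reports indices and importance summaries per
candidate threshold. How the published study aggregated its sweep table
is not stated, so the sweep reports means and maxima and leaves the final
choice to the user, with an optional heuristic (smallest threshold at
which the top-k dPC ranking stabilises) rather than a hard rule.

## Resistance surface

Four graded layers — MSPA class, land cover, elevation, slope — each map
to coefficients on a 1–100 ladder (defaults as published: e.g. woodland
10, construction land 100, elevation classes 10/20/40/70/90 at
150/300/600/1000 m breaks, slope classes at 5/10/30/45°). Terrain can
instead be classed by 5-class Jenks natural breaks (exact Fisher dynamic
programming, subsampled above 2000 distinct values); the fixed printed
breaks are the default because they are reproducible without the data.
Layers combine by weighted arithmetic mean — the standard reading of a
weighted overlay — clamped to [1, 100]. The default weights
(0.5638, 0.2634, 0.1178, 0.055) sum to 1 and are used as printed.
`ahp_weights()` recovers such weights from a pairwise comparison matrix by
power iteration (tolerance 1e-10) and reports Saaty's consistency ratio,
warning above 0.1.

## Corridors

Cost distance is exact Dijkstra on the 8-connected cell graph with move
cost = mean endpoint resistance × step length (1 or √2 *cell units*), so
cumulative cost is resistance × cells and is invariant in rank to cell
size; geometric length is reported separately in km. The backlink grid is
derived from the Bellman condition and is checked against it in tests.
For every unordered source pair the least-cost path may enter and leave
anywhere on the patches (virtual zero-cost patch vertices). Paths shorter
than 10 km are dropped; paths whose cell overlap is ≥ 90 % of the shorter
path are duplicates and the cheaper survives — the duplication criterion
is an implementation choice (the source workflow says only "duplicated
paths") and both numbers are configuration.

The gravity model uses the closed form G = L²ₘₐₓ ln(aᵢ) ln(aⱼ) / L²ᵢⱼ.
The published equation chain mixes several non-equivalent forms; only
this final form is fully specified, so it is the one implemented. Areas
enter in hectares by default: the logarithm demands areas above one unit,
and hectares keep ln positive for any patch bigger than 100 m². Because
the tier bounds (1/10/100) are only meaningful in the original's
(unstated) units, tiers on synthetic data are configuration-relative;
G is invariant to rescaling the whole resistance surface, which the tests
assert. Tiering: level 1 above 100, level 2 in (10, 100], level 3 in
(1, 10], excluded at or below 1.

## Hydrological nodes

Ridge and valley lines come from D8 flow routing on the resistance
surface. Sinks are filled by an iterative priority-flood with a tiny
epsilon gradient (1e-6 per step) so every interior cell gains a strictly
descending path — this makes D8 directions defined on filled flats and
the fill exactly idempotent, at the cost of raising pits ~1e-6 above
their pour points. Flow direction is steepest drop over step length with
a fixed tie priority (E, SE, S, SW, W, NW, N, NE); accumulation routes
cells in decreasing elevation order and conserves the cell count exactly
(asserted). Valley cells are the top accumulation quantile (default
0.95 — the published workflow never states how lines were thinned from
accumulation, so this is an explicit, configurable choice); ridges are
the same rule on the negated surface.

Node extraction intersects dilated-by-one-cell masks (exact cell-equality
intersections of thin raster lines are brittle): strategic = ridge ×
the maximum-cumulative-cost corridor (the singular reading of "the
maximum cost path"; an option applies the rule to all corridors),
natural = mutual crossings of corridors flagged persistent across dates
(all kept corridors by default in a single-date run), artificial =
valley × roads/rivers/paddy masks. Candidate cells merge into single
points within a 3-cell radius by union-find clustering, which is
order-independent.

## Network structural evaluation

For each subnetwork pairing (level-1 corridors with strategic nodes,
level-2/3 with natural, level-2/3 with artificial, plus the whole
network): α = (L−V+1)/(2V−5), β = L/V, γ = L/(3(V−2)), cost ratio
= 1 − L/C. C is read as the *total* corridor length of the subnetwork:
with the published corridor lengths this reading reproduces the printed
cost ratios after rounding, while a per-corridor reading does not. α and
γ are undefined below V = 3 and are flagged NA, never fabricated.
Reported tables round half away from zero to 2 decimals to match printed
conventions (R's own `round()` is banker's rounding).

## Markov–CA projector

`estimate_transitions()` cross-tabulates aligned date pairs;
`project_demand()` applies the row-stochastic matrix power and rounds by
largest remainder so the projected class counts conserve the cell total
exactly. The spatial allocator replaces the original's back-propagation
neural network with a pluggable suitability interface whose default is a
multinomial logistic model fitted on a seeded subsample (default 1 % of
cells, mirroring the published sampling rate) — the CA contract needs
only a per-class probability surface, and a transparent model keeps the
stage testable. Each iteration scores a random subset of convertible
cells as suitability × neighbourhood density (3×3 window) × class
inertia, where the inertia multiplier rises or falls with the remaining
demand deficit — a documented simplification of the original's
unpublished adaptive-inertia formulas. Conversions stop within 0.5 % of
demand or at 300 iterations; a class-pair convertibility matrix (all
allowed except construction land reverting to water, by default) and a
restricted mask (frozen cells) constrain moves. The total absolute
deficit is non-increasing by construction. Validation uses overall
accuracy and Cohen's kappa.

## The synthetic landscape

The generator emulates the structural features the analysis depends on:
a west-high / east-low terrain (midpoint-displacement relief on a linear
trend; at roughness 0 the surface is exactly the trend), autocorrelated
multi-class land cover obtained by thresholding a rank composite of a
Gaussian-smoothed random field and the terrain (so woodland and grassland
sit high, paddy low), a long narrow river overwritten as water with
bottomland banks, and a central construction-land disc. Defaults —
150×150 cells of 600 m (a 90 km frame), class shares 12 % paddy, 35 % dry
land, 10 % woodland, 8 % grassland, 4 % water, 3 % bottomland, 22 %
construction, 6 % unutilized, smoothing σ = 1.5 cells — were chosen once
as a plausible fragmented metropolitan mosaic whose sources end up tens
of kilometres apart, so the 10 km corridor floor and the gravity tiers
remain meaningful at demonstration scale.

Multi-date series sample each cell's next class *exactly* from the
transition matrix (multinomial counts per source class), and a contiguity
weight λ decides only *which* cells realise each sampled move, preferring
cells whose neighbourhood already holds the target class. This departs
from an alternative design in which λ mixes in the modal neighbour class
directly — that variant biases the realised transition frequencies, and
frequency fidelity is the property the projector's parameter-recovery
test depends on; the rank-based reallocation keeps marginals exact while
still producing patchy change (both properties are under test).

What the generator does **not** emulate: hydrologically consistent
drainage in the DEM, road networks, class-adjacency sociology (e.g.
bottomland only along rivers), or any calibration to a real region's
statistics. Passing tests therefore demonstrate the *algorithms* — the
segmentation rules, index formulas, shortest paths, flow routing,
demand conservation — on data with the right statistical shape, not
predictive skill on real landscapes.

## Problem sizes, determinism and limitations

The shipped tests run the full pipeline on 60×60 demonstration
landscapes, the parameter-recovery check on a 200×200 series, the MSPA
oracle on grids up to 15×15, the exhaustive path oracle on up to 6
patches and the brute-force cost-distance oracle on 6×6 grids — sizes at
which the independent oracles are exact and the suite stays fast. All
randomness flows from explicit integer seeds; a pipeline run is a pure
function of (inputs, configuration incl. seed) and repeated runs emit
byte-identical tables, which the acceptance suite asserts.

Known limitations: no reprojection (single planar frame assumed);
corridor geometry is a cell path, not a buffered swath; circuit-theory
(current-flow) connectivity is out of scope; the gravity tier bounds are
unit-relative; the CA is a transparent simplification, not a reimplementation
of the original neural-network-driven model; and GeoTIFF I/O is not
provided — convert rasters to Esri ASCII grids first.
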