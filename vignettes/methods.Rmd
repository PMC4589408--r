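---
title: "Modelling walking-time access to childbirth care: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling walking-time access to childbirth care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careshed)
```

## The problem

In rural districts with many small health facilities, the planning question
is not "are facilities close enough?" but "can fewer, better-staffed
delivery sites keep most women within an acceptable travel time?" The
operative quantity is *walking time* to the nearest facility offering
delivery care, because terrain — not road distance — dominates access in
mountainous districts, and because a two-hour bound is the conventional
window for reaching basic emergency obstetric care once a complication such
as haemorrhage begins.

`careshed` computes that quantity two independent ways (a raster cost
surface and a virtual mesh network), tabulates the population by
travel-time bands, summarises facility staffing and caseload, and evaluates
reduced-site scenarios. Two engines matter: when two structurally different
models agree on coverage, the result is credibly a property of the
geography rather than of one algorithm's discretization.

## The walking-speed model

Pedestrian speed follows the Naismith–Langmuir rule. On flat ground the
basal pace is 4 km/h, i.e. 15 minutes per horizontal km. For a signed slope
$s$ (rise/run along the direction of travel) the minutes per horizontal km
are

$$
t(s) \;=\; 15 \;+\;
\begin{cases}
0.1 \cdot (1000\,s) & s > 0 \quad\text{(ascent: +0.1 min per m climbed)}\\
-0.03 \cdot |1000\,s| & -12^\circ \le \arctan s < -5^\circ \quad\text{(moderate descent)}\\
+0.03 \cdot |1000\,s| & \arctan s < -12^\circ \quad\text{(steep descent)}\\
0 & \text{otherwise (gentle descent: basal pace)},
\end{cases}
$$

and the speed is $60/t(s)$ km/h. The rule is evaluated *continuously* in
the slope, not by class-midpoint lookup; the published per-class ascending
speeds (2.99, 1.98, …, 0.54 km/h for the 10%-wide classes from 0–10% to
90–100%) serve as a validation oracle, which the continuous evaluation
matches to ≤ 0.02 km/h at every class midpoint.

Two deliberate readings of the rule deserve a note:

* **No speed cap.** At the steep end of the moderate-descent band the rule
  evaluates to speeds up to ~7 km/h (about 1.74 × basal). We do not cap
  this: the literal rule is authoritative, and the published descent-class
  table itself prints 6.16 km/h for one class, which no capped variant
  could produce.
* **Descent column not reproducible.** The published *descending* class
  speeds cannot be reproduced from the stated rule under any midpoint
  convention we tried; they are therefore not used as oracles. Only the
  ascending column is.

Friction multiplies crossing time: a slope-class coefficient (0.98, 1.00,
1.20, 1.04, 1.06, 1.08 for the classes [0,20)% … ≥100%) and a land-use
coefficient by season (dry: open 0.95, bushy 1.00, forest 1.05; wet: 1.00,
1.05, 1.10). The 1.20 coefficient for the 40–60% class breaks the monotone
pattern of its neighbours; it is implemented verbatim as calibrated. Class
membership is left-closed, right-open — a convention that must simply be
fixed for reproducibility. Lakes and swamps are `barrier` land use:
impassable on foot, no finite crossing time.

Vehicular speeds are a flat table by road class: tarmac 75, loose-surface
45, dry-weather 40, motorable 20 km/h; footpaths carry only the pedestrian
basal speed and are not motorable.

## Raster engine

The terrain is a 90 m elevation grid. Per-cell slope uses the standard
Horn 3×3 stencil (masked neighbours fall back on the centre cell; edges are
replicated) and feeds *only* the slope-class friction coefficient. The
anisotropic part — "ascendant or descendant" — uses the signed slope *along
each move*: for adjacent cells the elevation difference divided by the move
distance. This is the only reading that uses both the asymmetric rule and
the slope-class table; it is recorded here because cost-distance tools do
not document their vertical-factor configuration.

Moves connect each cell to 8 neighbours (queen) or, by default, 16 (queen
plus knight moves at √5 × cell size), which reduces the grid-metric
overestimate of Euclidean distance from ≤ 8.2% to ≤ 2.8% on open ground.
Knight moves are blocked when either cell they pass over is a barrier or
masked — otherwise a one-cell lake or river wall would be "jumped", which
no walker can do. Friction coefficients of a move are the arithmetic mean
of the two endpoint cells' coefficients (symmetric, standard for cost
surfaces).

Accumulated times are **exact multi-source shortest-path distances**
(priority-queue Dijkstra in C++), not an iterative scan approximation: the
scan approximation is a tool-era implementation detail, while the intended
semantics — minimum cumulative crossing time over all cell paths — are
exactly what Dijkstra computes. Because the rule is asymmetric, we run the
expansion over the *transposed* move graph, so a cell's value is the time
for a person there to *reach* the nearest facility (the planning-relevant
direction), not the other way round.

Isochrone band $k$ covers times in $((k-1)w, kw]$ with $w = 20$ minutes by
default: a time of exactly 120 minutes is *within* two hours, matching the
"≤ 2 hours" row labels of coverage tables. Unreachable cells and times
beyond the maximum are beyond-range.

## Network engine

Where no digital path network exists, movement is modelled on a virtual
mesh: hexagons subdivided into six equilateral triangles, i.e. a
triangular lattice of nodes at the configured spacing (223 m by default,
so every edge is exactly one side long and never exceeds it). Of the two
readings of a "hexagonal/triangular" mesh, the subdivided-hexagon one
maximizes angular resolution (6 move directions) at bounded edge count.
Node elevations are sampled from the terrain; nodes on barrier cells are
removed with their edges.

The mapped road network is merged in: polylines are densified to ≤ one
side, vertices within 20 m of an existing node (GPS-accuracy order) snap
to it, and other vertices become new nodes tied to up to three surrounding
mesh nodes within one side. Road edges crossing barrier water are *kept* —
a mapped road across water implies a bridge or ferry — while mesh edges
never cross water.

Each edge carries four times: pedestrian forward/reverse from the walking
rule on the edge's signed slope (direction-specific), with the slope-class
coefficient of the edge grade and, for mesh edges, the mean land-use
coefficient of the endpoints; road edges are treated as cleared corridors
(land-use coefficient 1 — a road is a maintained surface regardless of the
vegetation beside it). Vehicular time is symmetric length/speed, present
only on motorable-class road edges.

Facility-to-node mapping is nearest-node with an error beyond one mesh
side (bounded discretization error). Shortest times are again exact
multi-source Dijkstra on the transposed directed graph. **Multimodal**
mode takes, on every edge, the minimum of walking and (where allowed)
riding, with free transfer at shared nodes. This is an optimistic bound —
zero waiting time and vehicle availability on every motorable edge — and
should be read as "travel time if transport were always at hand".
Restricting riding to the four motorized classes is this package's
choice; the footpath class is walk-only.

## Coverage statistics

Raster coverage is an exhaustive per-cell tally: percentage of total
population in cells with time ≤ each band bound. Network coverage
allocates each population cell to its nearest graph node (beyond five mesh
sides, population counts as beyond-range); at mesh resolution this is
equivalent to polygonizing band areas, without the geometry. Population
grids can be rescaled to a census total by one multiplicative factor,
which provably preserves every cell's share (mass-conserving resampling is
used when grids must be aligned — interpolation could invent or lose
people, and coverage percentages must not).

Facility statistics follow the published classing exactly: "first-line"
means dispensaries and health centres (hospitals always excluded);
staffing classes are 0 / 1 / ≥2 skilled birth attendants; caseload classes
are 0–49 / 50–99 / 100–199 / ≥200 / missing, with missing caseloads
excluded from medians, ranges and the under-100 tally. The hospital share
is hospital deliveries over all reported deliveries.

The per-facility tables behind the two worked-example summaries are
supplementary spreadsheets we cannot redistribute;
`reference_facility_table()` therefore ships *synthetic* row sets
constructed to reproduce every published aggregate exactly (class counts,
sums, medians, ranges, hospital totals). Conclusions that depend only on
those aggregates are faithful; the individual rows are not real
facilities.

## Scenario planning

Site selection is greedy maximal coverage: hospitals are locked in, then
the facility adding the most population within the 120-minute threshold
joins the selected set, until a target count or coverage target is
reached; ties break on ascending facility id, so selection is
deterministic and seed-free. The qualitative published criteria — "spatial
aspects and population density" — are operationalized this way because
greedy maximal coverage uses exactly those two signals, is reproducible,
and carries the classical (1 − 1/e) optimality guarantee, which the test
suite verifies against exhaustive search on small fixtures. Selection
optimizes the 2-hour threshold only; 1-hour coverage is reported but not
optimized, mirroring the stated feasibility criterion (≈80% within two
hours).

## The synthetic district

Real district geodata (elevation model, WorldPop raster, digitized roads)
are not shipped; a seeded generator produces districts with the structure
the analysis assumes, and every end-to-end property is tested on the
packaged reference district (default `district_spec()`, seed 42):

* **Terrain**: spectrally filtered Gaussian noise (27 × 27 km at 90 m
  cells, relief amplitude 900 m over a 1100 m base — highlands-to-midlands
  scale), lakes carved below the elevation quantile matching a 3% water
  fraction, land use by elevation terciles (valley floors open, mid-slopes
  bushy, uplands forest).
* **Settlement**: 90 villages on low-slope non-barrier cells with minimum
  spacing, log-normal village sizes, population spread by truncated
  Gaussian kernels (s.d. 1 km) and normalized to 120 000 people — the
  clustered WorldPop look at about half the real districts' population, on
  about a fifteenth of their area.
* **Roads and facilities**: a Euclidean minimum-spanning tree over
  villages plus shortest extra links to a 0.13 km/km² density, classed by
  endpoint importance; 20 delivery facilities (16 dispensaries, 3 health
  centres, 1 hospital at the largest village). First-line caseloads are
  log-normal (meanlog log 50, sdlog 0.85), calibrated *a priori* so
  roughly 70–80% of first-line facilities fall under 100 annual deliveries
  — the range the two real districts bracket (68.6% and 82.7%) — with a
  right-skewed range of ~2–300 matching the published medians (65 and 22)
  and ranges (2–277, 2–117); hospitals absorb a 40% delivery share
  (the real districts: 28% and 68.7%); 5% of caseloads are missing.

What the generator does *not* emulate: real hydrology (lakes are elevation
thresholds), road network topology beyond a connected spanning structure,
within-village settlement texture, and — importantly — the real districts'
facility density. The reference district is considerably *denser* in
facilities than the originals, so its baseline 2-hour coverage (~99%)
exceeds the published ~82–88%, and a 40% site reduction loses almost
nothing rather than ~7 points. Green end-to-end tests therefore establish
that the machinery is correct (engines agree, reductions behave
monotonically, losses stay within the stated bound), not that the
synthetic district reproduces the published coverage percentages — those
require the real geodata, which is out of scope by design.

## Numerical choices and degenerate inputs

* Shortest-path arithmetic is exact double-precision Dijkstra; oracle
  equivalence is asserted to 1e-9 minutes.
* Band boundaries: closed on the right (120.0 min is within 2 h).
* Slope and land-use class boundaries: left-closed, right-open.
* A documented worked value for a level 200 m open-dry mesh edge is
  2.84 min in one source; the defining formula
  (0.2/4 × 60 × 0.95 × 0.98) evaluates to 2.793 min, and the formula
  wins.
* Degenerate inputs fail loudly: 1-cell grids (no slope), all-barrier
  extents (no mesh), facilities on barrier cells (no sources), zero
  population (no coverage), coverage targets above the all-facility
  baseline (infeasible, baseline reported).
* Rasters travel as plain-text ESRI ASCII grids with an EPSG sidecar;
  geographic (degree) CRSs are refused rather than silently reprojected,
  since every computation assumes metric coordinates.

## Known limitations

Travel time ignores waiting, night travel, weather shocks and carrying
load; the multimodal bound is optimistic by construction. The mesh
discretizes direction to six headings (≤ 15.5% path overestimate in the
worst direction, before roads shorten anything); the raster engine's bound
is 2.8% but its slope sampling is cell-scale. Population allocation to
nodes is nearest-neighbour, not area-weighted. The greedy planner
guarantees (1 − 1/e) of optimal coverage, not optimality, and treats
facility capacity as unlimited.
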