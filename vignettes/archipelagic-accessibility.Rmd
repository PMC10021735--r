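---
title: "Measuring healthcare accessibility and equity across an archipelago"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring healthcare accessibility and equity across an archipelago}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(archaccess)
```

## The problem

In archipelagic provinces such as Maluku (Indonesia), a visit to a health
facility is rarely a single drive. Road networks are sparse and frequently
disconnected; many inhabited islands host no hospital and some host no
primary health centre (puskesmas) at all, so part of the population must
combine a land leg, a boat crossing, and a final land leg to reach care.
National referral rules add a further constraint: residents use public
facilities of the district they live in. `archaccess` implements a
reproducible pipeline that quantifies this mixed-mode accessibility and
combines it with health-workforce availability into a per-district equity
index.

The pipeline has six stages:

1. **Dasymetric population allocation.** District census totals are split
   over residential clusters in proportion to cluster footprint area:
   $p_i = P \cdot a_i / \sum_j a_j$. Allocations are kept as reals so the
   district total is conserved exactly; head counts are rounded only when
   printed.
2. **Access classification.** A residence needs a naval leg for facility
   type $k$ when it lies more than 5 km (straight line) from the nearest
   road of its island, or when its island hosts no same-district facility of
   type $k$. Otherwise it is land-connected.
3. **Land routing.** Road segments become a weighted graph (endpoints
   snapped within 1 m); residences and facilities attach by perpendicular
   access links that split the nearest edge. The closest same-district
   facility minimises access link + shortest path + facility link
   (Dijkstra, via igraph). These are route segments A (puskesmas) and B
   (hospital).
4. **Naval routing.** Naval-classified residences travel to their nearest
   admissible water-access point (ports/docks of the island, plus beaches
   within 500 m of the cluster) — segments C/D; cross water to the
   destination facility's hub (its nearest port or dock; beaches cannot be
   hubs) — segments E/F; and continue from hub to facility — segments G/H.
   The water leg is the shortest land-avoiding path, computed on a
   visibility graph over island-polygon corners: it equals the Euclidean
   distance whenever the straight segment stays on water.
5. **Summaries.** Per district: segment statistics (N, mean, SE, median,
   min, max), population shares reaching each facility type by land ($c$,
   $e$) versus by land+naval ($c_{nav}$, $e_{nav}$), route-type mean
   distances ($d$, $f$, $d_{nav}$, $f_{nav}$), and the weighted total
   distance
   $z = c\,d + c_{nav}\,d_{nav} + e\,f + e_{nav}\,f_{nav}$ (km).
6. **Workforce and equity.** Staff are weighted by national staffing
   standards normalised to the nurse standard (2500/855 = 2.92 per
   physician, 1000/855 = 1.17 per midwife, 1 per nurse). District
   availability terms are weighted workers per 1,000 population over
   puskesmas ($x$) and hospitals ($y$), and the equity index is
   $z / \operatorname{mean}(x, y)$ — low is excellent, high is severe. A
   plain two-step floating catchment area (2SFCA) score with a hard 10 km
   Euclidean buffer is computed alongside as a comparator.

## A worked example

The three-island toy region ships with hand-computable distances:

```{r toy}
out <- run_pipeline(toy_fixture())
out$district_summary[, c("district_id", "c", "c_nav", "e", "e_nav",
                         "mean_puskesmas_land", "mean_hospital_naval",
                         "z", "all_routes_mean")]
out$equity[, c("name", "x", "y", "z", "equity", "rank")]
```

District D1's hospital summary mixes a 10 km land route with an 8 km
three-leg naval route (2 km to the dock, a 4 km strait, 2 km of road on the
far side); with half the population in each cluster,
$z = 1 \cdot 3 + 0.5 \cdot 10 + 0.5 \cdot 8 = 12$ km. On island IC the
hospital trip's water leg must round the island's southern corners: 10 km
instead of the 8 km straight line that would cross land.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `road_proximity_km` | 5 | km | straight-line road-distance cut for naval classification |
| `beach_adjacency_km` | 0.5 | km | beaches usable as departure points when this close to a cluster |
| `fca_radius_km` | 10 | km | hard catchment buffer of the 2SFCA comparator |
| `hub_local_km` | 1 | km | hub-to-facility legs at or below this are straight-line, longer ones road-routed |
| `snap_tolerance_km` | 0.001 | km | road endpoint merge tolerance |
| `restrict_district` | `TRUE` | — | within-district referral rule; `FALSE` explores cross-district referral |
| `mean_mode` | `"centroid"` | — | route-type means per centroid, or population-weighted |
| `naval_mode` | `"total"` | — | destination minimises the three-leg total, or greedy per-leg (`"chained"`) |

The 5 km, 500 m and 10 km thresholds are the analysis rules of the study
design this package operationalises; they are configuration keys, never
hard-coded, so sensitivity analyses are one argument away.

## Design decisions in ambiguous territory

Several published conventions underdetermine the arithmetic; the package
fixes them as follows and exposes the alternative where one is defensible.

* **Centroid vs population weighting.** Route-type means are unweighted
  means over residential centroids (consistent with segment-table N counts,
  which count centroids), while access proportions are population-weighted
  (consistent with head-count rows). This split is the only reading
  consistent with both summary-table conventions; `mean_mode =
  "population"` switches the means to population weighting.
* **Equity functional form.** The printed formula ("z, mu, x, y") does not
  pin down an expression. We use $z / \operatorname{mean}(x,y)$, which has
  the stated direction (monotone up in distance, down in availability) and
  km-like scale; the reciprocal reading $z \cdot \operatorname{mean}(1/x,
  1/y)$ is available as `equity_form = "ratio"`. Both give identical
  rankings whenever $x = y$, and rankings — not magnitudes — are the
  reported output.
* **Segment letters.** Two lettering schemes circulate for the route
  decomposition; we adopt the summary-table scheme (A/B land; C/D
  residence-to-dock; E/F water; G/H dock-to-facility).
* **Access links count.** GIS closest-facility tools snap points to the
  network implicitly; we count the perpendicular access links in the route
  distance, since off-road residences can legitimately be up to 5 km from
  the network and dropping the link would under-report their burden.
* **Naval destination choice.** "Nearest dock, then nearest facility dock"
  chains greedy decisions and can be globally suboptimal; the default
  minimises the three-leg total, and `naval_mode = "chained"` reproduces
  the greedy construction for comparison.

## Numerical choices

Distances are planar kilometres; inputs are assumed already projected
(e.g. a UTM zone), and no geodetic computation is performed. Polygons are
single exterior rings; multi-part land masses are separate islands.
Reported distances are rounded half-up to 2 decimals at the reporting layer
only (73.085 prints as 73.09); all internal arithmetic is full precision.
Ties in facility choice break to the smallest facility id, and district
ranking ties break alphabetically — both make reruns byte-identical.
Degenerate inputs fail loudly: zero-area polygons, self-intersecting rings,
zero total cluster area, residences on no island, islands without any
port/dock for an arriving naval route, and districts with no workforce all
raise (or, in the pipeline, log) named errors rather than propagating NaN.
Disconnection in the road graph is a value (`Inf`), not an error.

The water metric treats island polygons as closed obstacles: paths may
touch coastlines (docks sit on them) but never cross interiors; visibility
edges may run along a polygon edge. The visibility graph is exact for the
polygon resolution used; its independent check in the test-suite is a
16-neighbour raster Dijkstra, whose lattice metric overestimates by up to
about 3%, so agreement is asserted within that discretisation bound plus
two cell widths for endpoint snapping.

## What the synthetic generator does and does not emulate

`generate_region()` produces multi-island districts (perturbed-ellipse
islands with a guaranteed 3 km sea gap), island-wise minimum-spanning-tree
road networks connecting a configurable share of residences (default 85%),
facilities with heterogeneous staffing (hospitals concentrated on main
islands), docks at the coastline point nearest each facility, a dock for
every inhabited island and beaches every 5 km of coast. Default study
conditions are three districts of two to four islands, roughly 100
residential clusters per district (about 300 total), three puskesmas and
one hospital per district, and district census totals between 75,000 and
430,000 — sized so some islands lack a puskesmas and most lack a hospital,
reproducing the mixed land/naval access pattern of a real archipelagic
province.

The generator does **not** emulate coastline fractality, bathymetry or
sailing routes, population gravity (clusters are area-uniform within an
island), travel time, cost, weather, or road condition. Tests passing on
synthetic regions therefore validate the pipeline's arithmetic and
invariants — allocation conservation, classification partitions, metric
properties of the water distance, equity monotonicity — not the empirical
accuracy of any real province's accessibility figures, which depend
entirely on the input geodata.

## Problem sizes and limitations

The shipped test-suite and the acceptance script run the full pipeline at
the default scale (3 districts, ~300 residences, ~10 islands), which
completes in well under a minute on a single CPU; the oracle-based checks
use 50-node graphs and a 0.4 km raster. Larger regions scale roughly with
(residences x facilities) for routing and with the square of total island
vertices for the visibility graph.

Known limitations: routes are distances, not times — ferries, speeds,
schedules and topography are out of scope; the within-district rule is a
hard filter (its relaxation is a flag, not a calibrated behavioural
model); water legs assume any two coastal points are navigable if a
land-avoiding path exists; and the equity index's absolute scale is only
meaningful relative to other districts computed under the same
conventions.
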