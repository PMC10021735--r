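# archaccess

Spatial healthcare accessibility and equity for archipelagic regions.

In island provinces, reaching a health facility often means a road leg to a
dock, a boat crossing, and a final leg to the facility — and referral rules
confine patients to facilities of their own district. `archaccess` is an R
package for quantifying that burden and turning it into a district-level
healthcare-equity index. It is aimed at health-geography and health-systems
researchers working with district polygons, island polygons, road
centrelines, residential clusters, coastal access points and staffed
facility registries (GeoJSON/CSV, projected planar coordinates in km).

## What it computes

* **Dasymetric population allocation** — district census totals split over
  residential clusters by footprint area: `p_i = P * a_i / sum(a)`.
* **Access classification** — a cluster needs a naval route to a facility
  type when it lies more than 5 km from its island's nearest road, or its
  island hosts no same-district facility of that type.
* **Routing** — district-restricted closest facilities over the snapped
  road graph (segments A/B), and three-leg land+naval routes
  (residence–dock C/D, dock–dock over water avoiding all land barriers E/F,
  dock–facility G/H). Water distances are shortest land-avoiding paths on a
  visibility graph over island-polygon corners.
* **Summaries** — per-district segment statistics, land/naval population
  shares `c`, `e`, `c_nav`, `e_nav`, route-type means `d`, `f`, `d_nav`,
  `f_nav`, and the weighted total distance
  `z = c·d + c_nav·d_nav + e·f + e_nav·f_nav` (km).
* **Workforce & equity** — staff weighted by national staffing standards
  normalised to the nurse standard (physician 2500/855 = 2.92, midwife
  1000/855 = 1.17, nurse 1); availability `x`, `y` = weighted workers per
  1,000 population over puskesmas/hospitals; equity = `z / mean(x, y)`
  (low is excellent, high is severe), with district ranking.
* **2SFCA comparator** — plain two-step floating catchment area scores with
  a hard 10 km buffer.
* **Synthetic archipelagos** — a seeded generator of valid multi-island
  regions for testing and simulation, plus a hand-computable toy fixture.

## A worked example

```r
library(archaccess)

result <- run_pipeline(toy_fixture())
result
#> <pipeline_result>
#>   3 residences, 2 districts, 12 route segments
#>   best equity: Alpha (equity = 19.91)

result$district_summary[, c("district_id", "c", "e", "e_nav",
                            "mean_puskesmas_land", "mean_hospital_naval", "z")]
#>   district_id c   e e_nav mean_puskesmas_land mean_hospital_naval        z
#> 1          D1 1 0.5   0.5                   3             8.00000 12.00000
#> 2          D2 0 0.0   1.0                  NA            15.47214 20.94427

result$equity[, c("name", "x", "y", "z", "equity", "rank")]
#>    name      x     y        z   equity rank
#> 1 Alpha 0.1794 1.026 12.00000 19.91040    1
#> 2  Beta 0.2086 1.126 20.94427 31.38659    2
```

Reading district D1 ("Alpha"): everyone reaches a puskesmas by land
(`c = 1`, mean 3 km), half the population reaches the hospital by land
(10 km) and half needs the naval route (2 km to the dock + 4 km strait +
2 km road = 8 km), so `z = 1·3 + 0.5·10 + 0.5·8 = 12` km. With puskesmas
availability `x = 0.18` and hospital availability `y = 1.03` weighted
workers per 1,000 residents, the equity value is `12 / mean(x, y) = 19.91`
— better (lower) than district Beta's 31.39, so Alpha ranks first.

Synthetic regions work the same way:

```r
region <- generate_region(generator_config(seed = 1))
out <- run_pipeline(region)
write_pipeline_result(out, "results/")        # CSV tables + run log
write_region(region, "data/region1/")         # GeoJSON/CSV round-trip
```

`maluku_districts()` ships the published district summary of Maluku
Province, Indonesia (2020 census populations, facility staffing, route-type
mean distances) as a worked-example input for the aggregation layer:

```r
tab <- maluku_districts()
round_half_up(province_aggregate(tab$mean_puskesmas_land))
#> [1] 8.89
```

See the vignette (`vignettes/archipelagic-accessibility.Rmd`) for the
model, its assumptions, and the design decisions.

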