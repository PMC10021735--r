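Package: archaccess
Title: Healthcare Accessibility and Equity Analysis for Archipelagic Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating spatial healthcare accessibility in
    archipelagic settings where travel combines road networks and boat
    crossings. Allocates district census totals to residential clusters in
    proportion to settlement area, routes each cluster to its
    district-restricted closest primary health centre (puskesmas) and
    hospital over the road graph, detects clusters that require naval
    travel (far from any road, or on an island without the facility type)
    and routes them residence-to-dock, dock-to-dock over water avoiding
    land barriers, and dock-to-facility. Route legs are decomposed into
    the A-H segment scheme, summarised per district, and combined with a
    staffing-standard-weighted health-workforce score into a district
    healthcare-equity index, alongside a two-step floating catchment area
    (2SFCA) comparator. Includes a seeded synthetic-archipelago generator
    and GeoJSON/CSV readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
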