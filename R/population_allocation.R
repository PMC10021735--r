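# Dasymetric (area-proportional) allocation of district census totals to
# residential clusters.

#' Allocate a district's population to its residential clusters
#'
#' Each cluster receives the district total multiplied by its share of the
#' district's total residential footprint area: population_i =
#' total * area_i / sum(area). Allocations are kept as reals so that they sum
#' to the district total exactly; rounding to head counts happens only at the
#' reporting layer.
#'
#' @param total_population district census total (>= 0).
#' @param areas_km2 positive cluster areas, one per cluster.
#' @return numeric vector of allocated populations, same order as `areas_km2`.
#' @export
allocate_population <- function(total_population, areas_km2) {
  if (length(areas_km2) < 1) stop("at least one cluster is required")
  if (any(areas_km2 <= 0)) stop("all cluster areas must be > 0")
  if (total_population < 0) stop("total_population must be >= 0")
  total_area <- sum(areas_km2)
  if (total_area <= 0) stop("zero total cluster area")
  total_population * areas_km2 / total_area
}

#' Allocate populations for every district of a region
#'
#' Runs [allocate_population()] district by district over the region's
#' residence table and returns the table with the `population` column filled.
#'
#' @param region a `study_region`.
#' @return the region, with `residences$population` populated and an
#'   `area_km2` column added.
#' @export
allocate_region_population <- function(region) {
  res <- region$residences
  res$area_km2 <- vapply(res$polygon, polygon_area, numeric(1))
  res$population <- NA_real_
  for (i in seq_len(nrow(region$districts))) {
    d <- region$districts[i, ]
    idx <- which(res$district_id == d$id)
    if (!length(idx)) next
    res$population[idx] <- allocate_population(d$total_population,
                                               res$area_km2[idx])
  }
  region$residences <- res
  region
}
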