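# Two-step floating catchment area (2SFCA) comparator with fixed-radius
# buffers: travel distance is replaced by straight-line buffer membership.

#' Two-step floating catchment area accessibility
#'
#' Step 1: each facility j of the requested kind gets a supply ratio R_j =
#' supply_j / (summed allocated population of residences whose centroid lies
#' within `radius_km` of j). Step 2: each residence sums the R_j of all
#' facilities within `radius_km` of its centroid. Residences inside no
#' facility buffer are flagged `in_range = FALSE` and their accessibility is
#' `NA` (undefined, not zero): values outside the buffers are not reliable
#' to report. Facilities with an empty catchment have an undefined ratio and
#' are excluded with a warning.
#'
#' Distances are Euclidean between centroids and facility locations --
#' the buffer deliberately stands in for travel distance. Supply is the
#' staffing-standard-weighted workforce by default; `supply = "counts"`
#' counts each facility as one unit instead.
#'
#' @param region a `study_region` with allocated populations.
#' @param facility_kind `"puskesmas"` or `"hospital"`.
#' @param radius_km buffer radius (default 10).
#' @param supply `"workforce"` (default) or `"counts"`.
#' @param weights worker weights for the workforce supply.
#' @return data frame with `residence_id`, `district_id`, `accessibility`
#'   (weighted workers per person), `in_range`.
#' @export
two_step_fca <- function(region, facility_kind, radius_km = 10,
                         supply = c("workforce", "counts"),
                         weights = standard_weights()) {
  supply <- match.arg(supply)
  stopifnot(facility_kind %in% facility_kinds)
  res <- region$residences
  if (any(is.na(res$population))) {
    stop("populations must be allocated before running 2SFCA")
  }
  fac <- region$facilities[region$facilities$kind == facility_kind, ,
                           drop = FALSE]
  if (!nrow(fac)) stop(sprintf("no %s in region", facility_kind))

  supply_j <- if (supply == "workforce") {
    weighted_workforce(fac$physicians, fac$midwives, fac$nurses, weights)
  } else {
    rep(1, nrow(fac))
  }

  # n_res x n_fac centroid-to-facility distances
  dmat <- outer(res$x, fac$x, `-`)^2 + outer(res$y, fac$y, `-`)^2
  in_buffer <- sqrt(dmat) <= radius_km

  catch_pop <- colSums(res$population * in_buffer)
  empty <- catch_pop <= 0
  if (any(empty)) {
    warning(sprintf("excluding %d %s facility(ies) with empty catchment: %s",
                    sum(empty), facility_kind,
                    paste(fac$id[empty], collapse = ", ")))
  }
  ratio <- ifelse(empty, 0, supply_j / pmax(catch_pop, 1e-300))
  usable <- in_buffer[, !empty, drop = FALSE]
  access <- as.numeric(usable %*% ratio[!empty])
  in_range <- rowSums(in_buffer) > 0
  access[!in_range] <- NA_real_
  data.frame(residence_id = res$id, district_id = res$district_id,
             accessibility = access, in_range = in_range)
}
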