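# Study-region container and validation.
#
# A study_region is a list of plain data frames; polygon geometry is carried
# in list-columns of n x 2 coordinate matrices (km, projected). This mirrors
# how the analysis consumes the data: attribute tables with geometry attached,
# one table per entity class.

#' Assemble a study region
#'
#' Bundles the six entity tables the accessibility pipeline consumes. All
#' coordinates are planar, in kilometres; inputs are assumed to be already
#' projected.
#'
#' @param districts data frame with columns `id`, `name`, `total_population`
#'   and a list-column `polygon` of ring matrices.
#' @param islands data frame with `id` and list-column `polygon`.
#' @param residences data frame with `id`, `district_id`, `x`, `y` (area
#'   centroid), `population` (NA until allocated) and list-column `polygon`.
#' @param roads data frame of road segments with columns `x1,y1,x2,y2`.
#' @param water_access data frame with `id`, `kind` (`"port"`, `"dock"` or
#'   `"beach"`), `x`, `y`.
#' @param facilities data frame with `id`, `kind` (`"puskesmas"` or
#'   `"hospital"`), `district_id`, `x`, `y`, `physicians`, `nurses`,
#'   `midwives`.
#' @return an object of class `study_region`.
#' @export
study_region <- function(districts, islands, residences, roads,
                         water_access, facilities) {
  region <- list(
    districts    = districts,
    islands      = islands,
    residences   = residences,
    roads        = roads,
    water_access = water_access,
    facilities   = facilities
  )
  class(region) <- "study_region"
  region
}

#' @export
print.study_region <- function(x, ...) {
  cat("<study_region>\n")
  cat(sprintf("  districts:     %d\n", nrow(x$districts)))
  cat(sprintf("  islands:       %d\n", nrow(x$islands)))
  cat(sprintf("  residences:    %d\n", nrow(x$residences)))
  cat(sprintf("  road segments: %d\n", nrow(x$roads)))
  cat(sprintf("  water access:  %d (%s)\n", nrow(x$water_access),
              paste(names(table(x$water_access$kind)), table(x$water_access$kind),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  facilities:    %d (%s)\n", nrow(x$facilities),
              paste(names(table(x$facilities$kind)), table(x$facilities$kind),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

water_access_kinds <- c("port", "dock", "beach")
facility_kinds <- c("puskesmas", "hospital")

#' Index of the island containing a point, or NA
#'
#' Points on an island boundary count as on the island.
#'
#' @param p length-2 point.
#' @param islands island table of a study region.
#' @param boundary_tol_km boundary tolerance in km.
#' @return integer row index into `islands`, or `NA_integer_`.
#' @export
island_of_point <- function(p, islands, boundary_tol_km = 1e-6) {
  for (i in seq_len(nrow(islands))) {
    poly <- islands$polygon[[i]]
    if (points_in_polygon(p[1], p[2], poly) ||
        point_polygon_distance(p, poly) <= boundary_tol_km) {
      return(i)
    }
  }
  NA_integer_
}

violation <- function(entity, rule, message) {
  data.frame(entity = entity, rule = rule, message = message)
}

#' Validate a study region against the model invariants
#'
#' Checks id uniqueness and referential integrity, polygon simplicity,
#' non-negative populations and staff counts, allowed water-access and
#' facility kinds, residence centroids (must equal the polygon area centroid
#' and lie on some island), facility locations (on some island), water-access
#' points (on or within 0.5 km of an island boundary), island disjointness,
#' and positive road-segment lengths.
#'
#' Violations are reported, not raised: a malformed region yields one row per
#' broken rule.
#'
#' @param region a `study_region`.
#' @return data frame with columns `entity`, `rule`, `message`; zero rows iff
#'   the region is well formed.
#' @export
validate_region <- function(region) {
  v <- list()
  add <- function(x) v[[length(v) + 1]] <<- x

  dup <- function(ids) ids[duplicated(ids)]
  for (tab in c("districts", "islands", "residences", "water_access", "facilities")) {
    d <- unique(dup(region[[tab]]$id))
    if (length(d)) {
      add(violation(paste0(tab, ":", d), "unique_ids",
                    sprintf("duplicated id in %s", tab)))
    }
  }

  for (i in seq_len(nrow(region$districts))) {
    di <- region$districts[i, ]
    if (!polygon_is_simple(di$polygon[[1]])) {
      add(violation(paste0("district:", di$id), "simple_polygon",
                    "district polygon self-intersects"))
    }
    if (is.na(di$total_population) || di$total_population < 0) {
      add(violation(paste0("district:", di$id), "population_nonnegative",
                    "total_population must be >= 0"))
    }
  }

  # islands pairwise interior-disjoint: no vertex of one strictly inside
  # another and no boundary crossing
  isl <- region$islands
  n_isl <- nrow(isl)
  if (n_isl > 1) {
    for (i in seq_len(n_isl - 1)) {
      pi_ <- as_ring(isl$polygon[[i]])
      for (j in (i + 1):n_isl) {
        pj <- as_ring(isl$polygon[[j]])
        overlap <- any(points_in_polygon(pj[, 1], pj[, 2], pi_)) ||
          any(points_in_polygon(pi_[, 1], pi_[, 2], pj))
        if (!overlap) {
          ei <- cbind(pi_, pi_[c(2:nrow(pi_), 1), , drop = FALSE])
          for (k in seq_len(nrow(pj))) {
            a <- pj[k, ]; b <- pj[if (k == nrow(pj)) 1 else k + 1, ]
            if (crosses_any_edge(a, b, ei[, 1], ei[, 2], ei[, 3], ei[, 4])) {
              overlap <- TRUE
              break
            }
          }
        }
        if (overlap) {
          add(violation(paste0("island:", isl$id[i], "+", isl$id[j]),
                        "islands_disjoint", "island interiors overlap"))
        }
      }
    }
  }

  res <- region$residences
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    ent <- paste0("residence:", r$id)
    if (!r$district_id %in% region$districts$id) {
      add(violation(ent, "district_resolves",
                    sprintf("district_id '%s' not found", r$district_id)))
    }
    poly <- r$polygon[[1]]
    if (!polygon_is_simple(poly)) {
      add(violation(ent, "simple_polygon", "residence polygon self-intersects"))
      next
    }
    cen <- polygon_centroid(poly)
    if (sqrt(sum((cen - c(r$x, r$y))^2)) > 1e-6) {
      add(violation(ent, "centroid_matches",
                    "stored centroid differs from polygon area centroid"))
    }
    if (is.na(island_of_point(c(r$x, r$y), region$islands))) {
      add(violation(ent, "centroid_on_island",
                    "residence centroid lies on no island"))
    }
    if (!is.na(r$population) && r$population < 0) {
      add(violation(ent, "population_nonnegative", "population must be >= 0"))
    }
  }

  wap <- region$water_access
  bad_kind <- !wap$kind %in% water_access_kinds
  for (i in which(bad_kind)) {
    add(violation(paste0("water_access:", wap$id[i]), "kind_allowed",
                  sprintf("kind '%s' not one of port/dock/beach", wap$kind[i])))
  }
  for (i in which(!bad_kind)) {
    p <- c(wap$x[i], wap$y[i])
    d_bound <- min(vapply(region$islands$polygon, function(poly) {
      ring <- as_ring(poly)
      n <- nrow(ring)
      closed <- rbind(ring, ring[1, ])
      min(point_segment_distance(p[1], p[2],
                                 closed[seq_len(n), 1], closed[seq_len(n), 2],
                                 closed[seq_len(n) + 1, 1], closed[seq_len(n) + 1, 2]))
    }, numeric(1)))
    if (d_bound > 0.5) {
      add(violation(paste0("water_access:", wap$id[i]), "on_coast",
                    "water-access point farther than 0.5 km from every island boundary"))
    }
  }

  fac <- region$facilities
  for (i in seq_len(nrow(fac))) {
    f <- fac[i, ]
    ent <- paste0("facility:", f$id)
    if (!f$kind %in% facility_kinds) {
      add(violation(ent, "kind_allowed",
                    sprintf("kind '%s' not one of puskesmas/hospital", f$kind)))
    }
    if (!f$district_id %in% region$districts$id) {
      add(violation(ent, "district_resolves",
                    sprintf("district_id '%s' not found", f$district_id)))
    }
    if (is.na(island_of_point(c(f$x, f$y), region$islands))) {
      add(violation(ent, "on_island", "facility located on no island (open water)"))
    }
    for (col in c("physicians", "nurses", "midwives")) {
      if (is.na(f[[col]]) || f[[col]] < 0) {
        add(violation(ent, "staff_nonnegative",
                      sprintf("%s must be a non-negative count", col)))
      }
    }
  }

  roads <- region$roads
  if (nrow(roads)) {
    len <- sqrt((roads$x2 - roads$x1)^2 + (roads$y2 - roads$y1)^2)
    for (i in which(len <= 0)) {
      add(violation(sprintf("road:%d", i), "positive_length",
                    "road segment has zero length"))
    }
  }

  if (length(v)) do.call(rbind, v) else violation(character(), character(), character())
}
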