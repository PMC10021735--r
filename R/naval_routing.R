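# Water-borne routing: water-access assignment, facility dock hubs, shortest
# water distance avoiding land barriers (visibility graph over island-polygon
# vertices), and assembly of combined land+naval routes (segments C-H).

point_strictly_inside <- function(p, polygon, tol = 1e-9) {
  if (!points_in_polygon(p[1], p[2], polygon)) return(FALSE)
  ring <- as_ring(polygon)
  n <- nrow(ring)
  closed <- rbind(ring, ring[1, ])
  d <- min(point_segment_distance(p[1], p[2],
                                  closed[seq_len(n), 1], closed[seq_len(n), 2],
                                  closed[seq_len(n) + 1, 1], closed[seq_len(n) + 1, 2]))
  d > tol
}

# is the open segment p-q free of land? touching boundaries is allowed,
# crossing interiors is not
segment_over_water <- function(p, q, islands, edge_mat) {
  if (crosses_any_edge(p, q, edge_mat[, 1], edge_mat[, 2],
                       edge_mat[, 3], edge_mat[, 4])) return(FALSE)
  for (t in c(0.25, 0.5, 0.75)) {
    m <- p + t * (q - p)
    for (poly in islands$polygon) {
      if (point_strictly_inside(m, poly)) return(FALSE)
    }
  }
  TRUE
}

#' Precompute the water visibility graph of a region's islands
#'
#' Vertices are all island-polygon corners; an edge joins two corners when
#' the straight segment between them does not cross any island interior
#' (touching or running along a coastline is allowed, as docks sit on it).
#' Query points are added per call by [water_distance()].
#'
#' @param islands the island table of a `study_region`.
#' @return a `water_vis` list used by the water-distance functions.
#' @export
water_vis_graph <- function(islands) {
  rings <- lapply(islands$polygon, as_ring)
  verts <- do.call(rbind, rings)
  n_per <- vapply(rings, nrow, integer(1))
  poly_id <- rep(seq_along(rings), n_per)
  # all island boundary edges, for crossing tests
  edge_mat <- do.call(rbind, lapply(rings, function(r) {
    nn <- nrow(r)
    cbind(r, r[c(2:nn, 1), , drop = FALSE])
  }))
  offs <- cumsum(c(0, n_per))
  nv <- nrow(verts)
  ii <- integer(); jj <- integer(); ww <- numeric()
  for (i in seq_len(max(nv - 1, 0))) {
    for (j in (i + 1):nv) {
      same <- poly_id[i] == poly_id[j]
      if (same) {
        k <- i - offs[poly_id[i]]; l <- j - offs[poly_id[j]]
        np <- n_per[poly_id[i]]
        adjacent <- (l - k == 1) || (k == 1 && l == np)
        if (!adjacent &&
            !segment_over_water(verts[i, ], verts[j, ], islands, edge_mat)) next
      } else if (!segment_over_water(verts[i, ], verts[j, ], islands, edge_mat)) {
        next
      }
      ii <- c(ii, i); jj <- c(jj, j)
      ww <- c(ww, euclid(verts[i, ], verts[j, ]))
    }
  }
  structure(list(verts = verts, edges = data.frame(i = ii, j = jj, w = ww),
                 edge_mat = edge_mat, islands = islands),
            class = "water_vis")
}

# visibility of an external point to all base vertices: returns indices + dists
vis_from_point <- function(p, vg) {
  nv <- nrow(vg$verts)
  vis <- logical(nv)
  for (k in seq_len(nv)) {
    vis[k] <- segment_over_water(p, vg$verts[k, ], vg$islands, vg$edge_mat)
  }
  idx <- which(vis)
  d <- sqrt((vg$verts[idx, 1] - p[1])^2 + (vg$verts[idx, 2] - p[2])^2)
  list(idx = idx, dist = d)
}

assert_not_inland <- function(p, islands, label) {
  for (poly in islands$polygon) {
    if (point_strictly_inside(p, poly, tol = 1e-6)) {
      stop(sprintf("%s point (%.3f, %.3f) lies strictly inside an island",
                   label, p[1], p[2]))
    }
  }
}

#' Shortest water distance between points, avoiding land
#'
#' Straight-line distance modified to avoid all land barriers: the length of
#' the shortest polyline from `p` to each target whose interior never crosses
#' an island interior. Computed on a visibility graph over island-polygon
#' vertices plus the query points; when the direct segment is unobstructed
#' the distance equals the Euclidean distance.
#'
#' @param p length-2 start point (on water or a coastline).
#' @param q length-2 end point, or an m x 2 matrix of end points for
#'   [water_distance_to_many()].
#' @param islands island table of a `study_region`.
#' @param vis optional precomputed [water_vis_graph()].
#' @return distance(s) in km.
#' @export
water_distance <- function(p, q, islands, vis = NULL) {
  water_distance_to_many(p, rbind(q), islands, vis)[1]
}

#' @rdname water_distance
#' @export
water_distance_to_many <- function(p, q, islands, vis = NULL) {
  q <- rbind(q)
  assert_not_inland(p, islands, "start")
  for (r in seq_len(nrow(q))) assert_not_inland(q[r, ], islands, "end")
  if (!nrow(islands)) {
    return(sqrt((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2))
  }
  if (is.null(vis)) vis <- water_vis_graph(islands)

  out <- numeric(nrow(q))
  direct <- logical(nrow(q))
  for (r in seq_len(nrow(q))) {
    if (segment_over_water(p, q[r, ], islands, vis$edge_mat)) {
      out[r] <- euclid(p, q[r, ])
      direct[r] <- TRUE
    }
  }
  if (all(direct)) return(out)

  nv <- nrow(vis$verts)
  pv <- vis_from_point(p, vis)
  edf <- data.frame(from = as.character(vis$edges$i),
                    to = as.character(vis$edges$j), weight = vis$edges$w)
  if (length(pv$idx)) {
    edf <- rbind(edf, data.frame(from = "src", to = as.character(pv$idx),
                                 weight = pv$dist))
  }
  targets <- which(!direct)
  tnames <- paste0("dst", targets)
  for (r in targets) {
    qv <- vis_from_point(q[r, ], vis)
    if (length(qv$idx)) {
      edf <- rbind(edf, data.frame(from = paste0("dst", r),
                                   to = as.character(qv$idx), weight = qv$dist))
    }
  }
  vnames <- c(as.character(seq_len(nv)), "src", tnames)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = vnames))
  d <- igraph::distances(g, v = "src", to = tnames)
  out[targets] <- as.numeric(d)
  if (any(!is.finite(out))) {
    # cannot occur with valid (interior-disjoint) island geometry
    stop("unroutable water leg: no land-avoiding path found")
  }
  out
}

#' Nearest water-access point of a residence
#'
#' Candidates are every port and dock on the residence's island, plus every
#' beach within `beach_adjacency_km` (default 0.5 km) of the residence
#' polygon. The winner minimises the land leg from the residence centroid.
#' The land leg is measured along the road network when the residence is
#' road-connected (within the 5 km rule) and the access point is attached and
#' reachable; otherwise it is the straight-line distance.
#'
#' @param residence one row of the residence table.
#' @param region a `study_region`.
#' @param network optional `region_network` (ports/docks are attached there).
#' @param road_proximity_km road-connection rule threshold (default 5).
#' @param beach_adjacency_km beach eligibility distance (default 0.5).
#' @return list with `wap` (the chosen water-access row), `land_leg_km`.
#' @export
nearest_water_access <- function(residence, region, network = NULL,
                                 road_proximity_km = 5,
                                 beach_adjacency_km = 0.5) {
  p <- c(residence$x, residence$y)
  isl <- island_of_point(p, region$islands)
  if (is.na(isl)) stop(sprintf("residence '%s' lies on no island", residence$id))
  wap <- region$water_access
  on_island <- vapply(seq_len(nrow(wap)), function(i) {
    identical(island_of_point(c(wap$x[i], wap$y[i]), region$islands,
                              boundary_tol_km = 0.51), isl)
  }, logical(1))
  hub_ok <- wap$kind %in% c("port", "dock") & on_island
  beach_ok <- wap$kind == "beach" & on_island &
    vapply(seq_len(nrow(wap)), function(i) {
      point_polygon_distance(c(wap$x[i], wap$y[i]),
                             residence$polygon[[1]]) <= beach_adjacency_km
    }, logical(1))
  cand <- wap[hub_ok | beach_ok, , drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("landlocked residence '%s': island has no water access",
                 residence$id))
  }
  road_connected <-
    nearest_road_distance(p, road_segments_on_island(region, isl)) <=
    road_proximity_km
  leg <- vapply(seq_len(nrow(cand)), function(i) {
    straight <- euclid(p, c(cand$x[i], cand$y[i]))
    if (road_connected && !is.null(network) &&
        cand$kind[i] %in% c("port", "dock")) {
      net_d <- attached_point_distance(network, paste0("res:", residence$id),
                                       paste0("wap:", cand$id[i]))
      if (is.finite(net_d)) return(net_d)
    }
    straight
  }, numeric(1))
  ord <- order(leg, cand$id)
  best <- ord[1]
  list(wap = cand[best, , drop = FALSE], land_leg_km = leg[best])
}

#' Main naval hub of a facility
#'
#' The port or dock nearest (straight-line) to the facility on the facility's
#' island; this hub is the arrival point for naval travel. Beaches are not
#' eligible as hubs. Ties break to the smallest id.
#'
#' @param facility one row of the facility table.
#' @param region a `study_region`.
#' @return the chosen water-access row.
#' @export
facility_hub <- function(facility, region) {
  isl <- island_of_point(c(facility$x, facility$y), region$islands)
  if (is.na(isl)) stop(sprintf("facility '%s' lies on no island", facility$id))
  wap <- region$water_access
  ok <- wap$kind %in% c("port", "dock") &
    vapply(seq_len(nrow(wap)), function(i) {
      identical(island_of_point(c(wap$x[i], wap$y[i]), region$islands,
                                boundary_tol_km = 0.51), isl)
    }, logical(1))
  cand <- wap[ok, , drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("no port or dock on the island of facility '%s'", facility$id))
  }
  d <- sqrt((cand$x - facility$x)^2 + (cand$y - facility$y)^2)
  cand[order(d, cand$id)[1], , drop = FALSE]
}

segment_letters <- list(
  puskesmas = c(land = "A", to_wap = "C", water = "E", to_fac = "G"),
  hospital  = c(land = "B", to_wap = "D", water = "F", to_fac = "H")
)

# land leg from a facility's hub to the facility: straight line when they sit
# within hub_local_km of each other, else routed on the road graph (falling
# back to straight line if unconnected)
hub_to_facility_leg <- function(hub, facility, network, hub_local_km = 1) {
  straight <- euclid(c(hub$x, hub$y), c(facility$x, facility$y))
  if (straight <= hub_local_km || is.null(network)) return(straight)
  net_d <- attached_point_distance(network, paste0("wap:", hub$id),
                                   paste0("fac:", facility$id))
  if (is.finite(net_d)) net_d else straight
}

#' Combined land+naval route from a residence to a facility
#'
#' Assembles the three-leg journey of residences classified `land_naval`:
#' residence to its nearest water-access point (segment C for
#' puskesmas-bound, D for hospital-bound), water crossing to a facility hub
#' avoiding land barriers (E/F), and hub to facility (G/H). By default the
#' destination facility is the same-district facility of the requested kind
#' minimising the three-leg total; `mode = "chained"` instead reproduces a
#' greedy leg-by-leg construction (nearest hub by water, then that hub's
#' facility).
#'
#' @param residence one row of the residence table.
#' @param facility_kind `"puskesmas"` or `"hospital"`.
#' @param region a `study_region`.
#' @param network optional `region_network`.
#' @param vis optional precomputed [water_vis_graph()].
#' @param mode `"total"` (default) or `"chained"`.
#' @param restrict_district set `FALSE` to allow cross-district referral.
#' @param road_proximity_km,beach_adjacency_km,hub_local_km rule thresholds.
#' @return a `naval_route` list with the three legs, their segment letters,
#'   the chosen facility and the total distance.
#' @export
combined_route <- function(residence, facility_kind, region, network = NULL,
                           vis = NULL, mode = c("total", "chained"),
                           restrict_district = TRUE, road_proximity_km = 5,
                           beach_adjacency_km = 0.5, hub_local_km = 1) {
  mode <- match.arg(mode)
  stopifnot(facility_kind %in% facility_kinds)
  fac <- region$facilities
  cand <- fac[fac$kind == facility_kind &
                (!restrict_district | fac$district_id == residence$district_id), ,
              drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("no eligible facility: no %s in district '%s'",
                 facility_kind, residence$district_id))
  }
  acc <- nearest_water_access(residence, region, network,
                              road_proximity_km, beach_adjacency_km)
  if (is.null(vis)) vis <- water_vis_graph(region$islands)

  hubs <- lapply(seq_len(nrow(cand)),
                 function(i) facility_hub(cand[i, ], region))
  hub_xy <- do.call(rbind, lapply(hubs, function(h) c(h$x, h$y)))
  wleg <- water_distance_to_many(c(acc$wap$x, acc$wap$y), hub_xy,
                                 region$islands, vis)
  gleg <- vapply(seq_len(nrow(cand)), function(i) {
    hub_to_facility_leg(hubs[[i]], cand[i, ], network, hub_local_km)
  }, numeric(1))
  total <- acc$land_leg_km + wleg + gleg
  best <- if (mode == "total") {
    order(total, cand$id)[1]
  } else {
    order(wleg, cand$id)[1]
  }
  letters <- segment_letters[[facility_kind]]
  structure(list(
    residence_id = residence$id,
    facility_id = cand$id[best],
    facility_kind = facility_kind,
    wap_id = acc$wap$id,
    hub_id = hubs[[best]]$id,
    legs = stats::setNames(c(acc$land_leg_km, wleg[best], gleg[best]),
                           letters[c("to_wap", "water", "to_fac")]),
    total_km = total[best]
  ), class = "naval_route")
}
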