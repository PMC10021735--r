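# Road-graph construction, residence/facility attachment, the land vs
# land+naval access classifier, and district-restricted closest-facility
# shortest paths (route segments A and B).

#' Build a road graph from raw segments
#'
#' Segment endpoints closer than `snap_tolerance_km` are merged into a single
#' node (single-linkage, via union-find over close endpoint pairs); each
#' segment becomes one edge whose weight is the original geometric segment
#' length. Segments whose two endpoints collapse onto the same node are
#' dropped, so the graph has no zero-length edges. The graph may be
#' disconnected -- island road networks usually are.
#'
#' @param segments data frame with columns `x1,y1,x2,y2` (km).
#' @param snap_tolerance_km merge tolerance for endpoints (default 0.001 km
#'   = 1 m).
#' @return a `road_network`: list with `nodes` (data frame `id,x,y`), `edges`
#'   (data frame `from,to,length_km`) and `graph` (weighted igraph).
#' @export
build_road_graph <- function(segments, snap_tolerance_km = 0.001) {
  n_seg <- nrow(segments)
  if (!n_seg) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(nodes = data.frame(id = integer(), x = numeric(),
                                             y = numeric()),
                          edges = data.frame(from = integer(), to = integer(),
                                             length_km = numeric()),
                          graph = g),
                     class = "road_network"))
  }
  pts <- rbind(as.matrix(segments[, c("x1", "y1")]),
               as.matrix(segments[, c("x2", "y2")]))
  n_pts <- nrow(pts)

  parent <- seq_len(n_pts)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # union endpoints within tolerance (vectorised distance per anchor point)
  for (i in seq_len(n_pts - 1)) {
    rest <- (i + 1):n_pts
    d <- sqrt((pts[rest, 1] - pts[i, 1])^2 + (pts[rest, 2] - pts[i, 2])^2)
    for (j in rest[d <= snap_tolerance_km]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n_pts), find, integer(1))
  node_id <- match(comp, unique(comp))
  n_nodes <- max(node_id)
  nodes <- data.frame(id = seq_len(n_nodes), x = NA_real_, y = NA_real_)
  for (k in seq_len(n_nodes)) {
    members <- which(node_id == k)
    nodes$x[k] <- mean(pts[members, 1])
    nodes$y[k] <- mean(pts[members, 2])
  }

  from <- node_id[seq_len(n_seg)]
  to <- node_id[seq_len(n_seg) + n_seg]
  length_km <- sqrt((segments$x2 - segments$x1)^2 + (segments$y2 - segments$y1)^2)
  keep <- from != to
  edges <- data.frame(from = from[keep], to = to[keep],
                      length_km = length_km[keep])

  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to),
               weight = edges$length_km),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id), x = nodes$x, y = nodes$y))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, total %.2f km\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_km)))
  invisible(x)
}

#' Euclidean distance from a point to the nearest road
#'
#' Minimum point-to-segment distance over a set of road segments. An empty
#' road set yields `Inf`, signalling "no road on this island".
#'
#' @param p length-2 point (km).
#' @param segments road-segment data frame (`x1,y1,x2,y2`).
#' @return distance in km, possibly `Inf`.
#' @export
nearest_road_distance <- function(p, segments) {
  if (is.null(segments) || !nrow(segments)) return(Inf)
  min(point_segment_distance(p[1], p[2], segments$x1, segments$y1,
                             segments$x2, segments$y2))
}

road_segments_on_island <- function(region, island_idx) {
  roads <- region$roads
  if (!nrow(roads)) return(roads)
  mx <- (roads$x1 + roads$x2) / 2
  my <- (roads$y1 + roads$y2) / 2
  poly <- region$islands$polygon[[island_idx]]
  roads[points_in_polygon(mx, my, poly), , drop = FALSE]
}

#' Classify a residence's access mode for one facility type
#'
#' A residence requires a naval leg (`"land_naval"`) when either condition
#' holds: it lies more than `road_proximity_km` (default 5 km) from the
#' nearest road of its island, or its island hosts no facility of the queried
#' kind belonging to the residence's district. Otherwise access is `"land"`.
#' The proximity rule uses straight-line distance to the road geometry: it
#' exists precisely for residences that are not on the network.
#'
#' @param residence one row of the region's residence table.
#' @param facility_kind `"puskesmas"` or `"hospital"`.
#' @param region a `study_region`.
#' @param road_proximity_km rule threshold in km (default 5).
#' @return `"land"` or `"land_naval"`.
#' @export
classify_access <- function(residence, facility_kind, region,
                            road_proximity_km = 5) {
  stopifnot(facility_kind %in% facility_kinds)
  p <- c(residence$x, residence$y)
  isl <- island_of_point(p, region$islands)
  if (is.na(isl)) stop(sprintf("residence '%s' lies on no island", residence$id))
  d_road <- nearest_road_distance(p, road_segments_on_island(region, isl))
  if (d_road > road_proximity_km) return("land_naval")

  fac <- region$facilities
  same <- fac[fac$kind == facility_kind &
                fac$district_id == residence$district_id, , drop = FALSE]
  if (nrow(same)) {
    on_island <- vapply(seq_len(nrow(same)), function(i) {
      identical(island_of_point(c(same$x[i], same$y[i]), region$islands), isl)
    }, logical(1))
    if (any(on_island)) return("land")
  }
  "land_naval"
}

#' Shortest network distance between two road-graph nodes
#'
#' Dijkstra over the weighted road graph. Disconnected node pairs return
#' `Inf`: disconnection is a value, not an error.
#'
#' @param network a `road_network` (or an igraph with a `weight` edge
#'   attribute).
#' @param from,to node ids (as in `network$nodes$id`) or vertex names.
#' @return distance in km, `Inf` if no path exists.
#' @export
shortest_land_distance <- function(network, from, to) {
  g <- if (inherits(network, "road_network")) network$graph else network
  as.numeric(igraph::distances(g, v = as.character(from),
                               to = as.character(to)))
}

# Attach off-graph points (residence centroids, facilities, docks) to a road
# network: each point gains a node joined by a perpendicular access link to
# the nearest point of its nearest edge, splitting that edge. Attachment is
# restricted per island so a point never snaps to a road across water.
# Returns an augmented igraph plus a lookup of point vertex names and link
# lengths (link NA / vertex NA when the point's island has no road).
attach_points_to_network <- function(region, points, snap_tolerance_km = 0.001) {
  islands <- region$islands
  pt_island <- vapply(seq_len(nrow(points)), function(i) {
    island_of_point(c(points$x[i], points$y[i]), islands)
  }, integer(1))

  base <- build_road_graph(region$roads, snap_tolerance_km)
  edges <- base$edges
  nodes <- base$nodes
  # island membership per snapped edge, from the edge midpoint
  if (nrow(edges)) {
    emx <- (nodes$x[edges$from] + nodes$x[edges$to]) / 2
    emy <- (nodes$y[edges$from] + nodes$y[edges$to]) / 2
    edge_island <- vapply(seq_len(nrow(edges)), function(i) {
      island_of_point(c(emx[i], emy[i]), islands)
    }, integer(1))
  } else {
    edge_island <- integer()
  }

  attach_info <- data.frame(point_id = points$id, island = pt_island,
                            vertex = NA_character_, link_km = NA_real_,
                            stringsAsFactors = FALSE)
  # per-edge attachment records: list of data.frames (t, vertex)
  edge_splits <- vector("list", nrow(edges))
  extra_vertices <- list()
  link_edges <- list()

  for (i in seq_len(nrow(points))) {
    isl <- pt_island[i]
    cand <- which(edge_island == isl)
    if (is.na(isl) || !length(cand)) next
    p <- c(points$x[i], points$y[i])
    best_e <- NA_integer_; best <- NULL; best_d <- Inf
    for (e in cand) {
      a <- c(nodes$x[edges$from[e]], nodes$y[edges$from[e]])
      b <- c(nodes$x[edges$to[e]], nodes$y[edges$to[e]])
      pr <- project_on_segment(p, a, b)
      if (pr$dist < best_d) {
        best_d <- pr$dist; best <- pr; best_e <- e
      }
    }
    pv <- paste0("pt:", points$id[i])
    av <- paste0("att:", points$id[i])
    extra_vertices[[length(extra_vertices) + 1]] <-
      data.frame(name = c(pv, av),
                 x = c(p[1], best$point[1]), y = c(p[2], best$point[2]))
    link_edges[[length(link_edges) + 1]] <-
      data.frame(from = pv, to = av, weight = best_d)
    edge_splits[[best_e]] <- rbind(edge_splits[[best_e]],
                                   data.frame(t = best$t, vertex = av))
    attach_info$vertex[i] <- pv
    attach_info$link_km[i] <- best_d
  }

  # rebuild edge list with splits
  new_edges <- list()
  for (e in seq_len(nrow(edges))) {
    sp <- edge_splits[[e]]
    a <- as.character(edges$from[e]); b <- as.character(edges$to[e])
    len <- edges$length_km[e]
    if (is.null(sp)) {
      new_edges[[length(new_edges) + 1]] <- data.frame(from = a, to = b, weight = len)
    } else {
      sp <- sp[order(sp$t), , drop = FALSE]
      chain <- c(a, sp$vertex, b)
      tt <- c(0, sp$t, 1)
      for (k in seq_len(length(chain) - 1)) {
        w <- (tt[k + 1] - tt[k]) * len
        new_edges[[length(new_edges) + 1]] <-
          data.frame(from = chain[k], to = chain[k + 1], weight = max(w, 0))
      }
    }
  }
  vdf <- rbind(data.frame(name = as.character(nodes$id), x = nodes$x, y = nodes$y),
               if (length(extra_vertices)) do.call(rbind, extra_vertices))
  edf <- do.call(rbind, c(new_edges, link_edges))
  g <- if (is.null(edf)) {
    igraph::make_empty_graph(0, directed = FALSE)
  } else {
    igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  }
  list(graph = g, attach = attach_info)
}

#' Precompute the routing network of a region
#'
#' Builds the snapped road graph and attaches every residence centroid,
#' facility and port/dock to it by perpendicular access links (restricted to
#' roads of the point's own island). The result is consumed by
#' [closest_facility_land()], [nearest_water_access()] and [combined_route()];
#' building it once avoids re-splitting edges per query.
#'
#' @param region a `study_region`.
#' @param snap_tolerance_km endpoint merge tolerance for [build_road_graph()].
#' @return a `region_network` list: `graph` (igraph), `attach` (data frame of
#'   point vertex names and access-link lengths, keyed by point id).
#' @export
build_region_network <- function(region, snap_tolerance_km = 0.001) {
  hubs <- region$water_access[region$water_access$kind %in% c("port", "dock"), ,
                              drop = FALSE]
  pts <- rbind(
    data.frame(id = paste0("res:", region$residences$id),
               x = region$residences$x, y = region$residences$y),
    data.frame(id = paste0("fac:", region$facilities$id),
               x = region$facilities$x, y = region$facilities$y),
    if (nrow(hubs)) data.frame(id = paste0("wap:", hubs$id),
                               x = hubs$x, y = hubs$y)
  )
  net <- attach_points_to_network(region, pts, snap_tolerance_km)
  structure(list(graph = net$graph, attach = net$attach),
            class = "region_network")
}

# network distance between two attached points (including both access
# links); Inf when either is unattached or disconnected
attached_point_distance <- function(network, id_a, id_b) {
  at <- network$attach
  ia <- match(id_a, at$point_id)
  ib <- match(id_b, at$point_id)
  if (is.na(ia) || is.na(ib) ||
      is.na(at$vertex[ia]) || is.na(at$vertex[ib])) return(Inf)
  as.numeric(igraph::distances(network$graph, v = at$vertex[ia],
                               to = at$vertex[ib]))
}

#' District-restricted closest facility by land
#'
#' Among facilities of the requested kind in the residence's own district
#' (the referral regulation restricts public-facility visits to the home
#' district), returns the one minimising access link + shortest road path +
#' facility access link. Ties break to the smallest facility id. Access-link
#' lengths count toward the reported distance.
#'
#' @param residence one row of the residence table.
#' @param facility_kind `"puskesmas"` or `"hospital"`.
#' @param region a `study_region`.
#' @param network a `region_network` from [build_region_network()] (built on
#'   the fly if omitted).
#' @param restrict_district set `FALSE` to allow cross-district referral.
#' @return list with `residence_id`, `facility_id`, `facility_kind`,
#'   `distance_km`.
#' @export
closest_facility_land <- function(residence, facility_kind, region,
                                  network = NULL, restrict_district = TRUE) {
  stopifnot(facility_kind %in% facility_kinds)
  if (is.null(network)) network <- build_region_network(region)
  fac <- region$facilities
  cand <- fac[fac$kind == facility_kind &
                (!restrict_district | fac$district_id == residence$district_id), ,
              drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("no eligible facility: no %s in district '%s'",
                 facility_kind, residence$district_id))
  }
  d <- vapply(cand$id, function(fid) {
    attached_point_distance(network, paste0("res:", residence$id),
                            paste0("fac:", fid))
  }, numeric(1))
  ord <- order(d, cand$id)
  best <- ord[1]
  list(residence_id = residence$id, facility_id = cand$id[best],
       facility_kind = facility_kind, distance_km = unname(d[best]))
}
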