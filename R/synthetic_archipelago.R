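# Seeded generator of synthetic archipelagic study regions, plus a
# hand-crafted three-island toy fixture whose route legs are computable by
# hand. The generator emulates the structure the analysis assumes:
# multi-island districts, sparse partially-connecting road networks, coastal
# water-access points, and facilities with heterogeneous staffing.

#' Configuration for the synthetic-archipelago generator
#'
#' Defaults describe a mid-sized archipelagic province at desk scale: three
#' districts of two to three islands each, roughly a hundred residential
#' clusters per district with 85% of them connected to a road, three
#' puskesmas and one hospital per district (the hospital on the district's
#' main island), district census totals spanning the range seen in Indonesian
#' island provinces, and beaches every 5 km of coastline.
#'
#' @param n_districts number of districts (>= 1).
#' @param islands_per_district length-2 integer range.
#' @param residences_per_district length-2 integer range.
#' @param road_coverage fraction of residences connected to the road network.
#' @param puskesmas_per_district,hospitals_per_district facility counts.
#' @param population_range district census total range.
#' @param staffing list of per-kind ranges for physicians/nurses/midwives.
#' @param beach_spacing_km coastline spacing of beach access points.
#' @param seed integer seed driving the single pseudo-random stream.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_districts = 3,
                             islands_per_district = c(2, 4),
                             residences_per_district = c(90, 110),
                             road_coverage = 0.85,
                             puskesmas_per_district = 3,
                             hospitals_per_district = 1,
                             population_range = c(75000, 430000),
                             staffing = list(
                               puskesmas = list(physicians = c(0, 2),
                                                nurses = c(2, 12),
                                                midwives = c(1, 8)),
                               hospital = list(physicians = c(5, 20),
                                               nurses = c(50, 150),
                                               midwives = c(10, 40))),
                             beach_spacing_km = 5,
                             seed = 1) {
  stopifnot(n_districts >= 1, road_coverage >= 0, road_coverage <= 1,
            puskesmas_per_district >= 0, hospitals_per_district >= 0,
            beach_spacing_km > 0)
  structure(list(n_districts = n_districts,
                 islands_per_district = islands_per_district,
                 residences_per_district = residences_per_district,
                 road_coverage = road_coverage,
                 puskesmas_per_district = puskesmas_per_district,
                 hospitals_per_district = hospitals_per_district,
                 population_range = population_range,
                 staffing = staffing,
                 beach_spacing_km = beach_spacing_km,
                 seed = seed),
            class = "generator_config")
}

rint <- function(range) {
  if (length(range) == 1) range <- c(range, range)
  as.integer(floor(stats::runif(1, range[1], range[2] + 1)))
}

# radial star polygon around a centre: near-convex perturbed ellipse
make_island_polygon <- function(center, radius, n_vert = 16) {
  theta <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  b <- radius * stats::runif(1, 0.65, 1)
  rot <- stats::runif(1, 0, pi)
  noise <- 1 + stats::runif(n_vert, -0.12, 0.12)
  rx <- radius * cos(theta) * noise
  ry <- b * sin(theta) * noise
  x <- center[1] + rx * cos(rot) - ry * sin(rot)
  y <- center[2] + rx * sin(rot) + ry * cos(rot)
  cbind(x, y)
}

# point inside a radial-star island at radial fraction <= t_max of the
# boundary, by interpolating the vertex radii
island_interior_point <- function(polygon, center, t_max = 0.7) {
  ring <- as_ring(polygon)
  ang <- atan2(ring[, 2] - center[2], ring[, 1] - center[1])
  rad <- sqrt((ring[, 1] - center[1])^2 + (ring[, 2] - center[2])^2)
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  th <- stats::runif(1, -pi, pi)
  k <- findInterval(th, ang)
  if (k == 0 || k == length(ang)) {
    a1 <- ang[length(ang)] - 2 * pi; r1 <- rad[length(rad)]
    a2 <- ang[1]; r2 <- rad[1]
    if (k == length(ang)) { a1 <- ang[k]; r1 <- rad[k]; a2 <- ang[1] + 2 * pi; r2 <- rad[1] }
  } else {
    a1 <- ang[k]; r1 <- rad[k]; a2 <- ang[k + 1]; r2 <- rad[k + 1]
  }
  w <- if (a2 > a1) (th - a1) / (a2 - a1) else 0
  rb <- r1 + w * (r2 - r1)
  t <- sqrt(stats::runif(1)) * t_max
  center + t * rb * c(cos(th), sin(th))
}

square_ring <- function(center, side) {
  h <- side / 2
  rbind(c(center[1] - h, center[2] - h), c(center[1] + h, center[2] - h),
        c(center[1] + h, center[2] + h), c(center[1] - h, center[2] + h))
}

mst_segments <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(data.frame(x1 = numeric(), y1 = numeric(),
                               x2 = numeric(), y2 = numeric()))
  d <- as.matrix(stats::dist(pts))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  m <- igraph::mst(g)
  el <- igraph::as_edgelist(m, names = FALSE)
  data.frame(x1 = pts[el[, 1], 1], y1 = pts[el[, 1], 2],
             x2 = pts[el[, 2], 1], y2 = pts[el[, 2], 2])
}

#' Generate a synthetic archipelagic study region
#'
#' Islands are placed as perturbed ellipses with rejection sampling keeping a
#' 3 km sea gap between any two; residential clusters are small squares in
#' island interiors; roads are Euclidean minimum spanning trees over the
#' island centre, its facilities and the road-connected share of residences;
#' every facility gets a dock at the nearest coastline point, every island
#' with residences gets at least one dock, and beaches line every coast at
#' the configured spacing. Identical config and seed give identical output.
#'
#' @param config a [generator_config()].
#' @return a `study_region` passing [validate_region()].
#' @export
generate_region <- function(config = generator_config()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  grid_n <- ceiling(sqrt(config$n_districts))
  spacing <- 90
  islands <- list(); isl_district <- character(); isl_center <- list()
  isl_radius <- numeric()

  district_names <- paste0("District-", LETTERS[seq_len(config$n_districts)])
  d_rows <- list()
  for (d in seq_len(config$n_districts)) {
    cx <- ((d - 1) %% grid_n) * spacing
    cy <- ((d - 1) %/% grid_n) * spacing
    n_isl <- rint(config$islands_per_district)
    if (n_isl < 1) stop("infeasible config: each district needs >= 1 island")
    for (k in seq_len(n_isl)) {
      radius <- if (k == 1) stats::runif(1, 10, 15) else stats::runif(1, 4, 8)
      placed <- FALSE
      for (try in seq_len(300)) {
        c_try <- c(cx, cy) + stats::runif(2, -26, 26)
        ok <- TRUE
        for (m in seq_along(islands)) {
          gap <- euclid(c_try, isl_center[[m]]) - radius - isl_radius[m]
          if (gap < 3) { ok <- FALSE; break }
        }
        if (ok) {
          poly <- make_island_polygon(c_try, radius)
          islands[[length(islands) + 1]] <- poly
          isl_district <- c(isl_district, paste0("D", d))
          isl_center[[length(isl_center) + 1]] <- c_try
          isl_radius <- c(isl_radius, radius * 1.15)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "infeasible config: cannot place island %d of district %d with a 3 km sea gap",
          k, d))
      }
    }
    d_rows[[d]] <- list(id = paste0("D", d), name = district_names[d],
                        total_population = round(stats::runif(
                          1, config$population_range[1],
                          config$population_range[2])))
  }

  island_df <- data.frame(id = paste0("I", seq_along(islands)))
  island_df$polygon <- islands
  island_df$district_id <- isl_district

  # district polygons: padded bounding boxes of the district's islands
  districts <- data.frame(
    id = vapply(d_rows, `[[`, character(1), "id"),
    name = vapply(d_rows, `[[`, character(1), "name"),
    total_population = vapply(d_rows, `[[`, numeric(1), "total_population"))
  districts$polygon <- lapply(districts$id, function(did) {
    polys <- island_df$polygon[island_df$district_id == did]
    xy <- do.call(rbind, polys)
    pad <- 2
    rbind(c(min(xy[, 1]) - pad, min(xy[, 2]) - pad),
          c(max(xy[, 1]) + pad, min(xy[, 2]) - pad),
          c(max(xy[, 1]) + pad, max(xy[, 2]) + pad),
          c(min(xy[, 1]) - pad, max(xy[, 2]) + pad))
  })

  # residences: per district, spread over its islands by area
  res_rows <- list()
  r_counter <- 0
  isl_area <- vapply(island_df$polygon, polygon_area, numeric(1))
  for (d in seq_len(nrow(districts))) {
    did <- districts$id[d]
    idx <- which(island_df$district_id == did)
    n_res <- rint(config$residences_per_district)
    isl_pick <- idx[sample.int(length(idx), n_res, replace = TRUE,
                               prob = isl_area[idx])]
    for (i in seq_len(n_res)) {
      ii <- isl_pick[i]
      center <- island_interior_point(island_df$polygon[[ii]],
                                      isl_center[[ii]], t_max = 0.7)
      side <- stats::runif(1, 0.4, 1.2)
      r_counter <- r_counter + 1
      res_rows[[r_counter]] <- list(id = sprintf("R%04d", r_counter),
                                    district_id = did, island = ii,
                                    x = center[1], y = center[2], side = side)
    }
  }
  residences <- data.frame(
    id = vapply(res_rows, `[[`, character(1), "id"),
    district_id = vapply(res_rows, `[[`, character(1), "district_id"),
    x = vapply(res_rows, `[[`, numeric(1), "x"),
    y = vapply(res_rows, `[[`, numeric(1), "y"),
    population = NA_real_)
  residences$polygon <- lapply(res_rows, function(r) {
    square_ring(c(r$x, r$y), r$side)
  })
  res_island <- vapply(res_rows, `[[`, numeric(1), "island")

  # facilities: hospitals on the district's main (largest) island, puskesmas
  # round-robin over islands starting from the main island
  fac_rows <- list()
  f_counter <- 0
  sample_staff <- function(kind) {
    s <- config$staffing[[kind]]
    c(physicians = rint(s$physicians), nurses = rint(s$nurses),
      midwives = rint(s$midwives))
  }
  for (d in seq_len(nrow(districts))) {
    did <- districts$id[d]
    idx <- which(island_df$district_id == did)
    idx <- idx[order(-isl_area[idx])]
    for (h in seq_len(config$hospitals_per_district)) {
      ii <- idx[1 + (h - 1) %% length(idx)]
      p <- island_interior_point(island_df$polygon[[ii]], isl_center[[ii]],
                                 t_max = 0.5)
      st <- sample_staff("hospital")
      f_counter <- f_counter + 1
      fac_rows[[f_counter]] <- list(id = sprintf("F%03d", f_counter),
                                    kind = "hospital", district_id = did,
                                    island = ii, x = p[1], y = p[2], st = st)
    }
    for (k in seq_len(config$puskesmas_per_district)) {
      ii <- idx[1 + (k - 1) %% length(idx)]
      p <- island_interior_point(island_df$polygon[[ii]], isl_center[[ii]],
                                 t_max = 0.6)
      st <- sample_staff("puskesmas")
      f_counter <- f_counter + 1
      fac_rows[[f_counter]] <- list(id = sprintf("F%03d", f_counter),
                                    kind = "puskesmas", district_id = did,
                                    island = ii, x = p[1], y = p[2], st = st)
    }
  }
  facilities <- data.frame(
    id = vapply(fac_rows, `[[`, character(1), "id"),
    kind = vapply(fac_rows, `[[`, character(1), "kind"),
    district_id = vapply(fac_rows, `[[`, character(1), "district_id"),
    x = vapply(fac_rows, function(f) f$x, numeric(1)),
    y = vapply(fac_rows, function(f) f$y, numeric(1)),
    physicians = vapply(fac_rows, function(f) f$st[["physicians"]], numeric(1)),
    nurses = vapply(fac_rows, function(f) f$st[["nurses"]], numeric(1)),
    midwives = vapply(fac_rows, function(f) f$st[["midwives"]], numeric(1)))
  fac_island <- vapply(fac_rows, `[[`, numeric(1), "island")

  # roads: per island, MST over centre + facilities + connected residences
  road_rows <- list()
  connected <- stats::runif(nrow(residences)) <= config$road_coverage
  for (ii in seq_len(nrow(island_df))) {
    pts <- rbind(matrix(isl_center[[ii]], 1),
                 as.matrix(facilities[fac_island == ii, c("x", "y")]),
                 as.matrix(residences[res_island == ii & connected,
                                      c("x", "y")]))
    seg <- mst_segments(pts)
    if (nrow(seg)) road_rows[[length(road_rows) + 1]] <- seg
  }
  roads <- if (length(road_rows)) do.call(rbind, road_rows) else
    data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())

  # water access: dock at the coastline point nearest each facility; a
  # village dock per inhabited island without one; beaches along all coasts
  wap_rows <- list()
  w_counter <- 0
  add_wap <- function(kind, p) {
    w_counter <<- w_counter + 1
    wap_rows[[w_counter]] <<- list(id = sprintf("W%04d", w_counter),
                                   kind = kind, x = p[1], y = p[2])
  }
  island_has_dock <- rep(FALSE, nrow(island_df))
  for (f in seq_len(nrow(facilities))) {
    ii <- fac_island[f]
    p <- nearest_ring_point(c(facilities$x[f], facilities$y[f]),
                            island_df$polygon[[ii]])
    add_wap(if (facilities$kind[f] == "hospital") "port" else "dock", p)
    island_has_dock[ii] <- TRUE
  }
  for (ii in seq_len(nrow(island_df))) {
    res_here <- which(res_island == ii)
    if (length(res_here) && !island_has_dock[ii]) {
      p <- nearest_ring_point(c(residences$x[res_here[1]],
                                residences$y[res_here[1]]),
                              island_df$polygon[[ii]])
      add_wap("dock", p)
      island_has_dock[ii] <- TRUE
    }
    beaches <- ring_points_at_spacing(island_df$polygon[[ii]],
                                      config$beach_spacing_km)
    for (b in seq_len(nrow(beaches))) add_wap("beach", beaches[b, ])
  }
  water_access <- data.frame(
    id = vapply(wap_rows, `[[`, character(1), "id"),
    kind = vapply(wap_rows, `[[`, character(1), "kind"),
    x = vapply(wap_rows, `[[`, numeric(1), "x"),
    y = vapply(wap_rows, `[[`, numeric(1), "y"))

  island_df$district_id <- NULL
  study_region(districts, island_df, residences, roads, water_access,
               facilities)
}

#' Hand-crafted three-island toy region
#'
#' A fixed two-district, three-island region with axis-aligned coordinates
#' chosen so that every route leg is computable by hand:
#'
#' * Island IA (district D1, square 0..10 x 0..10) hosts puskesmas F1 at
#'   (2,2), hospital F2 at (8,2), roads (2,2)-(2,8), (2,2)-(8,2),
#'   (8,2)-(10,2) and dock W1 at (10,2). Residence R1 sits on the road at
#'   (2,6): land distance 4 km to F1 and 10 km to F2.
#' * Island IB (district D1, square 14..20 x 0..6) hosts puskesmas F3 at
#'   (18,2), a road (14,2)-(18,2) and dock W2 at (14,2). Residence R2 at
#'   (16,2) reaches F3 by land (2 km) but needs a naval route to hospital
#'   F2: 2 km to dock W2, a 4 km open-water crossing W2-W1, and 2 km of road
#'   from W1 to F2 (total 8 km).
#' * Island IC (district D2, square 0..8 x 14..22) has no roads; puskesmas
#'   F4 at (1,15) with dock W3 at (0,15), hospital F5 at (7,15) with dock W4
#'   at (8,15). Residence R3 at (2,19) is classified land+naval for both
#'   kinds; its nearest water access is W3 (straight line, sqrt(20) km). The
#'   puskesmas trip shares W3 as the facility hub (water leg 0, 1 km hub
#'   leg); the hospital trip must round the island's southern corners
#'   ((0,14), (8,14)): water leg 1 + 8 + 1 = 10 km, plus a 1 km hub leg.
#'
#' District totals are 100,000 (D1) and 50,000 (D2); the three residential
#' squares have unit area, so allocation gives 50,000 to each D1 cluster and
#' 50,000 to R3.
#'
#' @return a `study_region`.
#' @export
toy_fixture <- function() {
  districts <- data.frame(id = c("D1", "D2"), name = c("Alpha", "Beta"),
                          total_population = c(100000, 50000))
  districts$polygon <- list(
    rbind(c(-1, -1), c(21, -1), c(21, 11), c(-1, 11)),
    rbind(c(-1, 13), c(9, 13), c(9, 23), c(-1, 23)))

  islands <- data.frame(id = c("IA", "IB", "IC"))
  islands$polygon <- list(
    rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
    rbind(c(14, 0), c(20, 0), c(20, 6), c(14, 6)),
    rbind(c(0, 14), c(8, 14), c(8, 22), c(0, 22)))

  residences <- data.frame(
    id = c("R1", "R2", "R3"),
    district_id = c("D1", "D1", "D2"),
    x = c(2, 16, 2), y = c(6, 2, 19),
    population = NA_real_)
  residences$polygon <- list(
    square_ring(c(2, 6), 1), square_ring(c(16, 2), 1), square_ring(c(2, 19), 1))

  roads <- data.frame(
    x1 = c(2, 2, 8, 14), y1 = c(2, 2, 2, 2),
    x2 = c(2, 8, 10, 18), y2 = c(8, 2, 2, 2))

  water_access <- data.frame(
    id = c("W1", "W2", "W3", "W4", "W5"),
    kind = c("dock", "dock", "dock", "dock", "beach"),
    x = c(10, 14, 0, 8, 17), y = c(2, 2, 15, 15, 0))

  facilities <- data.frame(
    id = c("F1", "F2", "F3", "F4", "F5"),
    kind = c("puskesmas", "hospital", "puskesmas", "puskesmas", "hospital"),
    district_id = c("D1", "D1", "D1", "D2", "D2"),
    x = c(2, 8, 18, 1, 7), y = c(2, 2, 2, 15, 15),
    physicians = c(1, 10, 0, 1, 5),
    nurses = c(5, 50, 3, 4, 30),
    midwives = c(4, 20, 2, 3, 10))

  study_region(districts, islands, residences, roads, water_access,
               facilities)
}
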