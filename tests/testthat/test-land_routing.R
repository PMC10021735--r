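test_that("road-graph snapping merges endpoints within tolerance", {
  seg <- data.frame(x1 = c(0, 1), y1 = c(0, 0), x2 = c(1, 2), y2 = c(0, 0))
  net <- build_road_graph(seg)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)

  seg2 <- data.frame(x1 = c(0, 1.0005), y1 = c(0, 0), x2 = c(1, 2), y2 = c(0, 0))
  net2 <- build_road_graph(seg2, snap_tolerance_km = 0.001)
  expect_equal(nrow(net2$nodes), 3)
  net3 <- build_road_graph(seg2, snap_tolerance_km = 0.0001)
  expect_equal(nrow(net3$nodes), 4)
})

test_that("snapped node count equals a brute-force union-find over endpoints", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 40
    seg <- data.frame(x1 = stats::runif(n, 0, 10), y1 = stats::runif(n, 0, 10),
                      x2 = stats::runif(n, 0, 10), y2 = stats::runif(n, 0, 10))
    # make some endpoints near-coincident
    seg$x2[1:10] <- seg$x1[11:20] + stats::runif(10, -4e-4, 4e-4)
    seg$y2[1:10] <- seg$y1[11:20] + stats::runif(10, -4e-4, 4e-4)
    tol <- 0.001
    pts <- rbind(as.matrix(seg[, 1:2]), as.matrix(seg[, 3:4]))
    # oracle: transitive closure of the "within tolerance" relation
    m <- nrow(pts)
    grp <- seq_len(m)
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):m) {
          if (grp[i] != grp[j] &&
              sqrt(sum((pts[i, ] - pts[j, ])^2)) <= tol) {
            grp[grp == grp[j]] <- grp[i]
            changed <- TRUE
          }
        }
      }
    }
    net <- build_road_graph(seg, tol)
    expect_equal(nrow(net$nodes), length(unique(grp)))
    expect_equal(nrow(net$edges), sum(seg$x1 != seg$x2 | seg$y1 != seg$y2))
  }
})

test_that("nearest road distance matches the exhaustive per-segment minimum", {
  road <- data.frame(x1 = -10, y1 = 0, x2 = 10, y2 = 0)
  expect_equal(nearest_road_distance(c(0, 6), road), 6)
  expect_equal(nearest_road_distance(c(3, 0), road), 0)
  expect_equal(nearest_road_distance(c(0, 0), road[0, ]), Inf)

  set.seed(33)
  seg <- data.frame(x1 = stats::runif(100, 0, 20), y1 = stats::runif(100, 0, 20),
                    x2 = stats::runif(100, 0, 20), y2 = stats::runif(100, 0, 20))
  for (rep in 1:20) {
    p <- stats::runif(2, 0, 20)
    brute <- min(vapply(seq_len(100), function(i) {
      a <- c(seg$x1[i], seg$y1[i]); b <- c(seg$x2[i], seg$y2[i])
      # direct quadratic minimisation along the segment
      f <- function(t) sqrt(sum((p - (a + t * (b - a)))^2))
      stats::optimize(f, c(0, 1), tol = 1e-10)$objective
    }, numeric(1)))
    expect_equal(nearest_road_distance(p, seg), brute, tolerance = 1e-6)
  }
})

test_that("access classification follows the 5 km rule and island facility rule", {
  r <- toy_fixture()
  res <- r$residences
  # R1: on a road, same-island puskesmas and hospital
  expect_equal(classify_access(res[1, ], "puskesmas", r), "land")
  expect_equal(classify_access(res[1, ], "hospital", r), "land")
  # R2: on a road, island has a puskesmas but no hospital
  expect_equal(classify_access(res[2, ], "puskesmas", r), "land")
  expect_equal(classify_access(res[2, ], "hospital", r), "land_naval")
  # R3: island has both facility kinds but no road at all (> 5 km rule)
  expect_equal(classify_access(res[3, ], "puskesmas", r), "land_naval")
  expect_equal(classify_access(res[3, ], "hospital", r), "land_naval")
})

test_that("the proximity threshold is a strict > 5 km cut", {
  r <- make_two_island_region()
  # move Ra's cluster so its centroid is exactly 6 km from the road y = 5
  sq <- rbind(c(4.5, 0.5), c(5.5, 0.5), c(5.5, 1.5), c(4.5, 1.5))
  r$residences$polygon[[1]] <- sq
  r$residences$x[1] <- 5; r$residences$y[1] <- 1
  # road at y=5: distance 4 -> land
  expect_equal(classify_access(r$residences[1, ], "puskesmas", r), "land")
  r$roads <- data.frame(x1 = 2, y1 = 9.5, x2 = 8, y2 = 9.5)  # 8.5 km away
  expect_equal(classify_access(r$residences[1, ], "puskesmas", r), "land_naval")
})

test_that("graph shortest paths match hand values and Floyd-Warshall", {
  chain <- build_road_graph(data.frame(x1 = c(0, 2), y1 = 0,
                                       x2 = c(2, 5), y2 = 0))
  a <- chain$nodes$id[chain$nodes$x == 0]
  c_ <- chain$nodes$id[chain$nodes$x == 5]
  expect_equal(shortest_land_distance(chain, a, c_), 5)

  set.seed(77)
  for (rep in 1:20) {
    rg <- random_graph(50, 120)
    oracle <- floyd_warshall(rg$dense)
    for (k in 1:20) {
      uv <- sample.int(50, 2)
      got <- as.numeric(igraph::distances(rg$graph, as.character(uv[1]),
                                          as.character(uv[2])))
      expect_equal(got, oracle[uv[1], uv[2]], tolerance = 1e-9)
    }
  }
})

test_that("the graph metric is symmetric, triangular and edge-monotone", {
  set.seed(91)
  rg <- random_graph(30, 70)
  d <- igraph::distances(rg$graph)
  expect_equal(d, t(d))
  for (rep in 1:50) {
    uvw <- sample.int(30, 3)
    expect_lte(d[uvw[1], uvw[3]],
               d[uvw[1], uvw[2]] + d[uvw[2], uvw[3]] + 1e-9)
  }
  # adding an edge never increases any distance
  g2 <- igraph::add_edges(rg$graph, c("3", "17"), weight = 0.05)
  d2 <- igraph::distances(g2)[rownames(d), colnames(d)]
  expect_true(all(d2 <= d + 1e-9))
})

test_that("closest facility by land minimises link + path + link with id tie-break", {
  r <- toy_fixture()
  net <- build_region_network(r)
  res <- r$residences
  out <- closest_facility_land(res[1, ], "puskesmas", r, net)
  expect_equal(out$facility_id, "F1")
  expect_equal(out$distance_km, 4)
  out <- closest_facility_land(res[1, ], "hospital", r, net)
  expect_equal(out$facility_id, "F2")
  expect_equal(out$distance_km, 10)
  out <- closest_facility_land(res[2, ], "puskesmas", r, net)
  expect_equal(out$facility_id, "F3")
  expect_equal(out$distance_km, 2)

  # equidistant pair -> smaller id wins
  r2 <- make_two_island_region()
  r2$facilities <- rbind(r2$facilities, r2$facilities[1, ])
  r2$facilities$id <- c("F2", "Fb", "F1")
  r2$facilities$x[3] <- 8  # F1 and F2 both 3 km along the road from Ra
  net2 <- build_region_network(r2)
  out <- closest_facility_land(r2$residences[1, ], "puskesmas", r2, net2)
  expect_equal(out$facility_id, "F1")
  expect_equal(out$distance_km, 3)

  expect_error(closest_facility_land(res[3, ], "hospital", r,
                                     restrict_district = TRUE),
               NA)  # D2 has a hospital (F5)
  r3 <- toy_fixture()
  r3$facilities <- r3$facilities[r3$facilities$id != "F5", ]
  expect_error(closest_facility_land(r3$residences[3, ], "hospital", r3),
               "no eligible facility")
})

test_that("closest-facility distance is minimal over all eligible facilities", {
  set.seed(14)
  r <- generate_region(generator_config(
    n_districts = 2, islands_per_district = c(2, 2),
    residences_per_district = c(8, 10), puskesmas_per_district = 3,
    seed = 14))
  net <- build_region_network(r)
  res <- r$residences
  fac <- r$facilities
  for (i in seq_len(nrow(res))) {
    if (classify_access(res[i, ], "puskesmas", r) != "land") next
    out <- closest_facility_land(res[i, ], "puskesmas", r, net)
    cand <- fac[fac$kind == "puskesmas" &
                  fac$district_id == res$district_id[i], ]
    for (fid in cand$id) {
      d <- archaccess:::attached_point_distance(net, paste0("res:", res$id[i]),
                                                paste0("fac:", fid))
      expect_gte(d + 1e-9, out$distance_km)
    }
  }
})
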