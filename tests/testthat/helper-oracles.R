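# Independent oracles used to cross-check the package implementation.
# These deliberately use different algorithms than the code under test.

# all-pairs shortest paths by Floyd-Warshall on a dense weight matrix
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- w
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# random connected-ish weighted graph as (edge list, dense matrix)
random_graph <- function(n_nodes, n_edges) {
  from <- sample.int(n_nodes, n_edges, replace = TRUE)
  to <- sample.int(n_nodes, n_edges, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  w <- stats::runif(length(from), 0.1, 10)
  dense <- matrix(Inf, n_nodes, n_nodes)
  for (i in seq_along(from)) {
    dense[from[i], to[i]] <- min(dense[from[i], to[i]], w[i])
    dense[to[i], from[i]] <- dense[from[i], to[i]]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to), weight = w),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n_nodes))))
  list(graph = g, dense = dense)
}

# Monte-Carlo polygon area: fraction of bounding-box samples inside
mc_polygon_area <- function(polygon, n = 1e6) {
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  x <- stats::runif(n, xr[1], xr[2])
  y <- stats::runif(n, yr[1], yr[2])
  mean(points_in_polygon(x, y, polygon)) * diff(xr) * diff(yr)
}

# Monte-Carlo centroid: mean of uniform interior samples
mc_polygon_centroid <- function(polygon, n = 2e5) {
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  x <- stats::runif(n, xr[1], xr[2])
  y <- stats::runif(n, yr[1], yr[2])
  inside <- points_in_polygon(x, y, polygon)
  c(mean(x[inside]), mean(y[inside]))
}

# random simple polygon: star-shaped around the origin
random_star_polygon <- function(n_vert = 8, r_min = 1, r_max = 5) {
  theta <- sort(stats::runif(n_vert, 0, 2 * pi))
  r <- stats::runif(n_vert, r_min, r_max)
  cbind(r * cos(theta), r * sin(theta))
}

# grid shortest-path oracle for water distance: 16-neighbour lattice over a
# bounding box, cells strictly inside an island blocked
raster_water_oracle <- function(islands, cell_km, pad = 2) {
  xy <- do.call(rbind, islands$polygon)
  xr <- range(xy[, 1]) + c(-pad, pad)
  yr <- range(xy[, 2]) + c(-pad, pad)
  nx <- ceiling(diff(xr) / cell_km)
  ny <- ceiling(diff(yr) / cell_km)
  cx <- xr[1] + (seq_len(nx) - 0.5) * cell_km
  cy <- yr[1] + (seq_len(ny) - 0.5) * cell_km
  gx <- rep(cx, times = ny)
  gy <- rep(cy, each = nx)
  blocked <- rep(FALSE, nx * ny)
  for (poly in islands$polygon) {
    blocked <- blocked | points_in_polygon(gx, gy, poly)
  }
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  offsets <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1),
                   c(2, 1), c(1, 2), c(2, -1), c(1, -2))
  ef <- integer(); et <- integer(); ew <- numeric()
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets[o, 1]; dy <- offsets[o, 2]
    ix <- seq_len(nx); iy <- seq_len(ny)
    ix1 <- rep(ix, times = ny); iy1 <- rep(iy, each = nx)
    ix2 <- ix1 + dx; iy2 <- iy1 + dy
    ok <- ix2 >= 1 & ix2 <= nx & iy2 >= 1 & iy2 <= ny
    a <- idx(ix1[ok], iy1[ok]); b <- idx(ix2[ok], iy2[ok])
    free <- !blocked[a] & !blocked[b]
    if (max(abs(dx), abs(dy)) > 1) {
      mid <- idx(pmin(pmax(round(ix1[ok] + dx / 2), 1), nx),
                 pmin(pmax(round(iy1[ok] + dy / 2), 1), ny))
      free <- free & !blocked[mid]
    }
    a <- a[free]; b <- b[free]
    ef <- c(ef, a); et <- c(et, b)
    ew <- c(ew, rep(sqrt(dx^2 + dy^2) * cell_km, length(a)))
  }
  g <- igraph::make_graph(rbind(ef, et), n = nx * ny, directed = FALSE)
  igraph::E(g)$weight <- ew
  nearest_free <- function(p) {
    d2 <- (gx - p[1])^2 + (gy - p[2])^2
    d2[blocked] <- Inf
    which.min(d2)
  }
  list(
    distance = function(p, q) {
      as.numeric(igraph::distances(g, v = nearest_free(p), to = nearest_free(q)))
    },
    random_water_point = function() {
      repeat {
        i <- sample(which(!blocked), 1)
        return(c(gx[i], gy[i]))
      }
    },
    cell_km = cell_km
  )
}

# tiny two-island region assembled directly, for constructed-fixture tests
make_two_island_region <- function() {
  districts <- data.frame(id = c("D1", "D2"), name = c("North", "South"),
                          total_population = c(1000, 2000))
  districts$polygon <- list(
    rbind(c(-1, -1), c(11, -1), c(11, 11), c(-1, 11)),
    rbind(c(-1, 19), c(11, 19), c(11, 31), c(-1, 31)))
  islands <- data.frame(id = c("I1", "I2"))
  islands$polygon <- list(
    rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
    rbind(c(0, 20), c(10, 20), c(10, 30), c(0, 30)))
  sq <- function(cx, cy, s = 1) {
    rbind(c(cx - s / 2, cy - s / 2), c(cx + s / 2, cy - s / 2),
          c(cx + s / 2, cy + s / 2), c(cx - s / 2, cy + s / 2))
  }
  residences <- data.frame(id = c("Ra", "Rb"), district_id = c("D1", "D2"),
                           x = c(5, 5), y = c(5, 25), population = NA_real_)
  residences$polygon <- list(sq(5, 5), sq(5, 25))
  roads <- data.frame(x1 = c(2, 2), y1 = c(5, 25), x2 = c(8, 8),
                      y2 = c(5, 25))
  water_access <- data.frame(id = c("Wa", "Wb"), kind = c("dock", "dock"),
                             x = c(5, 5), y = c(0, 20))
  facilities <- data.frame(
    id = c("Fa", "Fb"), kind = c("puskesmas", "puskesmas"),
    district_id = c("D1", "D2"), x = c(2, 2), y = c(5, 25),
    physicians = c(1, 0), nurses = c(5, 3), midwives = c(2, 1))
  study_region(districts, islands, residences, roads, water_access,
               facilities)
}
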