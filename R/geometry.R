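# Planar geometry primitives. All coordinates are projected, in kilometres.
# Polygons are n x 2 matrices of vertices of a single exterior ring, listed
# without repeating the first vertex; orientation is irrelevant.

#' Coerce a polygon argument to an n x 2 coordinate matrix
#' @noRd
as_ring <- function(polygon) {
  m <- as.matrix(polygon)
  if (ncol(m) != 2 || nrow(m) < 3 || !is.numeric(m)) {
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  }
  # drop an explicitly closed ring's duplicate last vertex
  if (nrow(m) > 3 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Test whether a polygon ring is simple (non-self-intersecting)
#'
#' Adjacent edges sharing one endpoint are permitted; any other crossing or
#' overlap makes the ring non-simple.
#'
#' @param polygon an n x 2 numeric matrix of ring vertices.
#' @return `TRUE` or `FALSE`.
#' @export
polygon_is_simple <- function(polygon) {
  p <- as_ring(polygon)
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Polygon area by the shoelace formula
#'
#' @param polygon an n x 2 numeric matrix of ring vertices (km).
#' @return area in km^2, always non-negative.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(polygon) {
  p <- as_ring(polygon)
  if (!polygon_is_simple(p)) stop("invalid geometry: polygon is self-intersecting")
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Area centroid of a simple polygon
#'
#' @param polygon an n x 2 numeric matrix of ring vertices (km).
#' @return length-2 numeric vector `c(x, y)`.
#' @export
polygon_centroid <- function(polygon) {
  p <- as_ring(polygon)
  if (!polygon_is_simple(p)) stop("invalid geometry: polygon is self-intersecting")
  n <- nrow(p)
  j <- c(2:n, 1)
  cross <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon: zero area")
  cx <- sum((p[, 1] + p[j, 1]) * cross) / (6 * a)
  cy <- sum((p[, 2] + p[j, 2]) * cross) / (6 * a)
  c(cx, cy)
}

#' Point-in-polygon test (even-odd rule), vectorised over points
#'
#' Points on the boundary may be classified either way (ray-casting); callers
#' that care about boundary points should test them separately.
#'
#' @param x,y numeric vectors of point coordinates.
#' @param polygon an n x 2 numeric matrix of ring vertices.
#' @return logical vector.
#' @export
points_in_polygon <- function(x, y, polygon) {
  p <- as_ring(polygon)
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    xi <- p[k, 1]; yi <- p[k, 2]
    xj <- p[j[k], 1]; yj <- p[j[k], 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Euclidean distance from points to a segment, vectorised over points
#' @noRd
point_segment_distance <- function(x, y, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx * dx + dy * dy, 1e-18)
  t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
  sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
}

#' Project a point onto a segment; returns list(point, t, dist)
#' @noRd
project_on_segment <- function(p, a, b) {
  d <- b - a
  len2 <- sum(d * d)
  t <- if (len2 < 1e-18) 0 else max(0, min(1, sum((p - a) * d) / len2))
  q <- a + t * d
  list(point = q, t = t, dist = sqrt(sum((p - q)^2)))
}

# signed orientation of triple (a,b,c): >0 counter-clockwise
orient2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

#' Do two closed segments intersect at all (including touching)?
#' @noRd
segments_intersect <- function(a, b, c, d) {
  d1 <- orient2(c[1], c[2], d[1], d[2], a[1], a[2])
  d2 <- orient2(c[1], c[2], d[1], d[2], b[1], b[2])
  d3 <- orient2(a[1], a[2], b[1], b[2], c[1], c[2])
  d4 <- orient2(a[1], a[2], b[1], b[2], d[1], d[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(px, py, qx, qy, rx, ry) {
    min(px, qx) - 1e-12 <= rx && rx <= max(px, qx) + 1e-12 &&
      min(py, qy) - 1e-12 <= ry && ry <= max(py, qy) + 1e-12
  }
  (d1 == 0 && on_seg(c[1], c[2], d[1], d[2], a[1], a[2])) ||
    (d2 == 0 && on_seg(c[1], c[2], d[1], d[2], b[1], b[2])) ||
    (d3 == 0 && on_seg(a[1], a[2], b[1], b[2], c[1], c[2])) ||
    (d4 == 0 && on_seg(a[1], a[2], b[1], b[2], d[1], d[2]))
}

#' Does segment p-q properly cross any edge of a set of polygon edges?
#'
#' Proper crossing means the interiors of the two segments intersect at a
#' single point with strictly opposite orientations -- touching an edge at a
#' shared endpoint or running collinearly along it does not count. Vectorised
#' over the edge set.
#'
#' @param p,q length-2 points.
#' @param ex1,ey1,ex2,ey2 numeric vectors: edge endpoints.
#' @return `TRUE` if any proper crossing exists.
#' @noRd
crosses_any_edge <- function(p, q, ex1, ey1, ex2, ey2) {
  d1 <- orient2(p[1], p[2], q[1], q[2], ex1, ey1)
  d2 <- orient2(p[1], p[2], q[1], q[2], ex2, ey2)
  d3 <- orient2(ex1, ey1, ex2, ey2, p[1], p[2])
  d4 <- orient2(ex1, ey1, ex2, ey2, q[1], q[2])
  eps <- 1e-12
  any((d1 > eps & d2 < -eps | d1 < -eps & d2 > eps) &
        (d3 > eps & d4 < -eps | d3 < -eps & d4 > eps))
}

#' Resample a closed ring at (approximately) fixed arc-length spacing
#'
#' Used to place beaches along island coastlines.
#'
#' @param polygon ring matrix.
#' @param spacing_km target spacing between consecutive points.
#' @return m x 2 matrix of boundary points.
#' @noRd
ring_points_at_spacing <- function(polygon, spacing_km) {
  p <- as_ring(polygon)
  n <- nrow(p)
  closed <- rbind(p, p[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  total <- sum(seg)
  m <- max(1L, floor(total / spacing_km))
  targets <- (seq_len(m) - 1) * total / m
  cum <- c(0, cumsum(seg))
  out <- matrix(0, m, 2)
  for (i in seq_len(m)) {
    k <- findInterval(targets[i], cum, rightmost.closed = TRUE)
    k <- min(k, n)
    t <- (targets[i] - cum[k]) / seg[k]
    out[i, ] <- closed[k, ] + t * (closed[k + 1, ] - closed[k, ])
  }
  out
}

#' Nearest point on a ring boundary to a point
#' @noRd
nearest_ring_point <- function(p, polygon) {
  ring <- as_ring(polygon)
  n <- nrow(ring)
  closed <- rbind(ring, ring[1, ])
  best <- NULL
  best_d <- Inf
  for (k in seq_len(n)) {
    pr <- project_on_segment(p, closed[k, ], closed[k + 1, ])
    if (pr$dist < best_d) {
      best_d <- pr$dist
      best <- pr$point
    }
  }
  best
}

#' Minimum distance from a point to a polygon (0 if inside)
#' @noRd
point_polygon_distance <- function(p, polygon) {
  if (points_in_polygon(p[1], p[2], polygon)) return(0)
  ring <- as_ring(polygon)
  n <- nrow(ring)
  closed <- rbind(ring, ring[1, ])
  min(point_segment_distance(p[1], p[2],
                             closed[seq_len(n), 1], closed[seq_len(n), 2],
                             closed[seq_len(n) + 1, 1], closed[seq_len(n) + 1, 2]))
}
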