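# Minimal planar vector geometry for rasterization and polygon membership.
# Features are plain lists: list(type = "line"|"polygon", coords = matrix
# (vertices x 2), class = "roads"|"water"|"fire", year = int (fire),
# unit_id = label (MU polygons)).

# distance from points (m x 2) to a polyline (v x 2); vectorized over points
points_to_polyline_dist <- function(pts, line) {
  m <- nrow(pts)
  dmin <- rep(Inf, m)
  for (s in seq_len(nrow(line) - 1L)) {
    p1 <- line[s, ]; p2 <- line[s + 1L, ]
    v <- p2 - p1
    L2 <- sum(v^2)
    if (L2 == 0) {
      d <- sqrt((pts[, 1] - p1[1])^2 + (pts[, 2] - p1[2])^2)
    } else {
      t <- ((pts[, 1] - p1[1]) * v[1] + (pts[, 2] - p1[2]) * v[2]) / L2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((pts[, 1] - (p1[1] + t * v[1]))^2 +
                  (pts[, 2] - (p1[2] + t * v[2]))^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

# even-odd ray casting; boundary points count as inside
points_in_polygon <- function(pts, poly) {
  x <- pts[, 1]; y <- pts[, 2]
  nv <- nrow(poly)
  # drop explicit closing vertex if present
  if (nv > 1L && all(poly[1, ] == poly[nv, ])) {
    poly <- poly[-nv, , drop = FALSE]; nv <- nv - 1L
  }
  inside <- rep(FALSE, length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  # boundary: within numerical tolerance of an edge
  onb <- points_to_polyline_dist(pts, rbind(poly, poly[1, , drop = FALSE])) <
    1e-9
  inside | onb
}

# do segments (a1,a2) and (b1,b2) properly intersect (incl. touching)?
segments_intersect <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
    (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r)
    d(p, q, r) == 0 && min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  on_seg(b1, b2, a1) || on_seg(b1, b2, a2) ||
    on_seg(a1, a2, b1) || on_seg(a1, a2, b2)
}

# does the straight segment p-q cross any segment of the polyline?
segment_crosses_polyline <- function(p, q, line) {
  for (s in seq_len(nrow(line) - 1L)) {
    if (segments_intersect(p, q, line[s, ], line[s + 1L, ])) return(TRUE)
  }
  FALSE
}

# distance from points to a polygon boundary (0 if inside)
points_to_polygon_dist <- function(pts, poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  d <- points_to_polyline_dist(pts, ring)
  d[points_in_polygon(pts, poly)] <- 0
  d
}
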