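# Planar geometry helpers on ring lists.
#
# A geometry is a list of "parts" (polygons); each part is a list of rings;
# each ring is an n x 2 numeric matrix of projected coordinates in metres,
# not closed (first vertex not repeated). The first ring of a part is the
# outer boundary, subsequent rings are holes. Point membership uses the
# even-odd rule over all rings, which handles holes without tracking
# orientation.

ring_area <- function(ring) abs(pracma::polyarea(ring[, 1], ring[, 2]))

# Area in m^2 of a geometry (outer rings minus holes, summed over parts).
geom_area <- function(geom) {
  sum(vapply(geom, function(part) {
    a <- vapply(part, ring_area, numeric(1))
    a[1] - sum(a[-1])
  }, numeric(1)))
}

geom_bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Even-odd point-in-geometry test for vectors of points; boundary counts in.
points_in_geom <- function(x, y, geom) {
  inside <- rep(0L, length(x))
  on_boundary <- rep(FALSE, length(x))
  for (part in geom) {
    for (ring in part) {
      res <- pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = TRUE)
      res_int <- pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = FALSE)
      inside <- inside + as.integer(res_int)
      on_boundary <- on_boundary | (res & !res_int)
    }
  }
  (inside %% 2L == 1L) | on_boundary
}

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle.
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1) n else i - 1, ]
      cin <- keep(cur); pin <- keep(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  r <- ring
  r <- clip_edge(r, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  r <- clip_edge(r, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  r <- clip_edge(r, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  r <- clip_edge(r, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  r
}

# Area of geometry lying inside an axis-aligned rectangle.
geom_area_in_rect <- function(geom, xmin, ymin, xmax, ymax) {
  sum(vapply(geom, function(part) {
    a <- vapply(part, function(ring) {
      cl <- clip_ring_rect(ring, xmin, ymin, xmax, ymax)
      if (nrow(cl) < 3) 0 else ring_area(cl)
    }, numeric(1))
    a[1] - sum(a[-1])
  }, numeric(1)))
}

# Minimum distance between a point and a segment.
pt_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2)
}

geom_vertices <- function(geom) {
  do.call(rbind, unlist(lapply(geom, function(p) p), recursive = FALSE))
}

# Minimum boundary-to-boundary distance between two geometries
# (vertex-to-segment, both directions). Adequate for adjacency tests.
geom_boundary_dist <- function(g1, g2) {
  segs <- function(geom) {
    do.call(rbind, unlist(lapply(geom, function(part) lapply(part, function(r) {
      nxt <- rbind(r[-1, , drop = FALSE], r[1, , drop = FALSE])
      cbind(r, nxt)
    })), recursive = FALSE))
  }
  d_vs <- function(v, s) {
    min(vapply(seq_len(nrow(s)), function(i)
      min(pt_seg_dist(v[, 1], v[, 2], s[i, 1], s[i, 2], s[i, 3], s[i, 4])),
      numeric(1)))
  }
  min(d_vs(geom_vertices(g1), segs(g2)), d_vs(geom_vertices(g2), segs(g1)))
}

# Repair: drop duplicated consecutive vertices and a repeated closing vertex.
clean_ring <- function(ring) {
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring[keep, , drop = FALSE]
}
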