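# Shared fixtures and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Four abutting 1 km squares in a 2 x 2 block, two departments.
four_squares <- function() {
  sq <- function(x0, y0, s = 1000) {
    list(list(matrix(c(x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s),
                     ncol = 2, byrow = TRUE)))
  }
  admin_units(unit_id = c("A1", "A2", "B1", "B2"),
              department_id = c("DA", "DA", "DB", "DB"),
              population = c(1000, 2000, 1500, 500),
              geometry = list(sq(0, 1000), sq(1000, 1000), sq(0, 0), sq(1000, 0)),
              crs_id = "test_metre")
}

const_raster <- function(value, n = 20, pixel = 100, origin_y = 2000,
                         semantics = "temperature_celsius", crs = "test_metre") {
  raster_grid(matrix(value, n, n), origin_x = 0, origin_y = origin_y,
              pixel_size = pixel, crs_id = crs, semantics = semantics)
}

# Independent ray-casting point-in-polygon (crossing number), written
# without reference to the package's geometry code or pracma.
oracle_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

oracle_in_geom <- function(px, py, geom) {
  crossings <- 0L
  for (part in geom) for (ring in part) {
    if (oracle_in_ring(px, py, ring)) crossings <- crossings + 1L
  }
  crossings %% 2L == 1L
}

# Brute-force zonal statistics: loop every pixel, ray-cast against every
# unit (bbox prefiltered), accumulate sums/counts per unit.
oracle_zonal <- function(raster, units, stat = c("mean", "fraction"),
                         numerator_codes = NULL) {
  stat <- match.arg(stat)
  bbs <- lapply(units$geometry, function(g) {
    xs <- unlist(lapply(g, function(p) lapply(p, function(r) r[, 1])))
    ys <- unlist(lapply(g, function(p) lapply(p, function(r) r[, 2])))
    c(min(xs), min(ys), max(xs), max(ys))
  })
  sums <- setNames(numeric(nrow(units)), units$unit_id)
  hits <- setNames(numeric(nrow(units)), units$unit_id)
  cnts <- setNames(numeric(nrow(units)), units$unit_id)
  for (row in seq_len(raster$n_rows)) {
    py <- raster$origin_y - (row - 0.5) * raster$pixel_size
    for (col in seq_len(raster$n_cols)) {
      v <- raster$values[row, col]
      if (v == raster$nodata || is.na(v)) next
      px <- raster$origin_x + (col - 0.5) * raster$pixel_size
      for (i in seq_len(nrow(units))) {
        bb <- bbs[[i]]
        if (px < bb[1] || px > bb[3] || py < bb[2] || py > bb[4]) next
        if (oracle_in_geom(px, py, units$geometry[[i]])) {
          id <- units$unit_id[i]
          cnts[id] <- cnts[id] + 1
          sums[id] <- sums[id] + v
          if (!is.null(numerator_codes) && v %in% numerator_codes)
            hits[id] <- hits[id] + 1
          break
        }
      }
    }
  }
  if (stat == "mean") ifelse(cnts > 0, sums / cnts, NA_real_)
  else ifelse(cnts > 0, hits / cnts, NA_real_)
}

# Plain indicator column over a fixed unit set.
ind <- function(values, name = "temperature", orientation = "risk") {
  indicator_column(name, values, orientation)
}
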