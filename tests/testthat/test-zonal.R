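# Zonal temperature reduction: temporal mean, pixel assignment, zonal mean.

test_that("temporal mean averages days and handles nodata per pixel", {
  r20 <- const_raster(20)
  r30 <- const_raster(30)
  m <- temporal_mean(list(r20, r30))
  expect_true(all(m$values == 25))

  r3 <- const_raster(28)
  r3$values[5, 5] <- r3$nodata
  m2 <- temporal_mean(list(r20, r30, r3))
  expect_equal(m2$values[5, 5], 25)          # mean of the 2 valid days
  expect_equal(m2$values[1, 1], 26)          # mean of all three

  # pixel with no valid day at all -> nodata
  ra <- const_raster(20); rb <- const_raster(30)
  ra$values[2, 2] <- ra$nodata; rb$values[2, 2] <- rb$nodata
  expect_equal(temporal_mean(list(ra, rb))$values[2, 2], ra$nodata)

  expect_error(temporal_mean(list()), class = "heatvuln_empty_input_error")
  off <- const_raster(20, origin_y = 1900)
  expect_error(temporal_mean(list(r20, off)), class = "heatvuln_alignment_error")
})

test_that("92 daily constant rasters average to the arithmetic mean", {
  consts <- seq(18, by = 0.1, length.out = 92)
  rs <- lapply(consts, const_raster, n = 5)
  m <- temporal_mean(rs)
  expect_equal(unique(as.vector(m$values)), mean(consts), tolerance = 1e-12)
})

test_that("pixel-centre assignment gives each 1 km square its 100 pixels", {
  units <- four_squares()
  r <- const_raster(25)
  asg <- assign_pixels(r, units)
  counts <- table(asg$unit)
  expect_equal(as.numeric(counts[units$unit_id]), rep(100, 4))
  expect_equal(asg$n_unassigned, 0)
})

test_that("boundary-centred pixels go to the lexicographically first unit", {
  units <- four_squares()
  # 500 m pixels starting at x = -250: centres fall at x = 0, 500, 1000, ...
  # so the first column of centres lies exactly on the shared west edge
  # and x = 1000 on the A1/A2 (B1/B2) shared edge.
  r <- raster_grid(matrix(25, 4, 5), origin_x = -250, origin_y = 2000,
                   pixel_size = 500, crs_id = "test_metre")
  asg <- assign_pixels(r, units)
  # centre (1000, 1750) sits on the A1|A2 boundary -> A1 (lexicographic)
  expect_identical(asg$unit[1, 3], "A1")
  # centre (1000, 750) sits on the B1|B2 boundary -> B1
  expect_identical(asg$unit[3, 3], "B1")
})

test_that("assignment matches a brute-force point-in-polygon oracle", {
  cfg <- synth_config(n_side = 5, cell_km = 1, pixel_m = 100, seed = 31)
  units <- make_commune_grid(cfg)
  frac <- make_true_artificial(cfg, units)
  r <- make_temperature_raster(cfg, units, frac)
  asg <- assign_pixels(r, units)
  mism <- 0
  for (row in seq(1, r$n_rows, by = 3)) {
    py <- r$origin_y - (row - 0.5) * r$pixel_size
    for (col in seq(1, r$n_cols, by = 3)) {
      px <- r$origin_x + (col - 0.5) * r$pixel_size
      hit <- NA_character_
      for (i in order(units$unit_id)) {
        if (oracle_in_geom(px, py, units$geometry[[i]])) {
          hit <- units$unit_id[i]; break
        }
      }
      if (!identical(hit, asg$unit[row, col]) && !(is.na(hit) && is.na(asg$unit[row, col])))
        mism <- mism + 1
    }
  }
  expect_equal(mism, 0)
})

test_that("zonal means match symmetry and the independent pixel-loop oracle", {
  units <- four_squares()
  expect_equal(unname(zonal_mean_temperature(const_raster(25), units)$values),
               rep(25, 4))

  # unit A1 half 20, half 30 -> 25
  r <- const_raster(20)
  r$values[1:10, 1:5] <- 30  # west half of A1 (rows 1-10, cols 1-5)
  zt <- zonal_mean_temperature(r, units)
  expect_equal(zt$values[["A1"]], 25)

  jit <- const_raster(22)
  set.seed(99)
  jit$values <- jit$values + matrix(rnorm(400), 20, 20)
  jit$values[4, 4] <- jit$nodata
  got <- zonal_mean_temperature(jit, units)$values
  want <- oracle_zonal(jit, units, "mean")
  expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-9)
})

test_that("units with no valid pixel are flagged missing, not zero-filled", {
  units <- four_squares()
  r <- const_raster(25)
  r$values[1:10, 1:10] <- r$nodata  # wipe all of A1
  zt <- zonal_mean_temperature(r, units)
  expect_true("A1" %in% zt$missing)
  expect_true(is.na(zt$values[["A1"]]))
  expect_equal(zt$values[["A2"]], 25)
})

test_that("zonal reduction conserves sums and respects invariances", {
  cfg <- synth_config(n_side = 4, cell_km = 1, pixel_m = 100, seed = 17)
  units <- make_commune_grid(cfg)
  frac <- make_true_artificial(cfg, units)
  r <- make_temperature_raster(cfg, units, frac)
  asg <- assign_pixels(r, units)
  zt <- zonal_mean_temperature(r, units, asg)
  npx <- attr(zt, "n_pixels")
  valid <- r$values != r$nodata & !is.na(asg$unit)
  expect_equal(sum(zt$values * npx, na.rm = TRUE), sum(r$values[valid]),
               tolerance = 1e-6 * abs(sum(r$values[valid])))

  # translation invariance: shift both layers by the same offset
  shifted_units <- units
  shifted_units$geometry <- lapply(units$geometry, function(g)
    lapply(g, function(p) lapply(p, function(rr) rr + 12345)))
  r2 <- r; r2$origin_x <- r$origin_x + 12345; r2$origin_y <- r$origin_y + 12345
  zt2 <- zonal_mean_temperature(r2, shifted_units)
  expect_equal(zt2$values, zt$values, tolerance = 1e-9)

  # adding c to every pixel adds exactly c to every unit mean
  r3 <- r; r3$values[r$values != r$nodata] <- r$values[r$values != r$nodata] + 3
  zt3 <- zonal_mean_temperature(r3, units, asg)
  expect_equal(unname(zt3$values - zt$values),
               rep(3, length(zt$values)), tolerance = 1e-9)
})
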