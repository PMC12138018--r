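# Synthetic-data generators: known latent structure, determinism.

test_that("commune grid tiles the study rectangle as configured", {
  units <- make_commune_grid(synth_config(n_side = 2, cell_km = 1, seed = 1))
  expect_equal(nrow(units), 4)
  expect_equal(units$area_km2, rep(1, 4), tolerance = 1e-12)

  units10 <- make_commune_grid(synth_config(n_side = 10, seed = 1))
  expect_equal(nrow(units10), 100)
  expect_equal(length(unique(units10$unit_id)), 100)
  expect_equal(mean(units10$area_km2), 14.9, tolerance = 1e-9)
})

test_that("generators are deterministic for a fixed seed", {
  cfg <- synth_config(n_side = 4, cell_km = 1, seed = 42, n_days = 2)
  a <- make_synthetic_inputs(cfg)
  b <- make_synthetic_inputs(cfg)
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_units(a$units, f1); write_units(b$units, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$landcover$values, b$landcover$values)
  expect_identical(a$temperature[[2]]$values, b$temperature[[2]]$values)
  expect_identical(as.data.frame(a$socio), as.data.frame(b$socio))
  expect_identical(a$ac_rates, b$ac_rates)
  expect_identical(as.data.frame(a$visits), as.data.frame(b$visits))
})

test_that("urban fraction decreases radially from the grid centre", {
  cfg <- synth_config(n_side = 9, cell_km = 1, seed = 5)
  units <- make_commune_grid(cfg)
  frac <- make_true_artificial(cfg, units)
  expect_true(all(frac >= 0 & frac <= 1))
  centre <- frac[["02014"]]  # row 5, col 5 = grid centre
  corner <- frac[["01001"]]
  expect_gt(centre, corner)
  # noise-free radial profile is monotone along a ray from the centre
  prof <- attr(frac, "profile")
  mid_row <- prof[sprintf("02%03d", 10:18)]  # row 5, cols 1..9
  expect_true(all(diff(mid_row[5:9]) <= 1e-12))
  # jitter stays within a few SDs of the profile
  expect_lt(max(abs(frac - pmin(1, pmax(0, prof)))), 6 * cfg$artif_jitter_sd)
})

test_that("land-cover raster realises the true fraction to within one pixel", {
  cfg <- synth_config(n_side = 3, cell_km = 2, pixel_m = 100, seed = 8)
  units <- make_commune_grid(cfg)
  frac <- setNames(c(1, 0, 0.25, 0.5, 0.9, 0.1, 0.33, 0.66, 0), units$unit_id)
  lc <- make_landcover_raster(cfg, units, frac)
  asg <- assign_pixels(lc, units)
  for (i in seq_len(nrow(units))) {
    px <- lc$values[which(asg$unit == units$unit_id[i])]
    px <- px[px != lc$nodata]
    n_art <- sum(px == 112)
    expect_lte(abs(n_art - frac[i] * length(px)), 1)
  }
  # extremes are exact
  expect_true(all(lc$values[which(asg$unit == units$unit_id[1])] == 112))
  expect_true(all(lc$values[which(asg$unit == units$unit_id[2])] == 311))
})

test_that("a finer pixel than the commune side is required", {
  expect_error(synth_config(n_side = 2, cell_km = 0.05, pixel_m = 100),
               class = "heatvuln_resolution_error")
})

test_that("temperature field is the closed-form urban-heat-island surface", {
  cfg <- synth_config(n_side = 3, cell_km = 1, pixel_m = 100,
                      noise_sd_c = 0, uhi_coeff = 0, seed = 2)
  units <- make_commune_grid(cfg)
  frac <- make_true_artificial(cfg, units)
  r0 <- make_temperature_raster(cfg, units, frac)
  v <- r0$values[r0$values != r0$nodata]
  expect_equal(v, rep(cfg$base_temp_c, length(v)))

  cfg2 <- synth_config(n_side = 3, cell_km = 1, pixel_m = 100,
                       noise_sd_c = 0, uhi_coeff = 4, seed = 2)
  r <- make_temperature_raster(cfg2, units, frac)
  zt <- zonal_mean_temperature(r, units)
  expect_equal(unname(zt$values[units$unit_id]),
               unname(cfg2$base_temp_c + 4 * frac[units$unit_id]),
               tolerance = 1e-9)
})

test_that("socioeconomic components reflect the one-factor model", {
  cfg <- synth_config(n_side = 23, cell_km = 1, seed = 11)  # 529 communes
  units <- make_commune_grid(cfg)
  tab <- make_socioeconomic_table(cfg, units)
  expect_gt(cor(tab$unemployment_rate, tab$latent_deprivation), 0)
  expect_gt(cor(tab$blue_collar_pct, tab$latent_deprivation), 0)
  expect_lt(cor(tab$graduates_pct, tab$latent_deprivation), 0)
  expect_lt(cor(tab$median_income, tab$latent_deprivation), 0)
  # zero noise: each component is an exact affine image of the latent factor
  tab0 <- make_socioeconomic_table(cfg, units, noise_sd = 0)
  expect_equal(abs(cor(tab0$unemployment_rate, tab0$latent_deprivation)), 1,
               tolerance = 1e-12)
  expect_equal(abs(cor(tab0$median_income, tab0$latent_deprivation)), 1,
               tolerance = 1e-12)
})

test_that("AC rates follow temperature and stay in [0, 100]", {
  cfg <- synth_config(n_side = 3, cell_km = 1, ac_noise_sd = 0, seed = 4)
  units <- make_commune_grid(cfg)
  temps <- setNames(seq(20, 28, length.out = 9), units$unit_id)
  rates <- make_ac_rates(cfg, units, temps)
  expect_true(all(diff(rates[order(temps)]) >= 0))
  cfg0 <- synth_config(n_side = 3, cell_km = 1, ac_slope = 0, ac_noise_sd = 0)
  expect_equal(unname(make_ac_rates(cfg0, units, temps)),
               rep(cfg0$ac_intercept, 9))
  cfg_hot <- synth_config(n_side = 3, cell_km = 1, ac_slope = 1e6, ac_noise_sd = 50)
  r <- make_ac_rates(cfg_hot, units, temps)
  expect_true(all(r >= 0 & r <= 100))
})

test_that("visit counts follow the Poisson rate model", {
  cfg <- synth_config(n_side = 4, cell_km = 1, visit_effect = 0,
                      visit_base_rate = 5, seed = 9)
  units <- make_commune_grid(cfg)
  vuln <- setNames(rep(0, nrow(units)), units$unit_id)
  mu_total <- sum(units$population) / 1e4 * cfg$visit_base_rate
  counts <- vapply(seq_len(200), function(i)
    nrow(make_visit_records(cfg, units, vuln, stream = i)), numeric(1))
  se <- sqrt(mu_total / 200)
  expect_lt(abs(mean(counts) - mu_total), 3 * se)

  cfg0 <- synth_config(n_side = 4, cell_km = 1, visit_base_rate = 0, seed = 9)
  expect_equal(nrow(make_visit_records(cfg0, units, vuln)), 0)

  v <- make_visit_records(cfg, units, vuln)
  expect_true(all(v$cause_code %in% cfg$cause_codes))
  expect_true(all(v$date >= cfg$window[1] & v$date <= cfg$window[2]))
  expect_true(all(v$source %in% c("emergency_department", "emergency_gp")))
})
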