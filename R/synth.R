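#' Synthetic study configuration
#'
#' Parameters of the synthetic geodata generator. The generator emulates
#' the statistical structure the vulnerability index assumes: an urban
#' heat island (surface temperature rising with the artificial surface
#' fraction), a one-factor deprivation model behind the four
#' socioeconomic variables, air-conditioning uptake increasing with
#' local summer temperature, and Poisson heat-morbidity visit counts
#' increasing with true vulnerability.
#'
#' Defaults define the reference study conditions: a 10 x 10 commune
#' grid with cell side sqrt(14.9) km, so every commune has exactly the
#' national mean commune area of 14.9 km2; a 3 degC urban-heat-island
#' amplitude on a 22 degC summer baseline with 0.5 degC pixel noise;
#' one-factor loadings (+1, +1, -1, -1) for unemployment, blue-collar,
#' graduates and income; AC uptake of 2 percentage points per degC above
#' baseline around a 15% intercept; and 5 expected summer visits per
#' 10 000 residents at average vulnerability, scaled by
#' exp(0.5 x vulnerability).
#'
#' @param n_side communes per grid side (n_side^2 communes), >= 2.
#' @param cell_km commune side length, km.
#' @param pixel_m raster resolution, metres.
#' @param base_temp_c baseline summer surface temperature, degC.
#' @param uhi_coeff degC added per unit artificial fraction.
#' @param noise_sd_c per-pixel temperature noise SD, degC.
#' @param artif_jitter_sd SD of the jitter on the radial urban gradient.
#' @param fdep_loadings 4 signed loadings for unemployment, blue-collar,
#'   graduates, income (latent-factor model).
#' @param socio_noise_sd component noise SD on the latent scale of the
#'   one-factor socioeconomic model.
#' @param ac_intercept AC equipment rate at baseline temperature, %.
#' @param ac_slope AC-rate dependence on temperature, % per degC.
#' @param ac_noise_sd AC-rate noise SD, percentage points.
#' @param visit_base_rate expected visits per 10 000 residents over the
#'   season at average vulnerability.
#' @param visit_effect multiplicative log-scale effect of standardised
#'   vulnerability on the visit rate.
#' @param cause_codes cause codes sampled for synthetic visits.
#' @param window summer window visits are drawn from (closed).
#' @param n_days number of daily temperature rasters to simulate.
#' @param seed integer seed; every generator derives its own stream from
#'   (seed, generator-name), so adding a generator never perturbs the
#'   draws of another.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_side = 10, cell_km = sqrt(14.9), pixel_m = 100,
                         base_temp_c = 22, uhi_coeff = 3, noise_sd_c = 0.5,
                         artif_jitter_sd = 0.02,
                         fdep_loadings = c(unemployment_rate = 1,
                                           blue_collar_pct = 1,
                                           graduates_pct = -1,
                                           median_income = -1),
                         socio_noise_sd = 0.5,
                         ac_intercept = 15, ac_slope = 2, ac_noise_sd = 3,
                         visit_base_rate = 5, visit_effect = 0.5,
                         cause_codes = c("T67.0", "T67.9", "E86", "E87.1"),
                         window = as.Date(c("2022-06-01", "2022-08-31")),
                         n_days = 7, seed = 1L) {
  if (n_side < 2) hv_abort("heatvuln_config_error", "n_side must be >= 2")
  if (cell_km <= 0) hv_abort("heatvuln_config_error", "cell_km must be > 0")
  if (noise_sd_c < 0) hv_abort("heatvuln_config_error", "noise_sd_c must be >= 0")
  if (visit_base_rate < 0)
    hv_abort("heatvuln_config_error", "visit_base_rate must be >= 0")
  if (pixel_m > cell_km * 1000)
    hv_abort("heatvuln_resolution_error",
             "pixel size larger than commune side")
  structure(list(n_side = n_side, cell_km = cell_km, pixel_m = pixel_m,
                 base_temp_c = base_temp_c, uhi_coeff = uhi_coeff,
                 noise_sd_c = noise_sd_c, artif_jitter_sd = artif_jitter_sd,
                 fdep_loadings = fdep_loadings, socio_noise_sd = socio_noise_sd,
                 ac_intercept = ac_intercept,
                 ac_slope = ac_slope, ac_noise_sd = ac_noise_sd,
                 visit_base_rate = visit_base_rate, visit_effect = visit_effect,
                 cause_codes = cause_codes, window = as.Date(window),
                 n_days = n_days, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic commune grid
#'
#' Tiles a rectangle with n_side^2 square communes of side `cell_km`.
#' Departments are assigned in horizontal bands of three grid rows; unit
#' ids follow the French five-digit convention `DDCCC` (department
#' number then a within-department counter), so leading zeros exercise
#' the opaque-identifier contract. Populations are log-normal
#' (median about 1500, so a mix of villages and towns), seeded.
#'
#' @param cfg a [synth_config].
#' @return An [admin_units] object with crs `"synthetic_metre"`.
#' @export
make_commune_grid <- function(cfg) {
  n <- cfg$n_side
  cell <- cfg$cell_km * 1000
  rows <- rep(seq_len(n), each = n)
  cols <- rep(seq_len(n), times = n)
  dept_num <- 1L + (rows - 1L) %/% 3L
  counter <- stats::ave(seq_along(rows), dept_num, FUN = seq_along)
  unit_id <- sprintf("%02d%03d", dept_num, counter)
  geometry <- lapply(seq_along(rows), function(i) {
    x0 <- (cols[i] - 1) * cell; x1 <- cols[i] * cell
    y1 <- (n - rows[i] + 1) * cell; y0 <- y1 - cell
    list(list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1),
                     ncol = 2, byrow = TRUE)))
  })
  population <- with_stream(cfg$seed, "population",
                            round(stats::rlnorm(n * n, log(1500), 1)) + 1)
  admin_units(unit_id = unit_id,
              name = sprintf("Commune %s", unit_id),
              department_id = sprintf("D%02d", dept_num),
              population = population,
              geometry = geometry,
              crs_id = "synthetic_metre")
}

# Noise-free radial urban gradient used by make_true_artificial:
# 0.9 at the grid centre falling to 0.05 at the farthest commune centre.
artificial_profile <- function(cfg, units) {
  cell <- cfg$cell_km * 1000
  centres <- t(vapply(units$geometry, function(g) {
    bb <- geom_bbox(g); c((bb["xmin"] + bb["xmax"]) / 2, (bb["ymin"] + bb["ymax"]) / 2)
  }, numeric(2)))
  mid <- cfg$n_side * cell / 2
  d <- sqrt((centres[, 1] - mid)^2 + (centres[, 2] - mid)^2)
  dn <- d / max(d)
  setNames(0.05 + 0.85 * (1 - dn)^2, units$unit_id)
}

#' True artificial-surface fractions
#'
#' A radially decreasing urban fraction from the grid centre (about 0.9
#' at the centre, 0.05 at the edge) with seeded Gaussian jitter, clipped
#' to `[0, 1]`. This is the latent urbanisation driving both the
#' land-cover raster and the urban-heat-island temperature field.
#'
#' @param cfg a [synth_config].
#' @param units communes from [make_commune_grid()].
#' @return Named vector unit_id -> fraction in `[0, 1]`, with the
#'   noise-free radial profile attached as attribute `profile`.
#' @export
make_true_artificial <- function(cfg, units) {
  prof <- artificial_profile(cfg, units)
  jit <- with_stream(cfg$seed, "artificial",
                     stats::rnorm(nrow(units), 0, cfg$artif_jitter_sd))
  out <- setNames(pmin(1, pmax(0, prof + jit)), units$unit_id)
  attr(out, "profile") <- prof
  out
}

#' Synthetic CORINE-coded land-cover raster
#'
#' Rasterises the true artificial fractions: inside each commune, a
#' seeded random subset of pixels (rounded to the nearest pixel count)
#' carries an artificial code (112, discontinuous urban fabric) and the
#' rest a vegetated code (311, broad-leaved forest), so the per-commune
#' artificial proportion equals the true fraction to within one pixel.
#'
#' @param cfg a [synth_config].
#' @param units communes from [make_commune_grid()].
#' @param true_artificial named fractions from [make_true_artificial()].
#' @param artificial_code,vegetated_code the two class codes written.
#' @return A `landcover_code` [raster_grid] covering the commune grid.
#' @export
make_landcover_raster <- function(cfg, units, true_artificial,
                                  artificial_code = 112, vegetated_code = 311) {
  geo <- synth_raster_geometry(cfg)
  vals <- matrix(vegetated_code, geo$n_rows, geo$n_cols)
  cidx <- commune_of_pixels(cfg, geo)
  with_stream(cfg$seed, "landcover", {
    for (i in seq_len(nrow(units))) {
      px <- which(cidx == i)
      k <- round(length(px) * true_artificial[[units$unit_id[i]]])
      if (k > 0) vals[sample(px, k)] <- artificial_code
    }
  })
  vals[is.na(cidx)] <- -9999
  raster_grid(vals, geo$origin_x, geo$origin_y, cfg$pixel_m,
              nodata = -9999, crs_id = "synthetic_metre",
              semantics = "landcover_code")
}

# Shared raster frame covering the commune grid exactly.
synth_raster_geometry <- function(cfg) {
  extent <- cfg$n_side * cfg$cell_km * 1000
  npx <- ceiling(extent / cfg$pixel_m - 1e-9)
  list(origin_x = 0, origin_y = extent, n_rows = npx, n_cols = npx)
}

# Analytic pixel-centre -> commune-index map for the square tiling
# (independent of assign_pixels, so generator truth does not rest on the
# implementation under test). Returns row-index into the unit table.
commune_of_pixels <- function(cfg, geo) {
  cell <- cfg$cell_km * 1000
  n <- cfg$n_side
  cx <- (seq_len(geo$n_cols) - 0.5) * cfg$pixel_m
  cy <- geo$origin_y - (seq_len(geo$n_rows) - 0.5) * cfg$pixel_m
  col_of <- floor(cx / cell) + 1
  row_of <- n - floor(cy / cell)
  m <- outer(row_of, col_of, function(r, c)
    ifelse(r >= 1 & r <= n & c >= 1 & c <= n, (r - 1) * n + c, NA_real_))
  m
}

#' Synthetic daily surface-temperature raster
#'
#' Pixel temperature = `base_temp_c` (plus an optional day offset) +
#' `uhi_coeff` x artificial fraction of the pixel's commune + Gaussian
#' noise of SD `noise_sd_c`, seeded. With zero noise the zonal mean of a
#' commune equals base + uhi x fraction exactly.
#'
#' @param cfg a [synth_config].
#' @param units communes from [make_commune_grid()].
#' @param true_artificial named fractions from [make_true_artificial()].
#' @param day integer day index; offsets the seed stream and adds a
#'   small deterministic day-to-day baseline wobble.
#' @return A `temperature_celsius` [raster_grid].
#' @export
make_temperature_raster <- function(cfg, units, true_artificial, day = 1) {
  geo <- synth_raster_geometry(cfg)
  cidx <- commune_of_pixels(cfg, geo)
  frac <- unname(true_artificial[units$unit_id])
  base_day <- cfg$base_temp_c + 1.5 * sinpi(2 * (day - 1) / 30)
  vals <- matrix(base_day, geo$n_rows, geo$n_cols) +
    matrix(ifelse(is.na(cidx), 0, cfg$uhi_coeff * frac[cidx]),
           geo$n_rows, geo$n_cols)
  if (cfg$noise_sd_c > 0) {
    noise <- with_stream(cfg$seed, paste0("temperature_day", day),
                         stats::rnorm(length(vals), 0, cfg$noise_sd_c))
    vals <- vals + matrix(noise, geo$n_rows, geo$n_cols)
  }
  vals[is.na(cidx)] <- -9999
  raster_grid(vals, geo$origin_x, geo$origin_y, cfg$pixel_m,
              nodata = -9999, crs_id = "synthetic_metre",
              semantics = "temperature_celsius")
}

#' Synthetic socioeconomic table with a one-factor deprivation model
#'
#' Draws a latent deprivation factor d_i ~ Normal(0, 1) per commune and
#' builds each component as loading x d_i + Normal(0, 0.5) on the latent
#' scale, then maps components onto realistic measurement scales with
#' fixed affine transforms (unemployment around 30%, blue-collar around
#' 45%, graduates around 50%, income around 21 000). Affine maps leave
#' the correlation-matrix principal component unchanged, so the score
#' recovers the latent factor exactly when `noise_sd = 0`. The latent
#' factor is returned in the `latent_deprivation` column, which is
#' test-only ground truth, not an observable input.
#'
#' @param cfg a [synth_config].
#' @param units communes from [make_commune_grid()].
#' @param noise_sd component noise SD on the latent scale (defaults to
#'   the config's `socio_noise_sd`).
#' @return A [socio_table] with an extra `latent_deprivation` column.
#' @export
make_socioeconomic_table <- function(cfg, units, noise_sd = cfg$socio_noise_sd) {
  n <- nrow(units)
  l <- cfg$fdep_loadings
  comp <- with_stream(cfg$seed, "socio", {
    d <- stats::rnorm(n)
    cbind(d = d,
          vapply(1:4, function(k) l[[k]] * d + stats::rnorm(n, 0, noise_sd),
                 numeric(n)))
  })
  d <- comp[, 1]
  socio_table(data.frame(
    unit_id = units$unit_id,
    unemployment_rate = 30 + 4 * comp[, 2],
    blue_collar_pct = 45 + 6 * comp[, 3],
    graduates_pct = 50 + 7 * comp[, 4],
    median_income = 21000 + 3000 * comp[, 5],
    latent_deprivation = d,
    stringsAsFactors = FALSE))
}

#' Synthetic air-conditioning equipment rates
#'
#' Rate = `ac_intercept` + `ac_slope` x (zonal temperature - baseline) +
#' seeded Gaussian noise, clipped to `[0, 100]` %. Hotter communes are
#' better equipped, making AC the protective indicator correlated with
#' exposure, as in real uptake data.
#'
#' @param cfg a [synth_config].
#' @param units communes from [make_commune_grid()].
#' @param zonal_temp named per-commune temperature (degC), e.g. the
#'   `values` of [zonal_mean_temperature()] or the generator's own
#'   expected temperatures.
#' @return Named vector unit_id -> rate in `[0, 100]` (%).
#' @export
make_ac_rates <- function(cfg, units, zonal_temp) {
  noise <- if (cfg$ac_noise_sd > 0)
    with_stream(cfg$seed, "ac", stats::rnorm(nrow(units), 0, cfg$ac_noise_sd))
  else rep(0, nrow(units))
  raw <- cfg$ac_intercept + cfg$ac_slope * (zonal_temp[units$unit_id] - cfg$base_temp_c) + noise
  setNames(pmin(100, pmax(0, unname(raw))), units$unit_id)
}

#' True standardised vulnerability of the synthetic communes
#'
#' Ground truth the generator feeds to the visit model: the equal-weight
#' combination of the noise-free drivers (expected commune temperature,
#' latent deprivation, artificial fraction, minus expected AC rate),
#' each standardised, then standardised again to unit variance.
#'
#' @param cfg a [synth_config].
#' @param units communes from [make_commune_grid()].
#' @param true_artificial named fractions from [make_true_artificial()].
#' @param latent_deprivation latent factor from
#'   [make_socioeconomic_table()] (its `latent_deprivation` column).
#' @return Named vector unit_id -> standardised true vulnerability.
#' @export
make_true_vulnerability <- function(cfg, units, true_artificial,
                                    latent_deprivation) {
  frac <- unname(true_artificial[units$unit_id])
  temp_exp <- cfg$base_temp_c + cfg$uhi_coeff * frac
  ac_exp <- pmin(100, pmax(0, cfg$ac_intercept + cfg$ac_slope * (temp_exp - cfg$base_temp_c)))
  v <- (pop_scale(temp_exp) + pop_scale(latent_deprivation) +
          pop_scale(frac) - pop_scale(ac_exp)) / 4
  setNames(pop_scale(v), units$unit_id)
}

#' Synthetic heat-morbidity visit records
#'
#' Per commune, the seasonal visit count is Poisson with mean
#' population / 10 000 x `visit_base_rate` x exp(`visit_effect` x
#' vulnerability). Each visit gets a cause code drawn uniformly from the
#' configured heat-cause set, source emergency department or emergency
#' GP with probability 0.7 / 0.3, and a date uniform over the summer
#' window. Fully seeded.
#'
#' @param cfg a [synth_config].
#' @param units communes from [make_commune_grid()].
#' @param true_vulnerability named standardised vulnerability.
#' @param stream suffix added to the seed stream, letting callers draw
#'   independent replicates without touching the other generators.
#' @return A [visit_records] table.
#' @export
make_visit_records <- function(cfg, units, true_vulnerability, stream = "") {
  mu <- units$population / 1e4 * cfg$visit_base_rate *
    exp(cfg$visit_effect * unname(true_vulnerability[units$unit_id]))
  with_stream(cfg$seed, paste0("visits", stream), {
    counts <- stats::rpois(nrow(units), mu)
    n <- sum(counts)
    uid <- rep(units$unit_id, counts)
    days <- as.integer(cfg$window[2] - cfg$window[1])
    visit_records(data.frame(
      unit_id = uid,
      date = cfg$window[1] + sample.int(days + 1, n, replace = TRUE) - 1,
      source = sample(c("emergency_department", "emergency_gp"), n,
                      replace = TRUE, prob = c(0.7, 0.3)),
      cause_code = sample(cfg$cause_codes, n, replace = TRUE),
      stringsAsFactors = FALSE))
  })
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator in sequence and returns the complete set of
#' pipeline inputs plus the latent ground truth (artificial fractions,
#' latent deprivation, true vulnerability) used by recovery tests.
#'
#' @param cfg a [synth_config].
#' @return List: `units`, `landcover` raster, `temperature` raster list
#'   (length `n_days`), `socio` table, `ac_rates`, `visits`, and a
#'   `truth` list (test-only latent quantities).
#' @export
make_synthetic_inputs <- function(cfg = synth_config()) {
  units <- make_commune_grid(cfg)
  frac <- make_true_artificial(cfg, units)
  lc <- make_landcover_raster(cfg, units, frac)
  temps <- lapply(seq_len(cfg$n_days), function(d)
    make_temperature_raster(cfg, units, frac, day = d))
  socio <- make_socioeconomic_table(cfg, units)
  temp_exp <- setNames(cfg$base_temp_c + cfg$uhi_coeff * unname(frac[units$unit_id]),
                       units$unit_id)
  ac <- make_ac_rates(cfg, units, temp_exp)
  vuln <- make_true_vulnerability(cfg, units, frac, socio$latent_deprivation)
  visits <- make_visit_records(cfg, units, vuln)
  list(units = units, landcover = lc, temperature = temps,
       socio = socio, ac_rates = ac, visits = visits,
       truth = list(artificial = frac, latent_deprivation =
                      setNames(socio$latent_deprivation, units$unit_id),
                    vulnerability = vuln, expected_temperature = temp_exp))
}
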