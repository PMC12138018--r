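#' Temporal mean of daily temperature rasters
#'
#' Reduces a list of co-registered daily rasters to one per-pixel mean,
#' ignoring nodata days; a pixel with no valid day becomes nodata. The
#' pipeline averages over time first and reduces zonally second (the two
#' orders agree only in the absence of nodata, so the order is fixed and
#' documented).
#'
#' @param rasters non-empty list of [raster_grid] objects sharing grid
#'   geometry, crs and `temperature_celsius` semantics.
#' @return A [raster_grid] of per-pixel means.
#' @export
temporal_mean <- function(rasters) {
  if (length(rasters) == 0)
    hv_abort("heatvuln_empty_input_error", "no rasters to average")
  ref <- rasters[[1]]
  for (r in rasters) {
    if (r$semantics != "temperature_celsius")
      hv_abort("heatvuln_schema_error", "temporal_mean expects temperature rasters")
    same <- identical(c(r$n_rows, r$n_cols), c(ref$n_rows, ref$n_cols)) &&
      isTRUE(all.equal(c(r$origin_x, r$origin_y, r$pixel_size),
                       c(ref$origin_x, ref$origin_y, ref$pixel_size))) &&
      identical(r$crs_id, ref$crs_id)
    if (!same)
      hv_abort("heatvuln_alignment_error", "rasters do not share grid geometry")
  }
  acc <- matrix(0, ref$n_rows, ref$n_cols)
  cnt <- matrix(0L, ref$n_rows, ref$n_cols)
  for (r in rasters) {
    valid <- r$values != r$nodata & !is.na(r$values)
    acc[valid] <- acc[valid] + r$values[valid]
    cnt <- cnt + valid
  }
  out <- acc / cnt
  out[cnt == 0] <- ref$nodata
  raster_grid(out, ref$origin_x, ref$origin_y, ref$pixel_size,
              nodata = ref$nodata, crs_id = ref$crs_id,
              semantics = "temperature_celsius")
}

#' Assign raster pixels to administrative units
#'
#' Implements the pixel-centre rule: a pixel belongs to the unit whose
#' polygon contains its centre point. If the centre lies exactly on a
#' shared boundary, the unit earliest in `unit_id` lexicographic order
#' wins, making the assignment deterministic under any unit ordering.
#' Pixels inside no unit remain unassigned.
#'
#' @param raster a [raster_grid].
#' @param units an [admin_units] object in the same reference system.
#' @return A `zonal_assignment`: list with `unit` (an
#'   `n_rows` x `n_cols` character matrix of unit ids, `NA` where
#'   unassigned), `n_unassigned`, and `rule`.
#' @export
assign_pixels <- function(raster, units) {
  if (!identical(raster$crs_id, units_crs(units)))
    hv_abort("heatvuln_alignment_error", "crs mismatch between raster and units")
  pc <- pixel_centres(raster)
  assign <- matrix(NA_character_, raster$n_rows, raster$n_cols)
  ord <- order(units$unit_id, method = "radix")
  for (i in ord) {
    g <- units$geometry[[i]]
    bb <- geom_bbox(g)
    cols <- which(pc$x >= bb["xmin"] - raster$pixel_size &
                  pc$x <= bb["xmax"] + raster$pixel_size)
    rows <- which(pc$y >= bb["ymin"] - raster$pixel_size &
                  pc$y <= bb["ymax"] + raster$pixel_size)
    if (!length(cols) || !length(rows)) next
    grid <- expand.grid(row = rows, col = cols)
    free <- is.na(assign[cbind(grid$row, grid$col)])
    grid <- grid[free, , drop = FALSE]
    if (!nrow(grid)) next
    inside <- points_in_geom(pc$x[grid$col], pc$y[grid$row], g)
    hit <- grid[inside, , drop = FALSE]
    if (nrow(hit))
      assign[cbind(hit$row, hit$col)] <- units$unit_id[i]
  }
  structure(list(unit = assign,
                 n_unassigned = sum(is.na(assign)),
                 rule = "pixel-centre-in-polygon; boundary tie to lexicographically first unit_id"),
            class = "zonal_assignment")
}

# Shared zonal reduction: per-unit mean of valid pixel values.
zonal_reduce_mean <- function(raster, units, assignment) {
  valid <- raster$values != raster$nodata & !is.na(raster$values)
  u <- assignment$unit
  keep <- !is.na(u) & valid
  sums <- tapply(raster$values[keep], u[keep], sum)
  cnts <- tapply(rep(1, sum(keep)), u[keep], sum)
  means <- setNames(rep(NA_real_, nrow(units)), units$unit_id)
  n_pix <- setNames(rep(0, nrow(units)), units$unit_id)
  means[names(sums)] <- sums / cnts
  n_pix[names(cnts)] <- cnts
  list(mean = means, n_pixels = n_pix)
}

#' Zonal mean temperature per unit
#'
#' Averages the (temporally averaged) surface-temperature raster over the
#' pixels assigned to each unit. Units with no valid pixel are flagged
#' missing rather than zero-filled: 0 degC is a valid temperature and a
#' silent fill would corrupt the downstream Z-scores.
#'
#' @param raster a `temperature_celsius` [raster_grid].
#' @param units an [admin_units] object.
#' @param assignment optional precomputed [assign_pixels()] result.
#' @return An [indicator_column] named `"temperature"`, orientation risk,
#'   with a `n_pixels` attribute (valid pixels per unit).
#' @export
zonal_mean_temperature <- function(raster, units, assignment = NULL) {
  if (raster$semantics != "temperature_celsius")
    hv_abort("heatvuln_schema_error", "raster semantics must be temperature_celsius")
  if (is.null(assignment)) assignment <- assign_pixels(raster, units)
  red <- zonal_reduce_mean(raster, units, assignment)
  col <- indicator_column("temperature", red$mean, "risk", units_label = "degC")
  attr(col, "n_pixels") <- red$n_pixels
  col
}
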