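#' Georeferenced raster grids
#'
#' A `raster_grid` is a single-band grid of cell values with the usual
#' north-up raster convention: `origin_x`/`origin_y` is the upper-left
#' *corner* of the upper-left pixel, pixels are square with side
#' `pixel_size` metres, and row index increases southward.
#'
#' @param values numeric or integer matrix (`n_rows` x `n_cols`; row 1 is
#'   the northernmost row).
#' @param origin_x,origin_y upper-left corner coordinates, metres.
#' @param pixel_size pixel side length, metres (> 0).
#' @param nodata sentinel value marking invalid cells.
#' @param crs_id reference-system identifier; must match the unit layer.
#' @param semantics `"temperature_celsius"` or `"landcover_code"`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_x, origin_y, pixel_size,
                        nodata = -9999, crs_id = "local_metre",
                        semantics = c("temperature_celsius", "landcover_code")) {
  semantics <- match.arg(semantics)
  values <- as.matrix(values)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    hv_abort("heatvuln_georeference_error", "pixel_size must be positive")
  if (semantics == "landcover_code") {
    v <- values[values != nodata & !is.na(values)]
    if (length(v) && any(v != round(v)))
      hv_abort("heatvuln_schema_error", "land-cover codes must be integers")
    storage.mode(values) <- "double"
  } else {
    v <- values[values != nodata & !is.na(values)]
    if (length(v) && any(v < -60 | v > 70))
      hv_abort("heatvuln_schema_error",
               "temperature outside [-60, 70] degC and not nodata")
  }
  structure(list(values = values, origin_x = origin_x, origin_y = origin_y,
                 pixel_size = pixel_size,
                 n_rows = nrow(values), n_cols = ncol(values),
                 nodata = nodata, crs_id = crs_id, semantics = semantics),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d @ %gm, %s, crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$semantics, x$crs_id))
  invisible(x)
}

#' @rdname raster_grid
#' @param raster a `raster_grid`.
#' @export
raster_extent <- function(raster) {
  c(xmin = raster$origin_x,
    ymin = raster$origin_y - raster$n_rows * raster$pixel_size,
    xmax = raster$origin_x + raster$n_cols * raster$pixel_size,
    ymax = raster$origin_y)
}

# Pixel-centre coordinates of every cell, in matrix (row-major) layout.
pixel_centres <- function(raster) {
  cx <- raster$origin_x + (seq_len(raster$n_cols) - 0.5) * raster$pixel_size
  cy <- raster$origin_y - (seq_len(raster$n_rows) - 0.5) * raster$pixel_size
  list(x = cx, y = cy)
}

#' Read a raster from an ESRI ASCII grid
#'
#' Reads the plain-text `.asc` interchange format (header of `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`, then
#' rows of values north to south). The reference system is read from a
#' sidecar `<path>.prj` text file; a missing sidecar is a georeference
#' error rather than a silent default, because raster/vector alignment
#' is checked by identifier.
#'
#' @param path path to the `.asc` file.
#' @param semantics `"temperature_celsius"` or `"landcover_code"`.
#' @return A [raster_grid].
#' @export
read_raster <- function(path, semantics = c("temperature_celsius", "landcover_code")) {
  semantics <- match.arg(semantics)
  if (!file.exists(path))
    hv_abort("heatvuln_schema_error", sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    hv_abort("heatvuln_georeference_error",
             sprintf("ASCII grid header incomplete in %s", path))
  prj <- paste0(path, ".prj")
  if (!file.exists(prj))
    hv_abort("heatvuln_georeference_error",
             sprintf("no reference system: sidecar %s missing", prj))
  crs_id <- trimws(readLines(prj, n = 1))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    hv_abort("heatvuln_schema_error",
             sprintf("expected %d values, found %d in %s", nr * nc,
                     length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  raster_grid(m,
              origin_x = hdr$xllcorner,
              origin_y = hdr$yllcorner + nr * hdr$cellsize,
              pixel_size = hdr$cellsize,
              nodata = hdr$nodata_value %||% -9999,
              crs_id = crs_id, semantics = semantics)
}

#' Write a raster to an ESRI ASCII grid
#'
#' Writes `<path>` plus the `<path>.prj` sidecar holding the crs id.
#'
#' @param raster a [raster_grid].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  hdr <- c(sprintf("ncols %d", raster$n_cols),
           sprintf("nrows %d", raster$n_rows),
           sprintf("xllcorner %.10g", raster$origin_x),
           sprintf("yllcorner %.10g",
                   raster$origin_y - raster$n_rows * raster$pixel_size),
           sprintf("cellsize %.10g", raster$pixel_size),
           sprintf("nodata_value %.10g", raster$nodata))
  rows <- apply(raster$values, 1, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(raster$crs_id, paste0(path, ".prj"))
  invisible(path)
}

#' Check raster/vector alignment
#'
#' Confirms that the raster and the unit layer declare the same reference
#' system (rasters are never silently reprojected or resampled) and that
#' at least 99% of the total unit area lies inside the raster extent.
#'
#' @param raster a [raster_grid].
#' @param units an [admin_units] object.
#' @param min_coverage minimum acceptable covered fraction of total area.
#' @return A list with `ok`, `covered_fraction`, and `uncovered` (ids of
#'   units with less than full coverage of their own area).
#' @export
validate_alignment <- function(raster, units, min_coverage = 0.99) {
  if (!identical(raster$crs_id, units_crs(units)))
    hv_abort("heatvuln_alignment_error",
             sprintf("crs mismatch: raster '%s' vs units '%s'",
                     raster$crs_id, units_crs(units)))
  ext <- raster_extent(raster)
  tot <- 0; cov <- 0; uncovered <- character(0)
  for (i in seq_len(nrow(units))) {
    g <- units$geometry[[i]]
    a <- geom_area(g)
    a_in <- geom_area_in_rect(g, ext["xmin"], ext["ymin"], ext["xmax"], ext["ymax"])
    tot <- tot + a; cov <- cov + a_in
    if (a_in < a * (1 - 1e-9)) uncovered <- c(uncovered, units$unit_id[i])
  }
  frac <- cov / tot
  list(ok = frac >= min_coverage, covered_fraction = frac,
       uncovered = uncovered)
}
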