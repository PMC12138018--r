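#' Administrative unit sets
#'
#' An `admin_units` object holds the polygons being scored: one row per
#' administrative unit (commune) with its identifier, name, department
#' (the grouping key used for imputation), population, and area, plus a
#' parallel list of polygon geometries in a projected, metre-unit
#' coordinate reference system.
#'
#' @param unit_id character vector of opaque unit identifiers (leading
#'   zeros are significant and preserved).
#' @param department_id character vector, same length as `unit_id`.
#' @param population non-negative numeric vector of resident counts.
#' @param geometry list of geometries, one per unit; each geometry is a
#'   list of polygon parts, each part a list of rings, each ring an
#'   n x 2 coordinate matrix in metres (first ring outer, rest holes).
#' @param name optional character vector of unit names.
#' @param crs_id identifier of the shared projected reference system.
#'
#' @return An object of class `admin_units`: a data frame with columns
#'   `unit_id`, `name`, `department_id`, `population`, `area_km2` and a
#'   `geometry` list column, plus a `crs_id` attribute.
#' @export
admin_units <- function(unit_id, department_id, population, geometry,
                        name = unit_id, crs_id = "local_metre") {
  unit_id <- as.character(unit_id)
  if (length(unit_id) == 0)
    hv_abort("heatvuln_empty_input_error", "empty unit set")
  if (anyDuplicated(unit_id))
    hv_abort("heatvuln_schema_error", "unit_id values must be unique")
  if (any(!is.finite(population) | population < 0))
    hv_abort("heatvuln_schema_error", "population must be non-negative")
  geometry <- lapply(geometry, function(g)
    lapply(g, function(part) lapply(part, function(r) clean_ring(as.matrix(r)))))
  area_km2 <- vapply(geometry, geom_area, numeric(1)) / 1e6
  if (any(area_km2 <= 0))
    hv_abort("heatvuln_schema_error", "every unit must have positive area")
  out <- data.frame(unit_id = unit_id,
                    name = as.character(name),
                    department_id = as.character(department_id),
                    population = as.numeric(population),
                    area_km2 = area_km2,
                    stringsAsFactors = FALSE)
  out$geometry <- geometry
  structure(out, crs_id = crs_id, class = c("admin_units", "data.frame"))
}

#' @export
print.admin_units <- function(x, ...) {
  cat(sprintf("<admin_units> %d units, crs '%s', mean area %.2f km2\n",
              nrow(x), attr(x, "crs_id"), mean(x$area_km2)))
  invisible(x)
}

#' @rdname admin_units
#' @param units an `admin_units` object.
#' @export
units_crs <- function(units) attr(units, "crs_id")

# Local equirectangular projection for geographic input: metre units,
# centred on the layer. Used only when a source file carries lon/lat.
project_lonlat <- function(lon, lat, lon0, lat0) {
  R <- 6371008.8
  cbind(R * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
        R * (lat - lat0) * pi / 180)
}

coords_look_geographic <- function(geoms) {
  xs <- unlist(lapply(geoms, function(g) lapply(g, function(p) lapply(p, function(r) r[, 1]))))
  ys <- unlist(lapply(geoms, function(g) lapply(g, function(p) lapply(p, function(r) r[, 2]))))
  all(abs(xs) <= 180) && all(abs(ys) <= 90)
}

parse_geojson_geometry <- function(g) {
  to_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    clean_ring(m)
  }
  if (g$type == "Polygon") {
    list(lapply(g$coordinates, to_ring))
  } else if (g$type == "MultiPolygon") {
    lapply(g$coordinates, function(part) lapply(part, to_ring))
  } else {
    hv_abort("heatvuln_schema_error",
             sprintf("unsupported geometry type '%s'", g$type))
  }
}

#' Read administrative units from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection whose features carry the mandatory
#' attributes `unit_id`, `department_id` and `population` (plus optional
#' `name`). Geometries must be Polygon or MultiPolygon. Geographic
#' (longitude/latitude) coordinates are reprojected to a local
#' equirectangular metre projection; projected coordinates are taken as
#' metres and passed through unchanged. Rasters, by contrast, are never
#' reprojected (see [validate_alignment()]).
#'
#' @param path path to a `.geojson`/`.json` file.
#' @param crs_id reference-system identifier to assign when the file does
#'   not declare one and coordinates are already projected.
#' @return An [admin_units] object.
#' @export
read_units <- function(path, crs_id = "local_metre") {
  if (!file.exists(path))
    hv_abort("heatvuln_schema_error", sprintf("file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- doc$features
  if (is.null(feats) || length(feats) == 0)
    hv_abort("heatvuln_empty_input_error", sprintf("empty layer: %s", path))
  props <- lapply(feats, `[[`, "properties")
  for (field in c("unit_id", "department_id", "population")) {
    miss <- vapply(props, function(p) is.null(p[[field]]), logical(1))
    if (any(miss))
      hv_abort("heatvuln_schema_error",
               sprintf("mandatory attribute '%s' missing in feature %d",
                       field, which(miss)[1]))
  }
  geoms <- lapply(feats, function(f) parse_geojson_geometry(f$geometry))
  file_crs <- tryCatch(doc$crs$properties$name, error = function(e) NULL)
  if (is.null(file_crs) && coords_look_geographic(geoms)) {
    allv <- do.call(rbind, lapply(geoms, geom_vertices))
    lon0 <- mean(range(allv[, 1])); lat0 <- mean(range(allv[, 2]))
    geoms <- lapply(geoms, function(g) lapply(g, function(part)
      lapply(part, function(r) project_lonlat(r[, 1], r[, 2], lon0, lat0))))
    file_crs <- sprintf("local_equirect(%.6f,%.6f)", lon0, lat0)
  }
  admin_units(
    unit_id = vapply(props, function(p) as.character(p$unit_id), character(1)),
    name = vapply(props, function(p) as.character(p$name %||% p$unit_id), character(1)),
    department_id = vapply(props, function(p) as.character(p$department_id), character(1)),
    population = vapply(props, function(p) as.numeric(p$population), numeric(1)),
    geometry = geoms,
    crs_id = file_crs %||% crs_id
  )
}

#' Write administrative units to GeoJSON
#'
#' Inverse of [read_units()]: attributes and geometry vertices round-trip
#' (coordinates are written at full double precision).
#'
#' @param units an [admin_units] object.
#' @param path output path.
#' @param extra optional data frame of additional per-unit attributes
#'   (matched by position) to embed in the feature properties.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path, extra = NULL) {
  feat <- function(i) {
    g <- units$geometry[[i]]
    coords <- lapply(g, function(part) lapply(part, function(r) {
      r <- rbind(r, r[1, , drop = FALSE])  # close ring
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2]))
    }))
    geometry <- if (length(g) == 1)
      list(type = "Polygon", coordinates = coords[[1]])
    else list(type = "MultiPolygon", coordinates = coords)
    props <- list(unit_id = units$unit_id[i], name = units$name[i],
                  department_id = units$department_id[i],
                  population = units$population[i],
                  area_km2 = units$area_km2[i])
    if (!is.null(extra)) props <- c(props, as.list(extra[i, , drop = FALSE]))
    list(type = "Feature", properties = props, geometry = geometry)
  }
  doc <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = units_crs(units))),
    features = lapply(seq_len(nrow(units)), feat)
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), path)
  invisible(path)
}
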