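#' Pipeline run configuration
#'
#' Collects every input path and knob of an end-to-end run. In file mode
#' all referenced paths must exist at run start; in synthetic mode
#' (`synth = TRUE`) the inputs are generated from `synth_cfg` instead.
#'
#' @param out_dir output directory (created if absent).
#' @param synth generate inputs with [make_synthetic_inputs()]?
#' @param synth_cfg a [synth_config] (synthetic mode).
#' @param units_path,temperature_paths,landcover_path,socio_path,ac_path,visits_path
#'   input files (file mode): units GeoJSON, one or more daily
#'   temperature `.asc` rasters, land-cover `.asc` raster, socioeconomic
#'   CSV, AC-rate CSV (`unit_id,ac_rate`), visit CSV.
#' @param grouping a [class_grouping] or path to a grouping config.
#' @param causes a [cause_map] or path to a cause config.
#' @param impute_policy imputation for the deprivation score
#'   (`department_median` by default; temperature and land-cover
#'   missingness is structural and left missing).
#' @param k number of quantile classes.
#' @param window closed date window for the morbidity indicator.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, synth = FALSE, synth_cfg = synth_config(),
                       units_path = NULL, temperature_paths = NULL,
                       landcover_path = NULL, socio_path = NULL,
                       ac_path = NULL, visits_path = NULL,
                       grouping = default_grouping(), causes = cause_map(),
                       impute_policy = "department_median", k = 5,
                       window = as.Date(c("2022-06-01", "2022-08-31"))) {
  if (k < 2) hv_abort("heatvuln_config_error", "k must be >= 2")
  if (!synth) {
    req <- list(units = units_path, temperature = temperature_paths,
                landcover = landcover_path, socio = socio_path,
                ac = ac_path, visits = visits_path)
    for (nm in names(req)) {
      if (is.null(req[[nm]]))
        hv_abort("heatvuln_config_error",
                 sprintf("missing input layer: %s", nm))
      missing_files <- req[[nm]][!file.exists(req[[nm]])]
      if (length(missing_files))
        hv_abort("heatvuln_config_error",
                 sprintf("%s input not found: %s", nm, missing_files[1]))
    }
  }
  if (is.character(grouping)) grouping <- read_grouping(grouping)
  if (is.character(causes)) causes <- read_cause_map(causes)
  structure(list(out_dir = out_dir, synth = synth, synth_cfg = synth_cfg,
                 units_path = units_path, temperature_paths = temperature_paths,
                 landcover_path = landcover_path, socio_path = socio_path,
                 ac_path = ac_path, visits_path = visits_path,
                 grouping = grouping, causes = causes,
                 impute_policy = impute_policy, k = k,
                 window = as.Date(window)),
            class = "run_config")
}

write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  path
}

#' Run the full vulnerability pipeline
#'
#' Orchestrates every stage from raw (or synthetic) layers to the scored
#' geodata product: temporal mean of the daily temperature rasters,
#' pixel assignment, zonal mean temperature, exposed land-cover
#' fraction, deprivation score, AC ingest, Z-scores, imputation,
#' equal-weight composite index, quantile classes, and the heat-
#' morbidity indicator. Writes, under `out_dir`:
#' `scores.csv`, `icanicule.csv`, `vulnerability.geojson` (index and
#' morbidity attributes on the unit polygons), and `manifest.json`
#' (version, config echo, per-stage counts, warnings, output md5
#' checksums). Deterministic given the inputs (and the seed in
#' synthetic mode); re-running with unchanged inputs reproduces
#' byte-identical CSVs.
#'
#' @param config a [run_config].
#' @return Invisibly, a list with `scores` (scores + class +
#'   morbidity data frame), `units`, `manifest`, and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character(0)
  manifest <- list(tool = "heatvuln",
                   version = as.character(utils::packageVersion("heatvuln")),
                   mode = if (config$synth) "synthetic" else "file",
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  stage <- "load_inputs"
  result <- tryCatch({
    if (config$synth) {
      inputs <- make_synthetic_inputs(config$synth_cfg)
      manifest$seed <- config$synth_cfg$seed
      ac_tab <- data.frame(unit_id = names(inputs$ac_rates),
                           ac_rate = unname(inputs$ac_rates))
    } else {
      inputs <- list(
        units = read_units(config$units_path),
        temperature = lapply(config$temperature_paths, read_raster,
                             semantics = "temperature_celsius"),
        landcover = read_raster(config$landcover_path,
                                semantics = "landcover_code"),
        socio = read_socio_table(config$socio_path),
        visits = read_visit_records(config$visits_path))
      ac_tab <- utils::read.csv(config$ac_path,
                                colClasses = c(unit_id = "character"))
      if (!all(c("unit_id", "ac_rate") %in% names(ac_tab)))
        hv_abort("heatvuln_schema_error", "AC table needs unit_id, ac_rate")
    }
    units <- inputs$units
    note("load_inputs", n_units = nrow(units),
         n_temperature_rasters = length(inputs$temperature))

    stage <- "alignment"
    rep1 <- validate_alignment(inputs$temperature[[1]], units)
    rep2 <- validate_alignment(inputs$landcover, units)
    if (!rep1$ok || !rep2$ok)
      hv_abort("heatvuln_alignment_error",
               sprintf("raster does not cover >= 99%% of unit area (%.1f%%)",
                       100 * min(rep1$covered_fraction, rep2$covered_fraction)))
    note("alignment", covered_fraction =
           min(rep1$covered_fraction, rep2$covered_fraction))

    stage <- "temporal_mean"
    temp_mean <- temporal_mean(inputs$temperature)
    note("temporal_mean", n_days = length(inputs$temperature))

    stage <- "zonal_temperature"
    assignment <- assign_pixels(temp_mean, units)
    temp_col <- zonal_mean_temperature(temp_mean, units, assignment)
    note("zonal_temperature", n_pixels_assigned =
           sum(!is.na(assignment$unit)), n_unassigned = assignment$n_unassigned,
         n_missing_units = length(temp_col$missing))

    stage <- "landcover"
    lc_assignment <- if (identical(c(inputs$landcover$n_rows, inputs$landcover$n_cols,
                                     inputs$landcover$pixel_size),
                                   c(temp_mean$n_rows, temp_mean$n_cols,
                                     temp_mean$pixel_size)))
      assignment else assign_pixels(inputs$landcover, units)
    artif_col <- unit_exposed_fraction(inputs$landcover, units,
                                       config$grouping, lc_assignment)
    note("landcover", n_missing_units = length(artif_col$missing))

    stage <- "deprivation"
    fdep_col <- fdep_score(inputs$socio)
    note("deprivation", n_complete = sum(!is.na(fdep_col$values)),
         explained_share = attr(fdep_col, "explained"))

    stage <- "ac_ingest"
    ac_values <- setNames(rep(NA_real_, nrow(units)), units$unit_id)
    ac_values[ac_tab$unit_id[ac_tab$unit_id %in% units$unit_id]] <-
      ac_tab$ac_rate[ac_tab$unit_id %in% units$unit_id]
    ac_col <- indicator_column("ac_rate", ac_values, "protective",
                               units_label = "%")
    note("ac_ingest", n_missing_units = length(ac_col$missing))

    stage <- "impute"
    fdep_col <- withCallingHandlers(
      impute(fdep_col, units, config$impute_policy),
      heatvuln_imputation_warning = function(w) {
        warn_log <<- c(warn_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    note("impute", policy = config$impute_policy,
         n_imputed = length(fdep_col$imputed))

    stage <- "index"
    scores <- composite_index(zscore(temp_col), zscore(fdep_col),
                              zscore(artif_col), zscore(ac_col))
    cls <- withCallingHandlers(
      quantile_classes(scores, config$k),
      heatvuln_class_collapse_warning = function(w) {
        warn_log <<- c(warn_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    scores$quantile_class <- cls
    note("index", n_scored = sum(!scores$missing),
         n_missing = sum(scores$missing))

    stage <- "icanicule"
    kept <- filter_heat_visits(inputs$visits, config$causes, config$window)
    morb <- aggregate_indicator(kept, units)
    note("icanicule", n_input = attr(kept, "n_input"),
         n_dropped = attr(kept, "n_dropped"), n_kept = nrow(kept),
         n_orphans = nrow(attr(morb, "orphans")))

    stage <- "write_outputs"
    out <- merge(scores, as.data.frame(morb), by = "unit_id", sort = FALSE)
    out <- out[match(units$unit_id, out$unit_id), ]
    rownames(out) <- NULL
    paths <- list(
      scores = file.path(config$out_dir, "scores.csv"),
      icanicule = file.path(config$out_dir, "icanicule.csv"),
      geodata = file.path(config$out_dir, "vulnerability.geojson"),
      manifest = file.path(config$out_dir, "manifest.json"))
    write_csv_stable(scores, paths$scores)
    write_csv_stable(as.data.frame(morb), paths$icanicule)
    write_units(units, paths$geodata,
                extra = out[, setdiff(names(out), "unit_id")])
    list(scores = out, units = units, paths = paths)
  }, heatvuln_error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest$warnings <- warn_log
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop(e)
  })
  manifest$warnings <- warn_log
  manifest$outputs <- as.list(tools::md5sum(unlist(result$paths[
    c("scores", "icanicule", "geodata")])))
  jsonlite::write_json(manifest, result$paths$manifest,
                       auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}

#' Export a choropleth of a scored attribute
#'
#' Writes the classed units as GeoJSON plus a static PNG choropleth for
#' documentation: a sequential fill ramp with one bin per class and a
#' distinct grey for missing units.
#'
#' @param scores a `vulnerability_scores` data frame (with
#'   `quantile_class`) or any data frame keyed by `unit_id`.
#' @param units the matching [admin_units].
#' @param field attribute to map (default `"quantile_class"`).
#' @param path output PNG path; the GeoJSON goes next to it.
#' @param width,height image size in pixels.
#' @return Invisibly, list of the two paths written.
#' @export
export_choropleth <- function(scores, units, field = "quantile_class",
                              path, width = 800, height = 800) {
  if (!field %in% names(scores))
    hv_abort("heatvuln_attribute_error",
             sprintf("unknown field '%s'", field))
  val <- scores[[field]][match(units$unit_id, scores$unit_id)]
  polys <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    rings <- unlist(units$geometry[[i]], recursive = FALSE)
    do.call(rbind, lapply(seq_along(rings), function(j) {
      r <- rings[[j]]
      data.frame(x = r[, 1], y = r[, 2],
                 grp = sprintf("%s_%d", units$unit_id[i], j),
                 value = if (is.na(val[i])) NA_character_ else as.character(val[i]))
    }))
  }))
  lv <- sort(unique(stats::na.omit(polys$value)))
  polys$value <- factor(polys$value, levels = lv)
  ramp <- grDevices::colorRampPalette(c("#ffffcc", "#bd0026"))(max(length(lv), 2))[seq_along(lv)]
  p <- ggplot2::ggplot(polys, ggplot2::aes(x = x, y = y, group = grp,
                                           fill = value)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = ramp, na.value = "grey80",
                               name = field, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  grDevices::png(path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  gj <- sub("\\.png$", ".geojson", path)
  extra <- scores[match(units$unit_id, scores$unit_id),
                  setdiff(names(scores), "unit_id"), drop = FALSE]
  write_units(units, gj, extra = extra)
  invisible(list(image = path, geodata = gj))
}
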