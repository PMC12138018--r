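# CORINE land-cover class grouping and per-unit exposed-surface fraction.

# The 44 level-3 CORINE codes, by level-1/level-2 block.
CORINE_CODES <- c(111, 112, 121, 122, 123, 124, 131, 132, 133, 141, 142,
                  211, 212, 213, 221, 222, 223, 231, 241, 242, 243, 244,
                  311, 312, 313, 321, 322, 323, 324,
                  331, 332, 333, 334, 335,
                  411, 412, 421, 422, 423,
                  511, 512, 521, 522, 523)

#' Default CORINE class grouping
#'
#' Maps every 3-digit CORINE level-3 code (111--523) to one of four
#' groups: `artificial` (111--142, the level-1 artificial-surfaces
#' block), `non_vegetated_open` (331--335, open spaces with little or no
#' vegetation: beaches, bare rock, sparse vegetation, burnt areas,
#' glaciers), `vegetated` (211--324, agricultural plus forest and
#' semi-natural vegetated classes), and `water` (411--523, wetlands and
#' water bodies). The exposure numerator is artificial plus
#' non-vegetated open surfaces; water stays in the denominator but not
#' the numerator. The grouping ships as an editable plain-text config
#' (see [read_grouping()]) so alternative readings are one edit away.
#'
#' @return A `class_grouping`: list with `map` (named character vector,
#'   code to group) and `numerator_groups`.
#' @export
default_grouping <- function() {
  grp <- ifelse(CORINE_CODES <= 142, "artificial",
         ifelse(CORINE_CODES <= 324, "vegetated",
         ifelse(CORINE_CODES <= 335, "non_vegetated_open", "water")))
  class_grouping(setNames(grp, CORINE_CODES),
                 numerator_groups = c("artificial", "non_vegetated_open"))
}

#' @rdname default_grouping
#' @param map named character vector mapping code (as name) to group.
#' @param numerator_groups groups counted as exposed surface.
#' @export
class_grouping <- function(map, numerator_groups) {
  groups <- c("artificial", "non_vegetated_open", "vegetated", "water")
  if (!all(map %in% groups))
    hv_abort("heatvuln_schema_error",
             sprintf("unknown group '%s'", setdiff(map, groups)[1]))
  if (length(numerator_groups) == 0)
    hv_abort("heatvuln_schema_error", "numerator_groups must be non-empty")
  structure(list(map = map, numerator_groups = numerator_groups),
            class = "class_grouping")
}

#' @rdname default_grouping
#' @param path plain-text config, one `code,group` pair per line; lines
#'   starting with `#` are comments. An optional `numerator,<g1>+<g2>`
#'   line overrides the exposure numerator.
#' @export
read_grouping <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ",")
  num <- c("artificial", "non_vegetated_open")
  map <- character(0)
  for (p in parts) {
    if (p[1] == "numerator") num <- strsplit(p[2], "\\+")[[1]]
    else map[p[1]] <- trimws(p[2])
  }
  class_grouping(map, num)
}

#' Per-unit exposed (artificial and non-vegetated) surface fraction
#'
#' For each unit, the fraction of assigned valid land-cover pixels whose
#' class falls in the exposure numerator groups. Shares the pixel-centre
#' assignment and boundary tie-break with [zonal_mean_temperature()] so
#' all raster-derived layers see the same pixels.
#'
#' @param raster a `landcover_code` [raster_grid].
#' @param units an [admin_units] object.
#' @param grouping a [class_grouping]; defaults to [default_grouping()].
#' @param assignment optional precomputed [assign_pixels()] result.
#' @return An [indicator_column] named `"artificial_fraction"`,
#'   orientation risk, values in `[0, 1]`; units with no valid pixel are
#'   missing. A `group_fractions` attribute carries the per-unit fraction
#'   of each of the four groups.
#' @export
unit_exposed_fraction <- function(raster, units, grouping = default_grouping(),
                                  assignment = NULL) {
  if (raster$semantics != "landcover_code")
    hv_abort("heatvuln_schema_error", "raster semantics must be landcover_code")
  if (is.null(assignment)) assignment <- assign_pixels(raster, units)
  valid <- raster$values != raster$nodata & !is.na(raster$values)
  codes <- as.character(raster$values[valid])
  unknown <- setdiff(unique(codes), names(grouping$map))
  if (length(unknown))
    hv_abort("heatvuln_unknown_class_error",
             sprintf("unknown land-cover code %s", unknown[1]))
  u <- assignment$unit
  keep <- !is.na(u) & valid
  grp <- grouping$map[as.character(raster$values[keep])]
  uid <- u[keep]
  tot <- table(factor(uid, levels = units$unit_id))
  groups <- c("artificial", "non_vegetated_open", "vegetated", "water")
  by_grp <- table(factor(uid, levels = units$unit_id),
                  factor(grp, levels = groups))
  frac_all <- sweep(unclass(by_grp), 1, as.numeric(tot), "/")
  exposed <- rowSums(frac_all[, grouping$numerator_groups, drop = FALSE])
  exposed[as.numeric(tot) == 0] <- NA_real_
  col <- indicator_column("artificial_fraction",
                          setNames(as.numeric(exposed), units$unit_id),
                          "risk", units_label = "proportion")
  attr(col, "group_fractions") <- frac_all
  attr(col, "n_pixels") <- setNames(as.numeric(tot), units$unit_id)
  col
}
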