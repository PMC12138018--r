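# iCanicule: syndromic heat-morbidity indicator from emergency-department
# and emergency-GP visit records.

#' Heat-cause diagnosis map
#'
#' Maps diagnosis-code prefixes to the three heat-morbidity categories:
#' hyperthermia/heatstroke (T67, effects of heat and light), dehydration
#' (E86, volume depletion), hyponatremia (E87.1, hypo-osmolality and
#' hyponatremia). Matching is prefix-based, so T67.0 and T67.9 both fall
#' under T67. Patterns must be non-overlapping: no code may match two
#' categories. The default is the obvious ICD-10 reading of the four
#' named conditions and is user-overridable.
#'
#' @param patterns named character vector: names are code prefixes,
#'   values are categories in `hyperthermia_heatstroke`, `dehydration`,
#'   `hyponatremia`.
#' @return A `cause_map` object.
#' @export
cause_map <- function(patterns = c("T67" = "hyperthermia_heatstroke",
                                   "E86" = "dehydration",
                                   "E87.1" = "hyponatremia")) {
  cats <- c("hyperthermia_heatstroke", "dehydration", "hyponatremia")
  if (!all(patterns %in% cats))
    hv_abort("heatvuln_schema_error",
             sprintf("unknown cause category '%s'", setdiff(patterns, cats)[1]))
  pre <- names(patterns)
  for (i in seq_along(pre)) for (j in seq_along(pre)) {
    if (i != j && startsWith(pre[i], pre[j]) && patterns[i] != patterns[j])
      hv_abort("heatvuln_schema_error",
               sprintf("overlapping cause patterns '%s' and '%s'", pre[i], pre[j]))
  }
  structure(list(patterns = patterns), class = "cause_map")
}

#' @rdname cause_map
#' @param path plain-text config, one `prefix,category` pair per line;
#'   `#` lines are comments.
#' @export
read_cause_map <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(lines, ","))
  cause_map(setNames(trimws(kv[, 2]), trimws(kv[, 1])))
}

match_cause <- function(codes, causes) {
  out <- rep(NA_character_, length(codes))
  # longest prefix wins, so a specific pattern can refine a broad one
  ord <- order(nchar(names(causes$patterns)), decreasing = TRUE)
  for (i in ord) {
    pre <- names(causes$patterns)[i]
    hit <- is.na(out) & startsWith(codes, pre)
    out[hit] <- causes$patterns[[i]]
  }
  out
}

#' Visit record sets
#'
#' Validates a table of individual emergency visits: `unit_id`, `date`
#' (ISO-8601 or `Date`), `source` (`emergency_department` or
#' `emergency_gp`), `cause_code` (diagnosis code).
#'
#' @param df data frame of visit records.
#' @return The validated data frame with class `visit_records`.
#' @export
visit_records <- function(df) {
  need <- c("unit_id", "date", "source", "cause_code")
  miss <- setdiff(need, names(df))
  if (length(miss))
    hv_abort("heatvuln_schema_error",
             sprintf("visit table missing column '%s'", miss[1]))
  if (!inherits(df$date, "Date")) {
    parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df$date))
    if (length(bad))
      hv_abort("heatvuln_parse_error",
               sprintf("malformed date '%s' in row %d", df$date[bad[1]], bad[1]))
    df$date <- parsed
  }
  ok <- df$source %in% c("emergency_department", "emergency_gp")
  if (!all(ok))
    hv_abort("heatvuln_schema_error",
             sprintf("unknown source '%s' in row %d", df$source[!ok][1],
                     which(!ok)[1]))
  df$unit_id <- as.character(df$unit_id)
  df$cause_code <- as.character(df$cause_code)
  structure(as.data.frame(df), class = c("visit_records", "data.frame"))
}

#' @rdname visit_records
#' @param path CSV with columns `unit_id,date,source,cause_code`.
#' @export
read_visit_records <- function(path) {
  visit_records(utils::read.csv(path, colClasses = c(unit_id = "character",
                                                     date = "character")))
}

#' Filter visits to heat-related causes within a period
#'
#' Keeps records whose date lies in the closed window and whose
#' diagnosis code matches a heat-cause category; everything else is
#' dropped and counted. The matched category is attached as a `category`
#' column.
#'
#' @param records a [visit_records] table.
#' @param causes a [cause_map].
#' @param window length-2 `Date` (or ISO string) vector, start <= end.
#' @return A [visit_records] table of kept records with a `category`
#'   column and attributes `n_input` and `n_dropped`.
#' @export
filter_heat_visits <- function(records, causes = cause_map(),
                               window = as.Date(c("2022-06-01", "2022-08-31"))) {
  records <- visit_records(records)
  window <- as.Date(window)
  if (window[1] > window[2])
    hv_abort("heatvuln_schema_error", "window start must be <= end")
  category <- match_cause(records$cause_code, causes)
  keep <- !is.na(category) & records$date >= window[1] & records$date <= window[2]
  out <- records[keep, , drop = FALSE]
  out$category <- category[keep]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(records)
  attr(out, "n_dropped") <- nrow(records) - nrow(out)
  attr(out, "window") <- window
  structure(out, class = c("visit_records", "data.frame"))
}

#' Aggregate the iCanicule indicator per unit
#'
#' Counts filtered heat visits per unit, split by source (emergency
#' department / emergency GP) and by cause category, and derives the
#' visit rate per 10 000 residents. Units with no records get count 0:
#' in surveillance counts the absence of events is information, not
#' missingness. Records whose `unit_id` is not in the unit layer go to
#' an orphan report instead of being silently dropped. No small-count
#' suppression or spatial smoothing is applied.
#'
#' @param records filtered [visit_records] (with `category` column).
#' @param units an [admin_units] object.
#' @return A `morbidity_indicator` data frame: `unit_id`, `n_visits`,
#'   `n_ed`, `n_gp`, `n_hyperthermia_heatstroke`, `n_dehydration`,
#'   `n_hyponatremia`, `rate_per_10k` (NA where population is 0); with
#'   an `orphans` attribute (records outside the unit set) and the
#'   period carried through.
#' @export
aggregate_indicator <- function(records, units) {
  if (is.null(records$category))
    hv_abort("heatvuln_schema_error",
             "records must be filtered (no category column); run filter_heat_visits first")
  known <- records$unit_id %in% units$unit_id
  orphans <- records[!known, , drop = FALSE]
  rec <- records[known, , drop = FALSE]
  f <- factor(rec$unit_id, levels = units$unit_id)
  n <- as.numeric(table(f))
  n_ed <- as.numeric(table(f[rec$source == "emergency_department"]))
  n_gp <- as.numeric(table(f[rec$source == "emergency_gp"]))
  cat_count <- function(cat) as.numeric(table(f[rec$category == cat]))
  rate <- ifelse(units$population > 0, 1e4 * n / units$population, NA_real_)
  out <- data.frame(unit_id = units$unit_id,
                    n_visits = n, n_ed = n_ed, n_gp = n_gp,
                    n_hyperthermia_heatstroke = cat_count("hyperthermia_heatstroke"),
                    n_dehydration = cat_count("dehydration"),
                    n_hyponatremia = cat_count("hyponatremia"),
                    rate_per_10k = rate,
                    stringsAsFactors = FALSE)
  attr(out, "orphans") <- orphans
  attr(out, "window") <- attr(records, "window")
  structure(out, class = c("morbidity_indicator", "data.frame"))
}
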