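#' Per-unit indicator columns
#'
#' An `indicator_column` carries one per-unit indicator (temperature,
#' deprivation score, artificial surface fraction, air-conditioning
#' rate, ...) together with its orientation with respect to heatwave
#' vulnerability: `"risk"` indicators raise vulnerability as they grow,
#' `"protective"` ones lower it. Missing units carry `NA` and are listed
#' in the `missing` attribute; they are never silently zero-filled.
#'
#' @param name indicator name (e.g. `"temperature"`, `"fdep"`,
#'   `"artificial_fraction"`, `"ac_rate"`).
#' @param values named numeric vector, names are unit ids; `NA` = missing.
#' @param orientation `"risk"` or `"protective"`.
#' @param units_label free-text unit label (degC, unitless score, ...).
#' @param imputed character vector of unit ids whose value was imputed.
#' @return An object of class `indicator_column`.
#' @export
indicator_column <- function(name, values, orientation = c("risk", "protective"),
                             units_label = "", imputed = character(0)) {
  orientation <- match.arg(orientation)
  if (is.null(names(values)))
    hv_abort("heatvuln_schema_error", "indicator values must be named by unit_id")
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad))
    hv_abort("heatvuln_schema_error",
             sprintf("non-finite indicator value for unit %s",
                     names(values)[bad][1]))
  structure(list(name = name, values = values, orientation = orientation,
                 missing = names(values)[is.na(values)],
                 units_label = units_label, imputed = imputed),
            class = "indicator_column")
}

#' @export
print.indicator_column <- function(x, ...) {
  cat(sprintf("<indicator_column> %s (%s), %d units, %d missing\n",
              x$name, x$orientation, length(x$values), length(x$missing)))
  invisible(x)
}

#' Standardise an indicator as Z-scores
#'
#' Z-scores are computed over the non-missing units with the population
#' convention (divisor n): z_i = (x_i - mean) / sd. Missing entries stay
#' missing. This places heterogeneous indicators (degrees Celsius, score
#' units, proportions, percentages) on one common scale before they are
#' combined.
#'
#' @param column an [indicator_column].
#' @return An [indicator_column] of z-scores with the same name,
#'   orientation and missingness.
#' @export
zscore <- function(column) {
  stopifnot(inherits(column, "indicator_column"))
  x <- column$values
  ok <- !is.na(x)
  if (sum(ok) < 2)
    hv_abort("heatvuln_degenerate_variance_error",
             "need at least 2 non-missing values to standardise")
  s <- pop_sd(x[ok])
  if (!is.finite(s) || s <= 0)
    hv_abort("heatvuln_degenerate_variance_error",
             sprintf("indicator '%s' has zero dispersion", column$name))
  z <- x
  z[ok] <- (x[ok] - mean(x[ok])) / s
  indicator_column(column$name, z, column$orientation,
                   units_label = "z-score", imputed = column$imputed)
}

#' Impute missing indicator values
#'
#' Implements the missing-data policies for per-unit indicators:
#' \describe{
#'   \item{drop}{missing units stay missing and are excluded downstream.}
#'   \item{department_median}{replace by the median of the non-missing
#'     values in the unit's own department.}
#'   \item{neighbour_mean}{replace by the mean over polygon-adjacent
#'     non-missing units (boundaries within `tol` metres).}
#' }
#' Units that remain unimputable under their policy (e.g. a whole
#' department missing) stay missing. Imputed unit ids are recorded on the
#' returned column.
#'
#' @param column an [indicator_column].
#' @param units the [admin_units] the column refers to.
#' @param policy `"drop"`, `"department_median"` or `"neighbour_mean"`.
#' @param tol adjacency tolerance in metres for `neighbour_mean`.
#' @return An [indicator_column] with imputations applied and flagged.
#' @export
impute <- function(column, units,
                   policy = c("drop", "department_median", "neighbour_mean"),
                   tol = 1) {
  policy <- match.arg(policy)
  stopifnot(inherits(column, "indicator_column"))
  x <- column$values
  miss <- names(x)[is.na(x)]
  if (policy == "drop" || length(miss) == 0) return(column)
  filled <- character(0)
  if (policy == "department_median") {
    dept <- setNames(units$department_id, units$unit_id)
    for (id in miss) {
      peers <- names(x)[dept[names(x)] == dept[id] & !is.na(x)]
      if (length(peers)) {
        x[id] <- stats::median(x[peers])
        filled <- c(filled, id)
        hv_warn("heatvuln_imputation_warning",
                sprintf("imputed %s for unit %s by department median",
                        column$name, id))
      }
    }
  } else {
    idx <- match(names(x), units$unit_id)
    for (id in miss) {
      gi <- units$geometry[[match(id, units$unit_id)]]
      bb <- geom_bbox(gi)
      nb <- character(0)
      for (j in seq_len(nrow(units))) {
        if (units$unit_id[j] == id) next
        bbj <- geom_bbox(units$geometry[[j]])
        if (bbj["xmin"] > bb["xmax"] + tol || bbj["xmax"] < bb["xmin"] - tol ||
            bbj["ymin"] > bb["ymax"] + tol || bbj["ymax"] < bb["ymin"] - tol) next
        if (geom_boundary_dist(gi, units$geometry[[j]]) <= tol)
          nb <- c(nb, units$unit_id[j])
      }
      nb <- nb[!is.na(x[nb])]
      if (length(nb)) {
        x[id] <- mean(x[nb])
        filled <- c(filled, id)
        hv_warn("heatvuln_imputation_warning",
                sprintf("imputed %s for unit %s by neighbour mean", column$name, id))
      }
    }
  }
  indicator_column(column$name, x, column$orientation, column$units_label,
                   imputed = union(column$imputed, filled))
}
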