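#' Composite heatwave-vulnerability index
#'
#' Combines the four standardised indicators with equal weights into one
#' index per unit:
#'
#'   V_i = (z_temp,i + z_fdep,i + z_artif,i - z_ac,i) / 4
#'
#' Each indicator contributes with weight 1/4 and enters with the sign
#' of its orientation: temperature, deprivation and artificial surface
#' are risk factors (+), the air-conditioning equipment rate is the
#' protective factor (-). Division by 4 (the mean of signed z-scores
#' rather than their raw sum) keeps the index on a z-like scale; the
#' equal-weights contract is satisfied either way. A unit missing any
#' non-imputed indicator is scored missing.
#'
#' @param z_temp,z_fdep,z_artif,z_ac [indicator_column] objects of
#'   z-scores over the same unit set, carrying orientation metadata
#'   (`z_ac` must be protective, the others risk).
#' @return A `vulnerability_scores` data frame: `unit_id`,
#'   `z_temperature`, `z_fdep`, `z_artificial`, `z_ac`, `index`,
#'   `imputed` (comma-separated indicator names), `missing`.
#' @export
composite_index <- function(z_temp, z_fdep, z_artif, z_ac) {
  cols <- list(temperature = z_temp, fdep = z_fdep,
               artificial_fraction = z_artif, ac_rate = z_ac)
  for (nm in names(cols)) {
    c_ <- cols[[nm]]
    if (!inherits(c_, "indicator_column") || is.null(c_$orientation))
      hv_abort("heatvuln_orientation_error",
               sprintf("indicator '%s' lacks orientation metadata", nm))
  }
  if (z_ac$orientation != "protective" ||
      any(vapply(cols[1:3], `[[`, character(1), "orientation") != "risk"))
    hv_abort("heatvuln_orientation_error",
             "expected risk orientation for temperature/fdep/artificial and protective for ac")
  ids <- names(z_temp$values)
  for (c_ in cols) {
    if (!identical(sort(names(c_$values)), sort(ids)))
      hv_abort("heatvuln_schema_error", "z-columns must cover the same unit set")
  }
  sgn <- vapply(cols, function(c_) if (c_$orientation == "risk") 1 else -1,
                numeric(1))
  zmat <- vapply(cols, function(c_) unname(c_$values[ids]), numeric(length(ids)))
  V <- unname(drop(zmat %*% sgn)) / 4
  imputed <- vapply(ids, function(id)
    paste(names(cols)[vapply(cols, function(c_) id %in% c_$imputed, logical(1))],
          collapse = ","), character(1))
  out <- data.frame(unit_id = ids,
                    z_temperature = zmat[, "temperature"],
                    z_fdep = zmat[, "fdep"],
                    z_artificial = zmat[, "artificial_fraction"],
                    z_ac = zmat[, "ac_rate"],
                    index = V,
                    imputed = imputed,
                    missing = is.na(V),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("vulnerability_scores", "data.frame"))
}

#' Quantile classes for choropleth mapping
#'
#' Classes scores into k quantile bins (quintiles by default, the usual
#' convention for heat-vulnerability choropleths). Breaks are the
#' 1/k, 2/k, ..., k/k quantiles computed by linear interpolation
#' (`stats::quantile` type 7) over non-missing scores; class c is the
#' smallest c with score <= c-th break (inclusive upper edges), so class
#' sizes differ by at most one when values are distinct. With fewer
#' distinct values than k the classes collapse to the distinct values,
#' with a warning.
#'
#' @param scores numeric vector (NA = missing) or a
#'   `vulnerability_scores` data frame (its `index` column is used).
#' @param k number of classes (>= 2).
#' @return Integer vector of class labels `1..k` (NA for missing), with
#'   a `breaks` attribute.
#' @export
quantile_classes <- function(scores, k = 5) {
  if (inherits(scores, "vulnerability_scores")) scores <- scores$index
  if (k < 2) hv_abort("heatvuln_schema_error", "k must be at least 2")
  ok <- !is.na(scores)
  if (sum(ok) < k)
    hv_abort("heatvuln_schema_error",
             sprintf("need at least k = %d non-missing scores", k))
  v <- scores[ok]
  n_distinct <- length(unique(v))
  if (n_distinct < k) {
    hv_warn("heatvuln_class_collapse_warning",
            sprintf("only %d distinct values; collapsing to %d classes",
                    n_distinct, n_distinct))
    k <- max(n_distinct, 1)
  }
  brks <- stats::quantile(v, probs = seq_len(k) / k, type = 7, names = FALSE)
  eps <- 1e-9 * max(1, diff(range(v)))
  cls <- rep(NA_integer_, length(scores))
  cls[ok] <- vapply(v, function(x) which(x <= brks + eps)[1], integer(1))
  attr(cls, "breaks") <- brks
  cls
}
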