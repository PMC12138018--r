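#' Socioeconomic component table
#'
#' Validates the four per-unit socioeconomic variables behind the
#' deprivation score: unemployment rate and percentage of blue-collar
#' workers (both among the active population aged 15--64), percentage of
#' high-school graduates among those aged 15 and over, and median
#' household income. Missing entries are `NA`, never zero-filled.
#'
#' @param df data frame with columns `unit_id`, `unemployment_rate`,
#'   `blue_collar_pct`, `graduates_pct`, `median_income`.
#' @return The validated data frame with class `socio_table`.
#' @export
socio_table <- function(df) {
  need <- c("unit_id", "unemployment_rate", "blue_collar_pct",
            "graduates_pct", "median_income")
  miss <- setdiff(need, names(df))
  if (length(miss))
    hv_abort("heatvuln_schema_error",
             sprintf("socio table missing column '%s'", miss[1]))
  for (v in c("unemployment_rate", "blue_collar_pct", "graduates_pct")) {
    x <- df[[v]]
    if (any(!is.na(x) & (x < 0 | x > 100)))
      hv_abort("heatvuln_schema_error", sprintf("%s outside [0, 100]", v))
  }
  if (any(!is.na(df$median_income) & df$median_income <= 0))
    hv_abort("heatvuln_schema_error", "median_income must be positive")
  df$unit_id <- as.character(df$unit_id)
  structure(df, class = c("socio_table", "data.frame"))
}

#' @rdname socio_table
#' @param path CSV path (header row, UTF-8, dot decimal separator).
#' @export
read_socio_table <- function(path) {
  socio_table(utils::read.csv(path, colClasses = c(unit_id = "character")))
}

socio_components <- c("unemployment_rate", "blue_collar_pct",
                      "graduates_pct", "median_income")

#' Standardise the four socioeconomic components
#'
#' Centres and scales each component to mean 0 and population standard
#' deviation 1 (divisor n) over the complete cases, the prerequisite for
#' a correlation-matrix principal component.
#'
#' @param table a [socio_table].
#' @return A matrix of 4 standardised columns over complete cases, with
#'   `unit_id` rownames and a `complete` logical attribute aligned to the
#'   input rows.
#' @export
standardise_components <- function(table) {
  stopifnot(inherits(table, "socio_table"))
  m <- as.matrix(as.data.frame(table)[, socio_components])
  complete <- stats::complete.cases(m)
  if (sum(complete) < 5)
    hv_abort("heatvuln_schema_error",
             "need at least 5 complete cases to standardise")
  mc <- m[complete, , drop = FALSE]
  sds <- apply(mc, 2, pop_sd)
  if (any(sds <= 0 | !is.finite(sds)))
    hv_abort("heatvuln_degenerate_variance_error",
             sprintf("component '%s' is constant across units",
                     socio_components[which(sds <= 0)[1]]))
  z <- sweep(sweep(mc, 2, colMeans(mc)), 2, sds, "/")
  rownames(z) <- table$unit_id[complete]
  attr(z, "complete") <- complete
  z
}

#' FDep-style deprivation score
#'
#' Computes an area deprivation score in the construction of the French
#' Deprivation Index: the projection of the four standardised
#' socioeconomic components on the leading eigenvector of their
#' correlation matrix (equivalently, the first principal component of
#' the correlation-matrix PCA). The eigenvector sign is anchored so the
#' score correlates positively with the unemployment rate: higher score
#' = more deprived. Because the PCA uses the correlation matrix, the
#' score is invariant to the measurement scale of any component (e.g.
#' the currency of median income).
#'
#' Incomplete cases are excluded from the eigen-decomposition and scored
#' missing; the index stage decides their imputation.
#'
#' @param table a [socio_table].
#' @return An [indicator_column] named `"fdep"`, orientation risk, with
#'   a `loadings` attribute (the anchored leading eigenvector) and an
#'   `explained` attribute (leading eigenvalue share).
#' @export
fdep_score <- function(table) {
  z <- standardise_components(table)
  cm <- stats::cor(z)
  eig <- eigen(cm, symmetric = TRUE)
  if (abs(eig$values[1] - eig$values[2]) < 1e-9)
    hv_abort("heatvuln_instability_error",
             "leading eigenvalue is not unique; first component undefined")
  v <- eig$vectors[, 1]
  score <- drop(z %*% v)
  if (stats::cor(score, z[, "unemployment_rate"]) < 0) {
    v <- -v; score <- -score
  }
  all_ids <- table$unit_id
  values <- setNames(rep(NA_real_, length(all_ids)), all_ids)
  values[rownames(z)] <- score
  col <- indicator_column("fdep", values, "risk", units_label = "score")
  attr(col, "loadings") <- setNames(v, socio_components)
  attr(col, "explained") <- eig$values[1] / sum(eig$values)
  col
}
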