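# Internal helpers: typed error conditions and seeded random streams.

#' @keywords internal
hv_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "heatvuln_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

hv_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "heatvuln_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Deterministic per-generator stream: the stream seed depends only on the
# user seed and the generator name, so adding a generator never perturbs
# the draws of another. Restores the caller's RNG state on exit.
with_stream <- function(seed, name, expr) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  sub_seed <- (as.double(seed) * 1009 + h * 31) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub_seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (divisor n) standard deviation.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# Population z-scores of a plain numeric vector (NA preserved).
pop_scale <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sqrt(mean((x[!is.na(x)] - m)^2))
  if (!is.finite(s) || s <= 0) hv_abort("heatvuln_degenerate_variance_error",
                                        "zero dispersion: cannot standardise")
  (x - m) / s
}
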