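# Z-scores, imputation, the equal-weight composite, quantile classes.

zcols <- function(vals, orient) {
  nms <- c("temperature", "fdep", "artificial_fraction", "ac_rate")
  unname(Map(function(v, n, o) indicator_column(n, v, o), vals, nms, orient))
}

risk3_prot1 <- c("risk", "risk", "risk", "protective")

test_that("z-scores use the population convention and stay affine-invariant", {
  x <- ind(setNames(c(1, 2, 3), c("a", "b", "c")))
  z <- zscore(x)
  expect_equal(unname(z$values), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(unname(z$values)[1], -1.2247, tolerance = 1e-4)

  set.seed(6)
  y <- ind(setNames(runif(30, 10, 40), sprintf("u%02d", 1:30)))
  zy <- zscore(y)$values
  expect_equal(mean(zy), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(zy^2)), 1, tolerance = 1e-9)
  aff <- ind(3.7 * y$values + 11)
  expect_equal(zscore(aff)$values, zy, tolerance = 1e-9)

  expect_error(zscore(ind(setNames(rep(2, 5), letters[1:5]))),
               class = "heatvuln_degenerate_variance_error")
})

test_that("missing entries survive z-scoring untouched", {
  x <- ind(setNames(c(1, NA, 3, 5), c("a", "b", "c", "d")))
  z <- zscore(x)
  expect_identical(z$missing, "b")
  expect_equal(mean(z$values, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("imputation policies fill, flag, or leave missing as specified", {
  units <- four_squares()  # departments DA = {A1, A2}, DB = {B1, B2}
  x <- ind(setNames(c(NA, 2, 1, 3), c("A1", "A2", "B1", "B2")), name = "fdep")
  expect_identical(impute(x, units, "drop")$missing, "A1")

  filled <- suppressWarnings(impute(x, units, "department_median"))
  expect_equal(filled$values[["A1"]], 2)  # median of {2}
  expect_identical(filled$imputed, "A1")

  y <- ind(setNames(c(1, 2, 3), c("A1", "A2", "B1")))
  expect_identical(impute(y, units, "department_median"), y)

  # whole department missing stays missing
  z <- ind(setNames(c(NA, NA, 1, 3), c("A1", "A2", "B1", "B2")), name = "fdep")
  zi <- impute(z, units, "department_median")
  expect_setequal(zi$missing, c("A1", "A2"))

  # neighbour mean over polygon-adjacent units (A1 touches A2 and B1)
  nb <- suppressWarnings(impute(x, units, "neighbour_mean"))
  expect_equal(nb$values[["A1"]], mean(c(2, 1, 3)))  # A2, B1 edge + B2 corner
  expect_identical(nb$imputed, "A1")

  # department median: {1,2,3} in one department -> 2
  one_dept <- four_squares()
  one_dept$department_id <- rep("D", 4)
  w <- ind(setNames(c(1, 2, 3, NA), c("A1", "A2", "B1", "B2")))
  expect_equal(suppressWarnings(
    impute(w, one_dept, "department_median"))$values[["B2"]], 2)
})

test_that("the composite index is the equal-weight oriented mean", {
  ids <- sprintf("u%02d", 1:8)
  zero <- setNames(rep(0, 8), ids)
  cols <- zcols(list(zero, zero, zero, zero), risk3_prot1)
  v0 <- do.call(composite_index, cols)
  expect_equal(v0$index, rep(0, 8))

  one_t <- zero; one_t[] <- 0; one_t["u01"] <- 1
  cols <- zcols(list(one_t, zero, zero, zero), risk3_prot1)
  expect_equal(do.call(composite_index, cols)$index[1], 0.25)

  set.seed(12)
  vals <- replicate(4, setNames(rnorm(8), ids), simplify = FALSE)
  cols <- zcols(vals, risk3_prot1)
  got <- do.call(composite_index, cols)
  direct <- (vals[[1]] + vals[[2]] + vals[[3]] - vals[[4]]) / 4
  expect_equal(got$index, unname(direct[got$unit_id]), tolerance = 1e-12)
})

test_that("orientation metadata is enforced", {
  ids <- letters[1:6]
  v <- setNames(rnorm(6), ids)
  cols <- zcols(replicate(4, v, simplify = FALSE),
                c("risk", "risk", "risk", "risk"))
  expect_error(do.call(composite_index, cols),
               class = "heatvuln_orientation_error")
  expect_error(composite_index(cols[[1]], cols[[2]], cols[[3]], v),
               class = "heatvuln_orientation_error")
})

test_that("positive affine transforms of raw indicators leave V unchanged", {
  set.seed(14)
  ids <- sprintf("u%02d", 1:40)
  raw <- list(setNames(rnorm(40, 25, 2), ids), setNames(rnorm(40), ids),
              setNames(runif(40), ids), setNames(runif(40, 0, 60), ids))
  build <- function(r) do.call(composite_index,
                               zcols(lapply(r, function(v) zscore(ind(v))$values),
                                     risk3_prot1))
  v1 <- build(raw)$index
  raw2 <- Map(function(v, a, b) a * v + b, raw,
              c(1.8, 100, 7, 0.01), c(-30, 5, 2, 55))
  v2 <- build(raw2)$index
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("raising risk raises and raising protection lowers the rank", {
  set.seed(15)
  ids <- sprintf("u%02d", 1:30)
  raw <- list(temperature = setNames(rnorm(30, 24, 1.5), ids),
              fdep = setNames(rnorm(30), ids),
              artificial_fraction = setNames(runif(30), ids),
              ac_rate = setNames(runif(30, 5, 50), ids))
  build <- function(r) {
    cols <- zcols(lapply(r, function(v) zscore(ind(v))$values), risk3_prot1)
    s <- do.call(composite_index, cols)
    setNames(rank(s$index), s$unit_id)
  }
  base_rank <- build(raw)
  target <- "u07"
  for (nm in c("temperature", "fdep", "artificial_fraction")) {
    up <- raw; up[[nm]][target] <- up[[nm]][target] + 2 * sd(up[[nm]])
    expect_gte(build(up)[[target]], base_rank[[target]])
  }
  up <- raw; up$ac_rate[target] <- up$ac_rate[target] + 2 * sd(up$ac_rate)
  expect_lte(build(up)[[target]], base_rank[[target]])
})

test_that("permuting unit order permutes the scores identically", {
  set.seed(16)
  ids <- sprintf("u%02d", 1:20)
  vals <- replicate(4, setNames(rnorm(20), ids), simplify = FALSE)
  a <- do.call(composite_index, zcols(vals, risk3_prot1))
  perm <- sample(20)
  b <- do.call(composite_index,
               zcols(lapply(vals, function(v) v[perm]), risk3_prot1))
  expect_equal(setNames(b$index, b$unit_id)[a$unit_id],
               setNames(a$index, a$unit_id))
})

test_that("quantile classes split evenly and collapse degenerately", {
  cls <- quantile_classes(1:10, k = 5)
  expect_equal(as.integer(cls), rep(1:5, each = 2))

  expect_warning(one <- quantile_classes(rep(3, 7), k = 4),
                 class = "heatvuln_class_collapse_warning")
  expect_true(all(one == 1))

  set.seed(18)
  u <- runif(1000)
  cls5 <- quantile_classes(u, k = 5)
  expect_equal(as.integer(table(cls5)), rep(200L, 5))

  withNA <- c(NA, 1:6, NA)
  c2 <- quantile_classes(withNA, k = 2)
  expect_true(all(is.na(c2[c(1, 8)])))
  expect_equal(as.integer(c2[2:7]), c(1, 1, 1, 2, 2, 2))

  expect_error(quantile_classes(1:3, k = 5), class = "heatvuln_schema_error")
})
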