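# Missingness filter, imputation, scaling, correlate removal, outliers.

test_that("missingness filter uses a strict threshold and preserves order", {
  m <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1:4, 2] <- NA   # 40% missing -> dropped
  m[1:3, 3] <- NA   # exactly 30% -> retained
  f <- filter_missingness(m, 0.30)
  expect_identical(colnames(f$matrix), c("a", "c"))
  expect_identical(f$excluded, "b")
  # zero missingness passes through untouched
  clean <- matrix(rnorm(20), 5, 4)
  expect_identical(filter_missingness(clean)$matrix, clean)
  expect_error(filter_missingness(matrix(NA_real_, 4, 2)), "all metabolites")
})

test_that("imputation honours observed cells, seeds, and linear structure", {
  set.seed(1)
  x <- runif(80, 1, 5)
  m <- cbind(a = x, b = 2 * x + 1, c = runif(80, 1, 5))
  complete <- impute_missing(m, seed = 1)
  expect_identical(complete, m)  # nothing missing -> unchanged

  m2 <- m
  truth <- m2[7, "b"]
  m2[7, "b"] <- NA
  imp <- impute_missing(m2, seed = 1)
  expect_identical(imp[-7, ], m2[-7, ])
  # b is perfectly determined by a; forest prediction within 10%
  expect_lt(abs(imp[7, "b"] - truth) / truth, 0.10)
  imp2 <- impute_missing(m2, seed = 1)
  expect_identical(imp, imp2)
  imp3 <- impute_missing(m2, seed = 2)
  expect_false(identical(imp[7, "b"], imp3[7, "b"]))
})

test_that("imputation refuses degenerate columns", {
  m <- cbind(a = c(NA, NA, NA), b = c(1, 2, 3))
  colnames(m) <- c("a", "b")
  expect_error(impute_missing(m, seed = 1), "fully missing")
})

test_that("log2 + Pareto scaling matches the arithmetic oracle", {
  m <- cbind(met = c(1, 2, 4, 8))
  s <- log2_pareto(m)
  sdv <- sd(c(0, 1, 2, 3))            # 1.290994...
  expect_equal(sdv, 1.2909944, tolerance = 1e-6)
  expect_equal(as.vector(s),
               (c(0, 1, 2, 3) - 1.5) / sqrt(sdv), tolerance = 1e-9)
  expect_equal(sqrt(sdv), 1.1362193, tolerance = 1e-6)
  # algebraic identity: post-scaling column variance = pre-scaling sd
  m2 <- matrix(rlnorm(200), 40, 5,
               dimnames = list(NULL, paste0("m", 1:5)))
  s2 <- log2_pareto(m2)
  pre_sd <- apply(log2(m2), 2, sd)
  expect_equal(unname(apply(s2, 2, var)), unname(pre_sd),
               tolerance = 1e-10)
})

test_that("log2 + Pareto handles nonpositive and constant columns per policy", {
  bad <- cbind(a = c(1, -2, 3))
  expect_error(log2_pareto(bad), "nonpositive")
  con <- cbind(a = rep(4, 5), b = c(1, 2, 3, 4, 5))
  expect_warning(s <- log2_pareto(con), "constant")
  expect_true(all(s[, "a"] == 0))
})

test_that("perfect-correlate removal drops later columns only", {
  set.seed(2)
  x <- rnorm(50)
  m <- cbind(a = x, b = rnorm(50), c = 3 * x + 2)
  d <- drop_perfect_correlates(m)
  expect_identical(d$dropped, "c")
  expect_identical(colnames(d$matrix), c("a", "b"))
  # independent columns survive
  ind <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  expect_length(drop_perfect_correlates(ind)$dropped, 0)
  # three mutually identical columns: the first is kept, two dropped
  tri <- cbind(a = x, b = x, c = x, d = rnorm(50))
  d3 <- drop_perfect_correlates(tri)
  expect_setequal(d3$dropped, c("b", "c"))
})

test_that("Hotelling-T2 outlier detection flags a displaced duplicate only", {
  base <- matrix(rep(c(1, 2, 3, 4, 5), each = 60), 60, 5)
  base[60, ] <- base[60, ] + 8
  rownames(base) <- sprintf("s%02d", 1:60)
  expect_warning(out <- detect_outliers_pca(base), "components")
  expect_identical(out$outliers, "s60")
})

test_that("outlier flag rate on a spherical cloud matches the F calibration", {
  set.seed(4)
  cloud <- matrix(rnorm(1000 * 8), 1000, 8)
  out <- detect_outliers_pca(cloud, alpha = 0.05)
  frac <- length(out$outliers) / 1000
  # joint rate over the (1,2) and (1,3) planes, near-nominal
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("pipeline recovers the planted structure of the default cohort", {
  coh <- simulate_cohort(cohort_spec(seed = 1))
  pp <- preprocess_concentrations(coh$concentrations, seed = 2)
  expect_length(pp$report$excluded_metabolites, 8)
  expect_equal(ncol(pp$imputed), 54)
  expect_identical(pp$report$dropped_correlates, "fumarate")
  expect_true(all(coh$outliers %in% pp$report$outliers))
  expect_false(any(pp$report$outliers %in% rownames(pp$normalized)))
  # retained column order preserved
  expect_identical(colnames(pp$imputed),
                   setdiff(colnames(coh$concentrations),
                           pp$report$excluded_metabolites))
  # deterministic stages are idempotent
  f2 <- filter_missingness(pp$imputed)
  expect_identical(f2$matrix, pp$imputed)
  expect_identical(impute_missing(pp$imputed, seed = 9), pp$imputed)
  expect_length(drop_perfect_correlates(pp$normalized)$dropped, 0)
})
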