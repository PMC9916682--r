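# Hierarchical phenotype discovery and PLS-DA variable importance.

test_that("complete linkage recovers 4 well-separated pairs, matching brute force", {
  set.seed(10)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  pts <- centers[rep(1:4, each = 2), ] + matrix(rnorm(16, sd = 0.2), 8, 2)
  rownames(pts) <- paste0("p", 1:8)
  hc <- hier_cluster(pts, k = 4)
  truth <- rep(1:4, each = 2)
  expect_equal(adjusted_rand(hc$labels, truth), 1)
  # brute force: the pairing minimises the maximum cluster diameter over
  # all 4-block partitions of the 8 points
  D <- as.matrix(dist(pts))
  diam <- function(blocks) max(vapply(blocks, function(b)
    if (length(b) == 1) 0 else max(D[b, b]), numeric(1)))
  parts <- set_partitions_k(8, 4)
  best <- parts[[which.min(vapply(parts, diam, numeric(1)))]]
  best_labels <- integer(8)
  for (i in seq_along(best)) best_labels[best[[i]]] <- i
  expect_equal(adjusted_rand(best_labels, truth), 1)
})

test_that("k = 1 yields a single cluster; oversized k errors", {
  m <- matrix(rnorm(30), 10, 3)
  rownames(m) <- paste0("s", 1:10)
  expect_true(all(hier_cluster(m, k = 1)$labels == 1))
  expect_error(hier_cluster(m, k = 11), "exceeds")
})

test_that("cluster labels are invariant to sample order up to relabeling", {
  coh <- simulate_cohort(cohort_spec(seed = 6))
  pp <- preprocess_concentrations(coh$concentrations, seed = 7)
  hc1 <- hier_cluster(pp$normalized, k = 4)
  perm <- sample(nrow(pp$normalized))
  hc2 <- hier_cluster(pp$normalized[perm, ], k = 4)
  common <- rownames(pp$normalized)
  expect_equal(adjusted_rand(hc1$labels[common], hc2$labels[common]), 1)
})

test_that("default cohort phenotypes are recovered with high fidelity", {
  coh <- simulate_cohort(cohort_spec(seed = 1))
  pp <- preprocess_concentrations(coh$concentrations, seed = 2)
  pats <- intersect(rownames(pp$normalized),
                    coh$samples$sample_id[coh$samples$type == "patient"])
  hc <- hier_cluster(pp$normalized[pats, ], k = 4)
  expect_gte(adjusted_rand(hc$labels, coh$phenotype[pats]), 0.9)
  # letter assignment marks the high-succinate cluster as D
  letters <- assign_phenotype_letters(hc, pp$normalized[pats, ],
                                      marker = "succinate")
  succ_means <- tapply(pp$normalized[pats, "succinate"], letters, mean)
  expect_equal(names(which.max(succ_means)), "D")
  # and the recovered D is the planted D
  tab <- table(letters, coh$phenotype[pats])
  expect_equal(names(which.max(tab["D", ])), "D")
})

test_that("a single separating metabolite earns the top VIP score", {
  set.seed(11)
  X <- matrix(rnorm(60 * 12), 60, 12,
              dimnames = list(NULL, paste0("m", 1:12)))
  y <- rep(c("g1", "g2"), each = 30)
  X[, "m5"] <- X[, "m5"] + ifelse(y == "g1", 2.5, -2.5)
  vip <- plsda_vip(X, y, n_components = 2)
  expect_equal(vip$metabolite[1], "m5")
  expect_equal(mean(vip$vip^2), 1, tolerance = 1e-8)
  expect_true(all(vip$vip >= 0))
  expect_error(plsda_vip(X[1:31, ], c(rep("a", 30), "b")), "single sample")
})

test_that("VIP ranking is invariant to metabolite column permutation", {
  set.seed(12)
  X <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(NULL, paste0("m", 1:8)))
  y <- rep(c("a", "b"), each = 20)
  X[, "m2"] <- X[, "m2"] + ifelse(y == "a", 1.5, -1.5)
  v1 <- plsda_vip(X, y)
  perm <- sample(8)
  v2 <- plsda_vip(X[, perm], y)
  expect_equal(v1$vip[order(v1$metabolite)],
               v2$vip[order(v2$metabolite)], tolerance = 1e-10)
})

test_that("under label permutation the planted metabolite's VIP rank is null", {
  set.seed(13)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(NULL, paste0("m", 1:10)))
  y <- rep(c("a", "b"), each = 25)
  X[, "m3"] <- X[, "m3"] + ifelse(y == "a", 2, -2)
  ranks <- replicate(200, {
    v <- plsda_vip(X, sample(y))
    v$rank[v$metabolite == "m3"]
  })
  # uniform over 1..10: mean 5.5, sd 2.87; 200 draws pin the mean well
  expect_gt(mean(ranks), 4.3)
  expect_lt(mean(ranks), 6.7)
  expect_gt(length(unique(ranks)), 5)
})

test_that("succinate ranks in the top 3 VIP metabolites of the default cohort", {
  coh <- simulate_cohort(cohort_spec(seed = 1))
  pp <- preprocess_concentrations(coh$concentrations, seed = 2)
  pats <- intersect(rownames(pp$normalized),
                    coh$samples$sample_id[coh$samples$type == "patient"])
  hc <- hier_cluster(pp$normalized[pats, ], k = 4)
  letters <- assign_phenotype_letters(hc, pp$normalized[pats, ])
  vip <- plsda_vip(pp$normalized[pats, ], letters)
  expect_lte(vip$rank[vip$metabolite == "succinate"], 3)
})

test_that("heatmap rendering writes a leaf-ordered CSV matching the tree", {
  coh <- simulate_cohort(cohort_spec(seed = 8))
  pp <- preprocess_concentrations(coh$concentrations, seed = 9)
  hc <- hier_cluster(pp$normalized, k = 4)
  path <- withr::local_tempfile(fileext = ".png")
  files <- render_phenotype_heatmap(pp$normalized, hc, path)
  csv <- read.csv(files[["csv"]], check.names = FALSE)
  expect_setequal(csv$sample_id, rownames(pp$normalized))
  expect_identical(csv$sample_id,
                   rownames(pp$normalized)[hc$tree$order])
  files2 <- render_phenotype_heatmap(pp$normalized, hc, path)
  expect_identical(readLines(files[["csv"]]), readLines(files2[["csv"]]))
})
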