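# Metabolic-task evaluation, normalization, clustering, ratios.

test_that("a linear chain task scores the uptake bound", {
  chain <- chain_network(ex_a = c(-5, 0))
  task <- list(task_id = "b_from_a", sources = "A_e", products = "B",
               objective = "DM_B", cofactors = "")
  res <- evaluate_task(chain, task)
  expect_equal(res$activity, 5, tolerance = 1e-9)
  expect_equal(res$status, "optimal")
  expect_error(
    evaluate_task(chain, list(task_id = "bad", sources = "ghost_e",
                              products = "", objective = "EX_B",
                              cofactors = "")),
    "unknown")
})

test_that("a product without a producing route is blocked at zero", {
  net <- metabolic_network(
    "orphan",
    metabolites = data.frame(id = c("A_e", "A", "Z"),
                             compartment = c("e", "c", "c")),
    reactions = data.frame(id = c("EX_A", "T1"),
                           lb = c(-5, 0), ub = c(0, 1000)),
    stoich = list(EX_A = c(A_e = -1), T1 = c(A_e = -1, A = 1)))
  res <- evaluate_task(net, list(task_id = "z", sources = "A_e",
                                 products = "Z", objective = "DM_Z",
                                 cofactors = ""))
  expect_equal(res$activity, 0)
  expect_equal(res$status, "blocked")
})

test_that("task activity never exceeds the fully-open optimum and is source-monotone", {
  net <- build_toy_ecgem()
  catalog <- build_toy_task_catalog()
  task <- catalog[catalog$task_id == "atp_glucose_total", ]
  open_opt <- evaluate_task(net, task)$activity
  tight <- set_bounds(net, "EX_glc_e", lb = -3)
  tight_opt <- evaluate_task(tight, task)$activity
  expect_lte(tight_opt, open_opt + 1e-6)
  tighter <- set_bounds(net, "EX_glc_e", lb = -1)
  expect_lte(evaluate_task(tighter, task)$activity, tight_opt + 1e-6)
})

test_that("the activity matrix is deterministic with model-wise columns", {
  net <- build_toy_ecgem()
  catalog <- build_toy_task_catalog()
  tam <- task_activity_matrix(list(m1 = net, m2 = net), catalog)
  expect_equal(tam$raw[, "m1"], tam$raw[, "m2"])
  tam_rev <- task_activity_matrix(list(m2 = net, m1 = net), catalog)
  expect_equal(tam$raw[, c("m2", "m1")], tam_rev$raw)
  expect_false(any(tam$status == "infeasible"))
})

test_that("row normalization maps linearly onto [-1.5, 1.5]", {
  m <- rbind(a = c(0, 5, 10), b = c(2, 2, 2), c = c(-1, 0, 3))
  nm <- normalize_activity(m)
  expect_equal(unname(nm$normalized["a", ]), c(-1.5, 0, 1.5))
  expect_equal(unname(nm$normalized["b", ]), c(0, 0, 0))
  expect_identical(nm$constant_rows, "b")
  expect_equal(range(nm$normalized["c", ]), c(-1.5, 1.5))
  # idempotence
  nm2 <- normalize_activity(nm$normalized)
  expect_equal(nm2$normalized, nm$normalized)
})

test_that("task clustering merges identical rows first and is deterministic", {
  m <- rbind(t1 = c(-1.5, 0, 1.5), t2 = c(-1.5, 0, 1.5),
             t3 = c(1.5, 0, -1.5), t4 = c(1.4, 0.1, -1.5))
  ct <- cluster_tasks(m)
  first <- sort(ct$tree$merge[1, ])
  expect_equal(first, c(-2, -1))  # t1, t2 merge at height 0
  ct2 <- cluster_tasks(m)
  expect_identical(ct$tree$merge, ct2$tree$merge)
  expect_setequal(rownames(ct$ordered), rownames(m))
})

test_that("the three planted activity archetypes separate at k = 3", {
  net <- build_toy_ecgem()
  bs <- sample_fluxes(net, 800, seed = 30)
  mapping <- toy_exchange_mapping()
  # archetypal fold-change profiles: glycolytic, intermediate/redox-high,
  # redox-high, catabolic
  fc_by_model <- list(
    A = c(glucose = 2.3, lactate = 2.3, methylglyoxal = 2.3,
          acetoacetate = 2.0),
    B = c(glutamine = 2.3, glutamate = 2.3),
    C = c(glutamine = 2.0, glutamate = 2.0),
    D = c(palmitate = 2.3, alanine = 2.3, urea = 2.3, glucose = 0.66,
          glutamine = 0.57, glutamate = 0.57))
  models <- lapply(fc_by_model, function(f) {
    full <- setNames(rep(1, nrow(mapping)), mapping$metabolite_id)
    full[names(f)] <- f
    contextualize_from_fc(net, bs, full, mapping)
  })
  catalog <- build_toy_task_catalog()
  tam <- task_activity_matrix(models, catalog)
  nm <- normalize_activity(tam)
  grp <- cutree(cluster_tasks(nm$normalized)$tree, k = 3)
  glycolytic <- c("atp_glycolysis", "atp_glucose_total", "mgx_synthesis",
                  "lactate_from_glucose", "r5p_synthesis", "acac_synthesis")
  catabolic <- c("pmtle_synthesis", "malcoa_synthesis", "tca_nadh",
                 "etc_atp")
  redox <- c("trdr_activity", "nadph_generation")
  truth <- c(rep(1, length(glycolytic)), rep(2, length(catabolic)),
             rep(3, length(redox)))
  names(truth) <- c(glycolytic, catabolic, redox)
  expect_equal(adjusted_rand(grp[names(truth)], truth), 1)
})

test_that("task ratios follow raw entries and flag zero denominators", {
  m <- rbind(t1 = c(10, 2), t2 = c(3, 3), t3 = c(1, 0))
  colnames(m) <- c("a", "b")
  expect_equal(task_ratio(m, "t1", "a", "b")$ratio, 5)
  expect_equal(task_ratio(m, "t2", "a", "b")$ratio, 1)
  r0 <- task_ratio(m, "t3", "a", "b")
  expect_true(is.infinite(r0$ratio))
  expect_false(r0$finite)
})
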