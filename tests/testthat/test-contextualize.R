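# Quartile bounds, fold changes, scaling, minimal relaxation.

test_that("transport quartiles follow the linear-interpolation convention", {
  fake <- structure(list(samples = cbind(r1 = rep(3.5, 100), r2 = 1:100),
                         sampler = "x", seed = 1, warmup = 0, thin = 1),
                    class = "FluxSampleSet")
  tb <- transport_quartiles(fake, c("r1", "r2"))
  expect_equal(tb$q1[tb$reaction == "r1"], 3.5)
  expect_equal(tb$q3[tb$reaction == "r1"], 3.5)
  expect_equal(tb$q1[tb$reaction == "r2"], 25.75)
  expect_equal(tb$q3[tb$reaction == "r2"], 75.25)
  expect_true(all(tb$q1 <= tb$q3))
  expect_error(transport_quartiles(fake, "ghost"), "absent")
})

test_that("fold changes are ratios of raw means with unmapped metabolites reported", {
  mapping <- data.frame(metabolite_id = c("glc", "lac"),
                        reaction_id = c("EX_g", "EX_l"))
  ph <- cbind(glc = c(10, 10), lac = c(4, 6), other = c(1, 3))
  hv <- cbind(glc = c(2, 2), lac = c(5, 5), other = c(2, 2))
  fc <- compute_fold_changes(ph, hv, mapping)
  expect_equal(unname(fc$fc["glc"]), 5)
  expect_equal(unname(fc$fc["lac"]), 1)
  expect_identical(fc$unmapped, "other")
  hv_bad <- hv; hv_bad[, "glc"] <- 0
  expect_error(compute_fold_changes(ph, hv_bad, mapping), "healthy mean")
})

test_that("generator calibration: fold changes recover two-to-the-shift at large n", {
  spec <- cohort_spec(phenotype_sizes = c(A = 2000, B = 50, C = 50, D = 2000),
                      n_per_iss_stratum = c(0, 0, 4104), n_healthy = 2000,
                      seed = 14)
  coh <- simulate_cohort(spec)
  pats_d <- names(coh$phenotype)[coh$phenotype == "D"]
  pats_d <- setdiff(pats_d, coh$outliers)
  healthy <- coh$samples$sample_id[coh$samples$type == "healthy"]
  mapping <- toy_exchange_mapping()
  conc <- coh$concentrations
  conc[is.na(conc)] <- 1  # crude fill; large n swamps it
  fc <- compute_fold_changes(conc[pats_d, ], conc[healthy, ], mapping)
  shift <- coh$spec$shift["D", ]
  for (met in c("glucose", "succinate", "palmitate", "glutamine")) {
    expect_equal(unname(fc$fc[met]), 2^shift[[met]], tolerance = 0.1,
                 label = met)
  }
})

test_that("fold-change scaling preserves bound ordering under any sign", {
  tb <- structure(data.frame(reaction = c("up", "sec", "keep"),
                             q1 = c(-4, 1, -2), q3 = c(-1, 3, 5)),
                  class = c("TransportBounds", "data.frame"))
  fc <- structure(list(fc = c(m1 = 2, m2 = 0.5),
                       reactions = c(m1 = "up", m2 = "sec"),
                       unmapped = character(0)),
                  class = "FoldChangeVector")
  cb <- apply_fold_changes(tb, fc)
  expect_equal(cb$lb[cb$reaction == "up"], -8)
  expect_equal(cb$ub[cb$reaction == "up"], -2)
  expect_equal(cb$lb[cb$reaction == "sec"], 0.5)
  expect_equal(cb$ub[cb$reaction == "sec"], 1.5)
  # unmapped reaction keeps baseline quartiles
  expect_equal(cb$lb[cb$reaction == "keep"], -2)
  expect_equal(cb$ub[cb$reaction == "keep"], 5)
  expect_true(all(cb$lb <= cb$ub))
  # FC = 1 leaves bounds untouched
  fc1 <- fc; fc1$fc[] <- 1
  cb1 <- apply_fold_changes(tb, fc1)
  expect_equal(cb1$lb, tb$q1)
  expect_equal(cb1$ub, tb$q3)
})

test_that("relaxation widens exactly the binding constrained bound", {
  chain <- chain_network()
  ok_cb <- data.frame(reaction = "EX_A", lb = -6, ub = -1, fc = 1)
  cm <- relax_to_feasible(chain, ok_cb)
  expect_equal(nrow(cm$relaxation_log), 0)
  expect_true(check_feasibility(cm$model)$feasible)

  capped <- set_bounds(chain, "R1", ub = 1)
  cb <- data.frame(reaction = "EX_A", lb = -8, ub = -2, fc = 2)
  cm2 <- relax_to_feasible(capped, cb)
  expect_equal(nrow(cm2$relaxation_log), 1)
  expect_equal(cm2$relaxation_log$reaction, "EX_A")
  expect_equal(cm2$relaxation_log$bound, "ub")
  expect_equal(cm2$relaxation_log$slack, 1, tolerance = 1e-6)
  expect_true(check_feasibility(cm2$model)$feasible)
  # only reactions whose final bounds differ appear in the log
  changed <- cm2$model$reactions$id[
    cm2$model$reactions$lb != capped$reactions$lb |
    cm2$model$reactions$ub != capped$reactions$ub]
  expect_setequal(setdiff(changed, cb$reaction), character(0))
})

test_that("all-FC-1 contextualization of the toy network needs no relaxation", {
  net <- build_toy_ecgem()
  bs <- sample_fluxes(net, 800, seed = 15)
  mapping <- toy_exchange_mapping()
  fc1 <- setNames(rep(1, nrow(mapping)), mapping$metabolite_id)
  cm <- contextualize_from_fc(net, bs, fc1, mapping)
  expect_equal(nrow(cm$relaxation_log), 0)
  expect_true(check_feasibility(cm$model)$feasible)
})

test_that("doubling a single uptake fold change never shrinks a consuming task", {
  net <- build_toy_ecgem()
  bs <- sample_fluxes(net, 800, seed = 16)
  mapping <- toy_exchange_mapping()
  fc1 <- setNames(rep(1, nrow(mapping)), mapping$metabolite_id)
  fc2 <- fc1; fc2["glucose"] <- 2
  cm1 <- contextualize_from_fc(net, bs, fc1, mapping)
  cm2 <- contextualize_from_fc(net, bs, fc2, mapping)
  catalog <- build_toy_task_catalog()
  for (id in c("atp_glycolysis", "lactate_from_glucose", "r5p_synthesis")) {
    task <- catalog[catalog$task_id == id, ]
    a1 <- evaluate_task(cm1$model, task, base_net = net)$activity
    a2 <- evaluate_task(cm2$model, task, base_net = net)$activity
    expect_gte(a2 + 1e-6, a1)
  }
})

test_that("the two-phenotype design shifts glycolytic and catabolic capacity oppositely", {
  net <- build_toy_ecgem()
  bs <- sample_fluxes(net, 800, seed = 17)
  mapping <- toy_exchange_mapping()
  fcs <- two_phenotype_fold_changes()
  cmA <- contextualize_from_fc(net, bs, fcs$A_like, mapping)
  cmD <- contextualize_from_fc(net, bs, fcs$D_like, mapping)
  catalog <- build_toy_task_catalog()
  tam <- task_activity_matrix(list(A = cmA, D = cmD), catalog)
  expect_gt(task_ratio(tam, "atp_glycolysis", "A", "D")$ratio, 1)
  expect_lt(task_ratio(tam, "tca_nadh", "A", "D")$ratio, 1)
})

test_that("contextualized models serialize with their relaxation log", {
  net <- build_toy_ecgem()
  bs <- sample_fluxes(net, 400, seed = 18)
  mapping <- toy_exchange_mapping()
  fc1 <- setNames(rep(1, nrow(mapping)), mapping$metabolite_id)
  cm <- contextualize_from_fc(net, bs, fc1, mapping)
  path <- file.path(withr::local_tempdir(), "model.json")
  files <- write_contextualized_model(cm, path)
  re <- load_network(files[["network"]])
  expect_equal(re$reactions[, c("id", "lb", "ub")],
               cm$model$reactions[, c("id", "lb", "ub")])
})
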