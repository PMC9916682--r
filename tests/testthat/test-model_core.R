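# Network representation, I/O, FBA, feasibility.

test_that("JSON network round-trips identically and loader validates input", {
  net <- build_toy_ecgem()
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  re <- load_network(path)
  expect_equal(re$metabolites, net$metabolites)
  expect_equal(re$reactions[, c("id", "lb", "ub", "kind")],
               net$reactions[, c("id", "lb", "ub", "kind")])
  expect_equal(re$stoich, net$stoich)
  expect_equal(re$objective$reaction, net$objective$reaction)

  expect_error(
    metabolic_network(
      "bad",
      metabolites = data.frame(id = "A", compartment = "c"),
      reactions = data.frame(id = "R1", lb = 0, ub = 1),
      stoich = list(R1 = c(ghost = 1))),
    "undeclared")
  expect_error(
    metabolic_network(
      "dup",
      metabolites = data.frame(id = "A", compartment = "c"),
      reactions = data.frame(id = c("R1", "R1"), lb = 0, ub = 1),
      stoich = list(R1 = c(A = 1))),
    "duplicate")
  expect_error(load_network(file.path(tempdir(), "nope.json")), "no such")
})

test_that("toy network loads with the manifest counts and inferred kinds", {
  net <- build_toy_ecgem()
  man <- toy_manifest()
  expect_identical(nrow(net$metabolites), man$n_metabolites)
  expect_identical(nrow(net$reactions), man$n_reactions)
  expect_identical(sum(net$reactions$kind == "exchange"), man$n_exchanges)
  # every exchange touches exactly one boundary metabolite
  for (r in net$reactions$id[net$reactions$kind == "exchange"]) {
    s <- net$stoich[[r]]
    expect_length(s, 1)
    expect_equal(
      net$metabolites$compartment[net$metabolites$id == names(s)], "e")
  }
})

test_that("SBML reader recovers species, stoichiometry and fbc bounds", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="mini">
    <listOfCompartments><compartment id="e"/><compartment id="c"/></listOfCompartments>
    <listOfSpecies>
      <species id="A_e" compartment="e"/>
      <species id="A" compartment="c"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_m10" value="-10"/>
      <parameter id="ub_0" value="0"/>
      <parameter id="ub_1000" value="1000"/>
      <parameter id="lb_0" value="0"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" lowerFluxBound="lb_m10" upperFluxBound="ub_0">
        <listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>
      </reaction>
      <reaction id="T1" reversible="false" lowerFluxBound="lb_0" upperFluxBound="ub_1000">
        <listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- load_network(path)
  expect_setequal(net$metabolites$id, c("A_e", "A"))
  expect_equal(net$reactions$lb[net$reactions$id == "EX_A"], -10)
  expect_equal(net$reactions$ub[net$reactions$id == "EX_A"], 0)
  expect_equal(net$stoich$T1[c("A_e", "A")], c(A_e = -1, A = 1))
  expect_equal(net$reactions$kind[net$reactions$id == "EX_A"], "exchange")
})

test_that("fba solves the linear chain at the binding bound", {
  chain <- chain_network()
  sol <- fba(chain, "EX_B")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  # internal cap binds instead
  sol5 <- fba(set_bounds(chain, "R1", ub = 5), "EX_B")
  expect_equal(sol5$objective, 5, tolerance = 1e-9)
  # steady state and bounds of the returned vertex
  S <- stoich_matrix(chain)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= chain$reactions$lb - 1e-6 &
                  sol$fluxes <= chain$reactions$ub + 1e-6))
})

test_that("fba reports bound inconsistency and infeasibility explicitly", {
  chain <- chain_network()
  bad <- set_bounds(chain, "R1", lb = 7, ub = 5)
  sol <- fba(bad, "EX_B")
  expect_equal(sol$status, "infeasible_by_bounds")
  expect_true("R1" %in% sol$detail)
  # forced uptake 10 against capacity 5
  inf <- set_bounds(chain, "EX_A", lb = -10, ub = -10)
  inf <- set_bounds(inf, "R1", ub = 5)
  expect_equal(fba(inf, "EX_B")$status, "infeasible")
})

test_that("fba matches the brute-force vertex-enumeration oracle", {
  set.seed(101)
  chain <- chain_network()
  for (trial in 1:25) {
    net <- chain
    net$reactions$lb <- pmin(round(runif(5, -8, 0), 1), 0)
    net$reactions$ub <- round(runif(5, 0, 8), 1)
    obj <- sample(net$reactions$id, 1)
    oracle <- fba_oracle(net, obj)
    sol <- fba(net, obj)
    expect_equal(sol$status, "optimal")
    expect_equal(sol$objective, oracle, tolerance = 1e-6)
  }
})

test_that("check_feasibility certifies slack and names bad bounds", {
  chain <- chain_network()
  ok <- check_feasibility(chain)
  expect_true(ok$feasible)
  expect_equal(ok$total_slack, 0)

  forced <- set_bounds(chain, "EX_A", lb = -10, ub = -10)
  forced <- set_bounds(forced, "R1", ub = 5)
  rep <- check_feasibility(forced)
  expect_false(rep$feasible)
  expect_equal(rep$total_slack, 5, tolerance = 1e-6)

  bad <- set_bounds(chain, "T2", lb = 3, ub = 1)
  repb <- check_feasibility(bad)
  expect_equal(repb$status, "infeasible_by_bounds")
  expect_true("T2" %in% repb$bad_bounds)
})

test_that("sampled fluxes satisfy steady state, bounds, and seed identity", {
  net <- polytope_1d_network()
  ss <- sample_fluxes(net, 500, seed = 7)
  expect_true(all(samples_feasible(ss, net, tol = 1e-6)))
  ss2 <- sample_fluxes(net, 500, seed = 7)
  expect_identical(ss$samples, ss2$samples)
  ss3 <- sample_fluxes(net, 500, seed = 8)
  expect_false(identical(ss$samples, ss3$samples))
})

test_that("sampling a 1-D polytope with range [2, 6] is centred near 4", {
  net <- polytope_1d_network()
  ss <- sample_fluxes(net, 1000, seed = 11)
  m <- mean(ss$samples[, "EX_B"])
  expect_gte(m, 3.8)
  expect_lte(m, 4.2)
  # all three reactions carry the same flux
  expect_lt(max(abs(ss$samples[, "EX_B"] + ss$samples[, "EX_A"])), 1e-6)
})

test_that("sampling is invariant to reaction ordering up to relabeling", {
  net <- polytope_1d_network()
  perm <- c(3, 1, 2)
  net2 <- net
  net2$reactions <- net$reactions[perm, ]
  net2$stoich <- net$stoich[perm]
  s1 <- sample_fluxes(net, 200, seed = 5)
  s2 <- sample_fluxes(net2, 200, seed = 5)
  expect_equal(s1$samples[, sort(colnames(s1$samples))],
               s2$samples[, sort(colnames(s2$samples))])
})

test_that("fba optimum dominates every sampled flux of the objective", {
  net <- build_toy_ecgem()
  ss <- sample_fluxes(net, 300, seed = 13)
  opt <- fba(net, "ATPM")$objective
  expect_gte(opt + 1e-6, max(ss$samples[, "ATPM"]))
})
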