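test_that("enzyme knockouts delete the catalyzed reactions", {
  toy <- toy_network()
  cfg0 <- toy$config
  expect_identical(apply_disease_knockouts(toy$network, cfg0), toy$network)

  cfg <- scenario_config(toy$config$objective_weights,
                         default_flux_upper = 10,
                         inhibited_enzymes = "E5")
  net <- apply_disease_knockouts(toy$network, cfg)
  expect_equal(length(net$reactions), 7)
  expect_false("R5" %in% net$reaction_ids)
  expect_equal(unname(classify_metabolites(net)["C9"]), "isolated")

  # one enzyme catalyzing two reactions takes both out
  rxns <- list(parse_reaction_equation("A -> B", "R1", "E"),
               parse_reaction_equation("A -> C", "R2", "E"),
               parse_reaction_equation("A -> D", "R3", "F"))
  net2 <- build_network(c("A", "B", "C", "D"), rxns)
  cfg2 <- scenario_config(c(D = 1), default_flux_upper = 1,
                          inhibited_enzymes = "E")
  expect_equal(apply_disease_knockouts(net2, cfg2)$reaction_ids, "R3")
  expect_warning(
    apply_disease_knockouts(net2, scenario_config(
      c(D = 1), default_flux_upper = 1, inhibited_enzymes = "nope")),
    "matching no reaction")
})

test_that("the pathologic LP has the documented structure", {
  toy <- toy_network()
  lp <- build_pathologic_lp(toy$network, toy$config)
  expect_s3_class(lp, "linear_program")
  expect_length(lp$vars, 8 + 12)
  expect_true(lp$maximize)
  # C6 is an intermediate: production row v1 + 3 v2 = x_C6 and
  # consumption row 2 v6 + v7 = x_C6 must both be present
  prod_row <- lp$A[lp$row_labels == "production_C6", ]
  expect_equal(prod_row[c("v_R1", "v_R2", "x_C6")], c(v_R1 = 1, v_R2 = 3,
                                                      x_C6 = -1))
  cons_row <- lp$A[lp$row_labels == "consumption_C6", ]
  expect_equal(cons_row[c("v_R6", "v_R7", "x_C6")], c(v_R6 = 2, v_R7 = 1,
                                                      x_C6 = -1))
  expect_equal(unname(lp$upper[paste0("v_R", 1:8)]), rep(10, 8))
})

test_that("single reaction A -> B pins x_A = v = x_B at the flux cap", {
  net <- single_reaction_network()
  cfg <- scenario_config(c(B = 1), default_flux_upper = 7)
  st <- solve_pathologic(net, cfg)
  expect_equal(st$solver_status, "optimal")
  expect_equal(unname(st$v), 7)
  expect_equal(unname(st$x), c(7, 7))
  expect_state_feasible(net, cfg, st)
})

test_that("pathologic optimum matches grid-search oracles on tiny networks", {
  # chain A -> B -> C: feasible set is v1 = v2 = t, t in [0, min(U)]
  net <- chain_network()
  cfg <- scenario_config(c(C = 1), flux_upper = c(R1 = 8, R2 = 5),
                         default_flux_upper = 10)
  st <- solve_pathologic(net, cfg)
  grid <- seq(0, 8, by = 0.01)
  oracle <- vapply(grid, function(t) if (t <= 5) t else -Inf, 0)
  expect_equal(st$objective, max(oracle), tolerance = 1e-8)
  expect_state_feasible(net, cfg, st)

  # independent branches: box feasible region, separable optimum
  net2 <- branch_network()
  cfg2 <- scenario_config(c(B = 2, D = 1),
                          flux_upper = c(R1 = 3, R2 = 4),
                          default_flux_upper = 10)
  st2 <- solve_pathologic(net2, cfg2)
  pts <- expand.grid(v1 = seq(0, 3, 0.05), v2 = seq(0, 4, 0.05))
  oracle2 <- max(2 * pts$v1 + pts$v2)
  expect_equal(st2$objective, oracle2, tolerance = 1e-8)
  # sampled feasible points never beat the LP optimum
  expect_true(all(2 * pts$v1 + pts$v2 <= st2$objective + 1e-6))
})

test_that("mass-flow caps bind and zero weights give a zero objective", {
  net <- single_reaction_network()
  cfg <- scenario_config(c(B = 1), default_flux_upper = 100,
                         massflow_upper = c(B = 4))
  st <- solve_pathologic(net, cfg)
  expect_equal(st$objective, 4)
  expect_state_feasible(net, cfg, st)
})

test_that("raising a flux cap never lowers the optimum; scaling scales it", {
  toy <- toy_network()
  base <- solve_pathologic(toy$network, toy$config)$objective
  for (rid in c("R1", "R5", "R7")) {
    up <- scenario_config(toy$config$objective_weights,
                          flux_upper = setNames(25, rid),
                          default_flux_upper = 10)
    expect_gte(solve_pathologic(toy$network, up)$objective, base - 1e-9)
  }
  for (lam in c(0.5, 2, 3.25)) {
    scaled <- scenario_config(toy$config$objective_weights,
                              default_flux_upper = 10 * lam)
    expect_equal(solve_pathologic(toy$network, scaled)$objective,
                 lam * base, tolerance = 1e-7)
  }
})

test_that("unbounded and infeasible statuses are reported", {
  net <- single_reaction_network()
  cfg <- scenario_config(c(B = 1))  # default cap Inf
  st <- solve_pathologic(net, cfg)
  expect_equal(st$solver_status, "unbounded")
  expect_true(all(is.na(st$v)))

  cfg2 <- scenario_config(c(B = 1), default_flux_upper = 5)
  st2 <- solve_pathologic(net, cfg2, fixed_fluxes = c(R1 = 9))
  expect_equal(st2$solver_status, "infeasible")
})

test_that("every optimal state passes the independent feasibility audit", {
  for (seed in 1:5) {
    net <- generate_network(generator_params(n_metabolites = 10,
                                             n_reactions = 7, seed = seed))
    sc <- plant_disease_scenario(net)
    expect_state_feasible(net, sc$config, sc$state)
  }
})
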