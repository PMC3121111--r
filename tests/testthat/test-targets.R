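v0_toy <- c(R1 = 10, R2 = 3.75, R3 = 10, R4 = 5, R5 = 5, R6 = 10,
            R7 = 1.25, R8 = 10)
v1_toy <- c(R1 = 10, R2 = 1, R3 = 0, R4 = 0, R5 = 5, R6 = 6.33,
            R7 = 0.33, R8 = 0)

test_that("changed_reactions compares elementwise with a strict tolerance", {
  expect_equal(changed_reactions(v0_toy, v1_toy),
               c("R2", "R3", "R4", "R6", "R7", "R8"))
  expect_length(changed_reactions(v0_toy, v0_toy), 0)
  # a difference of exactly tol is not "changed"
  v <- c(R1 = 1); w <- c(R1 = 1 + 1e-6)
  expect_length(changed_reactions(v, w, tol = 1e-6), 0)
  expect_equal(changed_reactions(v, w, tol = 0.9e-6), "R1")
  expect_error(changed_reactions(c(1, 2), c(1, 2, 3)), "length")
})

test_that("the changed-reaction subnetwork keeps reactants and products", {
  toy <- toy_network()
  sub <- build_subnetwork(toy$network, c("R2", "R3", "R4", "R6", "R7", "R8"))
  expect_setequal(sub$reaction_ids, c("R2", "R3", "R4", "R6", "R7", "R8"))
  expect_setequal(sub$metabolite_ids,
                  c("C2", "C3", "C4", "C6", "C7", "C8", "C10", "C11", "C12"))
  expect_equal(sub$S["C3", "R2"], 4)   # stoichiometry preserved
  expect_error(build_subnetwork(toy$network, "R99"), "unknown")
  empty <- build_subnetwork(toy$network, character())
  expect_length(empty$reactions, 0)
})

test_that("single-pass pruning removes exactly the unproduced compounds", {
  toy <- toy_network()
  sub <- build_subnetwork(toy$network, c("R2", "R3", "R4", "R6", "R7", "R8"))
  pr <- prune_zero_indegree(sub)
  expect_setequal(pr$metabolite_ids,
                  c("C6", "C7", "C8", "C10", "C11", "C12"))
  empty_reactants <- vapply(pr$reactions,
                            function(r) length(r$reactants) == 0L, TRUE)
  expect_setequal(pr$reaction_ids[empty_reactants], c("R2", "R3", "R4"))
  expect_length(pr$reactions, 6)   # reactions are never deleted
  # a fully produced subnetwork is untouched
  expect_setequal(prune_zero_indegree(pr)$metabolite_ids,
                  pr$metabolite_ids)
  # chain head: only the unproduced A goes
  ch <- prune_zero_indegree(chain_network())
  expect_setequal(ch$metabolite_ids, c("B", "C"))
  # pruning never removes a product of a changed reaction
  produced <- unique(unlist(lapply(sub$reactions,
                                   function(r) names(r$products))))
  expect_true(all(produced %in% pr$metabolite_ids))
})

test_that("the toy pipeline identifies R2, R3, R4 as inhibition targets", {
  toy <- toy_network()
  p <- solve_pathologic(toy$network, toy$config)
  m <- solve_medication(toy$network, toy$config, toy$scenario1)
  rep <- identify_targets(p, m, toy$network)
  expect_equal(rep$targets$reaction, c("R2", "R3", "R4"))
  expect_equal(rep$targets$required_flux, c(1, 0, 0), tolerance = 1e-6)
  expect_equal(rep$targets$mode, rep("inhibition", 3))
  expect_equal(rep$targets$enzymes, c("E2", "E3", "E4"))
  expect_true(all(rep$targets$reaction %in% rep$changed$reaction))
  expect_equal(rep$side_effect, 11 / 3, tolerance = 1e-6)
})

test_that("identical states produce an empty report", {
  toy <- toy_network()
  p <- solve_pathologic(toy$network, toy$config)
  fake_med <- structure(list(state = p, dev_above = numeric(),
                             dev_below = numeric(), side_effect = 0),
                        class = "medication_solution")
  rep <- identify_targets(p, fake_med, toy$network)
  expect_equal(nrow(rep$changed), 0)
  expect_equal(nrow(rep$targets), 0)
  expect_length(rep$subnetwork$reactions, 0)
})

test_that("target sets are invariant to reaction input ordering", {
  toy <- toy_network()
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  net2 <- build_network(toy$network$metabolite_ids,
                        toy$network$reactions[perm])
  p <- solve_pathologic(net2, toy$config)
  m <- solve_medication(net2, toy$config, toy$scenario1)
  rep <- identify_targets(p, m, net2)
  expect_setequal(rep$targets$reaction, c("R2", "R3", "R4"))
  expect_equal(rep$side_effect, 11 / 3, tolerance = 1e-6)
})

test_that("verify_targets reproduces the medication state from the targets", {
  toy <- toy_network()
  res <- fba_drug_targets(toy$network, toy$config, toy$scenario1)
  ver <- res$verification
  expect_true(ver$feasible)
  expect_true(ver$disease_in_range)
  expect_equal(ver$side_effect, res$medication$side_effect,
               tolerance = 1e-6)
  # fixing nothing reproduces the pathologic state
  ver0 <- verify_targets(toy$network, toy$config, toy$scenario1,
                         setNames(numeric(0), character(0)))
  expect_equal(ver0$state$v, res$pathologic$v, tolerance = 1e-8)
  # fixing a non-target at its pathologic value changes nothing
  ver1 <- verify_targets(toy$network, toy$config, toy$scenario1,
                         c(R1 = unname(res$pathologic$v[["R1"]])))
  expect_equal(ver1$state$v, res$pathologic$v, tolerance = 1e-8)
})

test_that("pipeline self-consistency holds on planted random scenarios", {
  for (seed in c(11, 23, 37)) {
    net <- generate_network(generator_params(n_metabolites = 10,
                                             n_reactions = 7, seed = seed))
    sc <- plant_disease_scenario(net)
    res <- fba_drug_targets(net, sc$config, sc$ranges)
    expect_equal(res$verification$side_effect,
                 res$medication$side_effect, tolerance = 1e-6)
    expect_true(all(res$report$targets$reaction %in%
                      res$report$changed$reaction))
  }
})
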