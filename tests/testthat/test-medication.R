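test_that("the medication LP carries deviation variables only for ranged N", {
  toy <- toy_network()
  lp <- build_medication_lp(toy$network, toy$config, toy$scenario1)
  expect_length(lp$vars, 8 + 12 + 4)   # d+/d- for C9 and C10 only
  expect_setequal(grep("^d", lp$vars, value = TRUE),
                  c("dplus_C9", "dplus_C10", "dminus_C9", "dminus_C10"))
  expect_false(lp$maximize)
  expect_error(
    build_medication_lp(toy$network, toy$config,
                        healthy_ranges(list(C9 = c(0, 1)), character())),
    "no disease-causing compound")
})

test_that("deviations take their max(0, .) closed forms at the optimum", {
  toy <- toy_network()
  med <- solve_medication(toy$network, toy$config, toy$scenario1)
  x <- med$state$x
  for (id in c("C9", "C10")) {
    ab <- toy$scenario1$ranges[[id]]
    expect_equal(med$dev_above[[id]], max(0, x[[id]] - ab[2]),
                 tolerance = 1e-9)
    expect_equal(med$dev_below[[id]], max(0, ab[1] - x[[id]]),
                 tolerance = 1e-9)
    # complementarity
    expect_lt(med$dev_above[[id]] * med$dev_below[[id]], 1e-9)
  }
  expect_equal(med$side_effect, sum(med$dev_above) + sum(med$dev_below),
               tolerance = 1e-9)
  # disease compounds sit inside their (hard) ranges
  expect_true(x[["C11"]] >= 10 - 1e-6 && x[["C11"]] <= 15 + 1e-6)
  expect_lte(x[["C12"]], 1 + 1e-6)
})

test_that("medication optimum matches a grid oracle on a tiny network", {
  # chain A -> B -> C, flux cap 10; the feasible set is x_B = x_C = t.
  # Disease: C with range [2, 4] (hard); N: B with range [6, 10].
  # side effect(t) = max(0, 6 - t) on t in [2, 4], minimized at t = 4.
  net <- chain_network()
  cfg <- scenario_config(c(C = 1), default_flux_upper = 10)
  rng <- healthy_ranges(list(C = c(2, 4), B = c(6, 10)), "C")
  med <- solve_medication(net, cfg, rng)
  grid <- seq(2, 4, by = 0.001)
  oracle <- min(pmax(0, 6 - grid))
  expect_equal(med$side_effect, oracle, tolerance = 1e-6)
  expect_equal(unname(med$state$x[["C"]]), 4, tolerance = 1e-6)
})

test_that("all-infinite ranges give zero side effect trivially", {
  net <- chain_network()
  cfg <- scenario_config(c(C = 1), default_flux_upper = 10)
  rng <- healthy_ranges(list(C = c(0, Inf), B = c(0, Inf)), "C")
  med <- solve_medication(net, cfg, rng)
  expect_equal(med$side_effect, 0)
})

test_that("a pinned disease range forces the exact attainable value", {
  net <- chain_network()
  cfg <- scenario_config(c(C = 1), default_flux_upper = 10)
  med <- solve_medication(net, cfg,
                          healthy_ranges(list(C = c(3, 3)), "C"))
  expect_equal(unname(med$state$x[["C"]]), 3, tolerance = 1e-8)
  expect_equal(unname(med$state$v), c(3, 3), tolerance = 1e-8)
})

test_that("states already in range yield zero side effect", {
  toy <- toy_network()
  p <- solve_pathologic(toy$network, toy$config)
  loose <- healthy_ranges(
    list(C11 = c(0, 100), C12 = c(0, 100), C9 = c(0, 100),
         C10 = c(0, 100)),
    disease = c("C11", "C12"))
  med <- solve_medication(toy$network, toy$config, loose)
  expect_equal(med$side_effect, 0)
})

test_that("widening a non-disease range never increases the side effect", {
  toy <- toy_network()
  base <- solve_medication(toy$network, toy$config,
                           toy$scenario1)$side_effect
  widen <- toy$scenario1
  widen$ranges$C10 <- c(5, 15)
  expect_lte(solve_medication(toy$network, toy$config, widen)$side_effect,
             base + 1e-9)
  widen$ranges$C10 <- c(0, Inf)
  expect_lte(solve_medication(toy$network, toy$config, widen)$side_effect,
             base + 1e-9)
})

test_that("infeasible disease ranges are diagnosed with the culprit named", {
  net <- chain_network()
  cfg <- scenario_config(c(C = 1), default_flux_upper = 10)
  med <- solve_medication(net, cfg,
                          healthy_ranges(list(C = c(50, 60)), "C"))
  expect_equal(med$state$solver_status, "infeasible")
  expect_true(is.na(med$side_effect))
  expect_equal(med$binding_ranges, "C")
  # widening the disease range restores feasibility
  med2 <- solve_medication(net, cfg,
                           healthy_ranges(list(C = c(0, 60)), "C"))
  expect_equal(med2$state$solver_status, "optimal")
})

test_that("side-effect weights scale the objective", {
  net <- chain_network()
  cfg <- scenario_config(c(C = 1), default_flux_upper = 10)
  rng <- healthy_ranges(list(C = c(2, 4), B = c(6, 10)), "C",
                        weights = c(B = 3))
  med <- solve_medication(net, cfg, rng)
  expect_equal(med$side_effect, 3 * 2, tolerance = 1e-6)
})

test_that("an independently built LP (pracma) agrees on the side effect", {
  # Build the scenario-1 medication LP from the raw equations with a
  # different LP layer; only the minimized side effect is compared (the
  # optimal vertex is not unique).
  toy <- toy_network()
  S <- toy$network$S; Tm <- toy$network$T
  nv <- 8; nx <- 12
  nd <- 4  # dplus/dminus for C9, C10
  vars <- nv + nx + nd
  cc <- c(rep(0, nv + nx), rep(1, nd))
  Aeq <- NULL; beq <- NULL
  roles <- classify_metabolites(toy$network)
  for (i in 1:12) {
    if (roles[[i]] %in% c("consumed_only", "intermediate")) {
      r <- numeric(vars); r[1:nv] <- S[i, ]; r[nv + i] <- -1
      Aeq <- rbind(Aeq, r); beq <- c(beq, 0)
    }
    if (roles[[i]] %in% c("produced_only", "intermediate")) {
      r <- numeric(vars); r[1:nv] <- Tm[, i]; r[nv + i] <- -1
      Aeq <- rbind(Aeq, r); beq <- c(beq, 0)
    }
  }
  A <- NULL; b <- NULL
  add_le <- function(coefs, rhs) { A <<- rbind(A, coefs); b <<- c(b, rhs) }
  xi <- function(id) nv + match(id, toy$network$metabolite_ids)
  # hard ranges C11 in [10,15], C12 <= 1
  r <- numeric(vars); r[xi("C11")] <- 1; add_le(r, 15)
  r <- numeric(vars); r[xi("C11")] <- -1; add_le(r, -10)
  r <- numeric(vars); r[xi("C12")] <- 1; add_le(r, 1)
  # soft ranges C9, C10 in [10,15]: x - d+ <= 15, -x - d- <= -10
  dp <- c(C9 = nv + nx + 1, C10 = nv + nx + 2)
  dm <- c(C9 = nv + nx + 3, C10 = nv + nx + 4)
  for (id in c("C9", "C10")) {
    r <- numeric(vars); r[xi(id)] <- 1; r[dp[[id]]] <- -1; add_le(r, 15)
    r <- numeric(vars); r[xi(id)] <- -1; r[dm[[id]]] <- -1; add_le(r, -10)
  }
  for (j in 1:nv) {            # flux caps as rows (v_j <= 10)
    r <- numeric(vars); r[j] <- 1; add_le(r, 10)
  }
  res <- pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = beq,
                         maxiter = 200, maximize = FALSE)
  med <- solve_medication(toy$network, toy$config, toy$scenario1)
  expect_equal(res$fval, med$side_effect, tolerance = 1e-6)
})

test_that("optional biomass stage keeps the side-effect optimum", {
  toy <- toy_network()
  med <- solve_medication(toy$network, toy$config, toy$scenario1,
                          maximize_biomass = TRUE)
  expect_equal(med$side_effect, 11 / 3, tolerance = 1e-6)
  expect_true(med$state$x[["C11"]] >= 10 - 1e-6)
})
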