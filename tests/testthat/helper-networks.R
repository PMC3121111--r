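# Small hand-built networks with closed-form optima, used as oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A -> B -> C chain: balance forces v1 = v2, so the whole feasible set is
# parameterized by t in [0, min(U)].
chain_network <- function() {
  build_network(c("A", "B", "C"),
                list(parse_reaction_equation("A -> B", "R1", "Ea"),
                     parse_reaction_equation("B -> C", "R2", "Eb")))
}

# Two independent branches A -> B, C -> D: no intermediates, every point of
# the flux box is feasible.
branch_network <- function() {
  build_network(c("A", "B", "C", "D"),
                list(parse_reaction_equation("A -> B", "R1"),
                     parse_reaction_equation("C -> D", "R2")))
}

single_reaction_network <- function() {
  build_network(c("A", "B"),
                list(parse_reaction_equation("A -> B", "R1")))
}

expect_state_feasible <- function(network, config, state, tol = 1e-6) {
  expect_true(check_flux_state(network, config, state, tol = tol))
}
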