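#' The 12-metabolite / 8-reaction illustrative network
#'
#' Reconstructs, in code, the small simulated network used throughout the
#' package's examples and tests, together with its biomass scenario and two
#' healthy-range scenarios:
#'
#' \preformatted{
#' R1: 2 C1 + C2 -> C5 + C6      R5: 2 C5 -> 3 C9
#' R2: 4 C3 -> 3 C6 + C7         R6: 2 C6 -> C10 + 2 C11
#' R3: 3 C2 -> C8                R7: C6 + 3 C7 -> 2 C11 + 3 C12
#' R4: C4 -> 2 C8                R8: 2 C8 -> 3 C12
#' }
#'
#' Note on R7: the published source of this example prints R7 with the
#' impossible left side "C6 + 3 C6"; that stoichiometry balances with none
#' of the published flux/mass-flow vectors. The unique correction under
#' which every published number balances exactly is `C6 + 3 C7 -> 2 C11 +
#' 3 C12` (C7 is otherwise produced by R2 but consumed nowhere), and that
#' is what this fixture uses.
#'
#' The scenario puts biomass weight 1 on C8, C9, C11, C12, caps every flux
#' at 10 and no mass flow. Scenario 1 declares C11 and C12 disease-causing
#' with healthy ranges `C9, C10, C11 in [10, 15]`, `C12 in [0, 1]`;
#' scenario 2 uses `C9, C12 in [10, 15]`, `C10 in [5, 15]`,
#' `C11 in [15, 20]`.
#'
#' @param enzymes logical; attach placeholder enzyme ids `E1`..`E8` (one
#'   per reaction) so that enzyme-level reporting has something to show.
#' @return list with `network`, `config`, `scenario1`, `scenario2`.
#' @export
toy_network <- function(enzymes = TRUE) {
  eqs <- c(R1 = "2 C1 + C2 -> C5 + C6",
           R2 = "4 C3 -> 3 C6 + C7",
           R3 = "3 C2 -> C8",
           R4 = "C4 -> 2 C8",
           R5 = "2 C5 -> 3 C9",
           R6 = "2 C6 -> C10 + 2 C11",
           R7 = "C6 + 3 C7 -> 2 C11 + 3 C12",
           R8 = "2 C8 -> 3 C12")
  rxns <- lapply(seq_along(eqs), function(j)
    parse_reaction_equation(eqs[[j]], names(eqs)[j],
                            if (enzymes) paste0("E", j) else character()))
  network <- build_network(paste0("C", 1:12), rxns)
  config <- scenario_config(
    objective_weights = c(C8 = 1, C9 = 1, C11 = 1, C12 = 1),
    default_flux_upper = 10)
  scenario1 <- healthy_ranges(
    list(C9 = c(10, 15), C10 = c(10, 15), C11 = c(10, 15), C12 = c(0, 1)),
    disease = c("C11", "C12"))
  scenario2 <- healthy_ranges(
    list(C9 = c(10, 15), C10 = c(5, 15), C11 = c(15, 20), C12 = c(10, 15)),
    disease = c("C11", "C12"))
  list(network = network, config = config,
       scenario1 = scenario1, scenario2 = scenario2)
}

#' Parameters for the random layered-network generator
#'
#' @param n_metabolites total metabolite count (>= 2 per layer on average).
#' @param n_reactions reaction count.
#' @param n_layers metabolites are partitioned into this many layers;
#'   reactions consume from one layer and produce into later layers, so the
#'   reaction dependency order is acyclic and a nonzero feasible flux always
#'   exists.
#' @param max_coefficient stoichiometric coefficients are integers drawn
#'   from `1:max_coefficient`.
#' @param flux_upper common flux cap.
#' @param seed integer; all randomness flows from it.
#' @return a `generator_params` list.
#' @export
generator_params <- function(n_metabolites = 12, n_reactions = 8,
                             n_layers = 3, max_coefficient = 3,
                             flux_upper = 10, seed = 1) {
  stopifnot(n_layers >= 2, n_metabolites >= n_layers, n_reactions >= 1,
            max_coefficient >= 1, flux_upper > 0)
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_reactions = as.integer(n_reactions),
                 n_layers = as.integer(n_layers),
                 max_coefficient = as.integer(max_coefficient),
                 flux_upper = flux_upper, seed = as.integer(seed)),
            class = "generator_params")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random feasible metabolic network
#'
#' Layered construction: metabolites `M1..Mk` are split into consecutive
#' layers; each reaction draws 1-3 reactants from one non-final layer and
#' 1-3 products from strictly later layers, with integer coefficients.
#' Layer-0 metabolites are never produced (sources) and last-layer
#' metabolites never consumed (sinks), so the bipartite digraph is acyclic
#' and a strictly positive feasible flux exists; this is verified
#' internally by solving the pathologic LP with uniform weights on all
#' sinks and requiring a positive optimum, resampling a bounded number of
#' times otherwise.
#'
#' @param params a [generator_params()].
#' @return a `metabolic_network`; the common flux cap is attached as
#'   attribute `"flux_upper"`.
#' @export
generate_network <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  for (attempt in seq_len(20L)) {
    net <- with_seed(params$seed + (attempt - 1L) * 7919L,
                     draw_layered_network(params))
    caps <- setNames(rep(params$flux_upper, length(net$reaction_ids)),
                     net$reaction_ids)
    sinks <- net$metabolite_ids[net$metabolites$role == "produced_only"]
    if (length(sinks) == 0L) next
    config <- scenario_config(
      objective_weights = setNames(rep(1, length(sinks)), sinks),
      flux_upper = caps, default_flux_upper = params$flux_upper)
    st <- solve_pathologic(net, config)
    if (st$solver_status == "optimal" && st$objective > 1e-6) {
      attr(net, "flux_upper") <- caps
      return(net)
    }
  }
  stop("could not generate a feasible network in 20 attempts; ",
       "loosen the generator parameters", call. = FALSE)
}

draw_layered_network <- function(params) {
  m <- params$n_metabolites; L <- params$n_layers
  layer <- sort(c(seq_len(L), sample(seq_len(L), m - L, replace = TRUE)))
  ids <- paste0("M", seq_len(m))
  rxns <- vector("list", params$n_reactions)
  for (j in seq_len(params$n_reactions)) {
    from <- sample(seq_len(L - 1L), 1L)
    pool_r <- ids[layer == from]
    pool_p <- ids[layer > from]
    nr <- sample(seq_len(min(3L, length(pool_r))), 1L)
    np <- sample(seq_len(min(3L, length(pool_p))), 1L)
    reactants <- setNames(sample(params$max_coefficient, nr, replace = TRUE),
                          sample(pool_r, nr))
    products <- setNames(sample(params$max_coefficient, np, replace = TRUE),
                         sample(pool_p, np))
    rxns[[j]] <- reaction(paste0("G", j), reactants, products,
                          enzymes = paste0("EG", j))
  }
  suppress_isolated_warning(build_network(ids, rxns))
}

#' Plant a disease scenario on a generated network
#'
#' Mirrors the construction of the illustrative example on a random
#' network: solve the pathologic LP with uniform weight on all sinks, pick
#' the sink with the largest pathologic mass flow as the disease-causing
#' compound, and set its healthy range strictly below that value (a
#' fraction `severity` of it), with wide ranges `[0, Inf)` elsewhere. The
#' ground-truth target superset is the set of source reactions (reactions
#' consuming only layer-0/unproduced metabolites) from which the disease
#' compound is reachable in the bipartite digraph — any correct target must
#' come from it.
#'
#' @param network a network from [generate_network()].
#' @param severity healthy upper bound as a fraction of the pathologic
#'   mass flow (default 0.5).
#' @return list with `config`, `ranges`, `ground_truth_targets`, and the
#'   pathologic `state`.
#' @export
plant_disease_scenario <- function(network, severity = 0.5) {
  caps <- attr(network, "flux_upper")
  stopifnot(!is.null(caps), severity > 0, severity < 1)
  sinks <- network$metabolite_ids[network$metabolites$role == "produced_only"]
  config <- scenario_config(
    objective_weights = setNames(rep(1, length(sinks)), sinks),
    flux_upper = caps,
    default_flux_upper = max(caps))
  st <- solve_pathologic(network, config)
  flows <- st$x[sinks]
  if (all(flows <= 1e-9)) stop("no sink with nonzero mass flow",
                               call. = FALSE)
  disease <- sinks[which.max(flows)]
  ranges <- healthy_ranges(
    setNames(list(c(0, severity * st$x[[disease]])), disease),
    disease = disease)
  list(config = config, ranges = ranges,
       ground_truth_targets = source_reactions_reaching(network, disease),
       state = st)
}

# Source reactions (all reactants unproduced in the full network) from
# which `metabolite` is reachable in the bipartite digraph.
source_reactions_reaching <- function(network, metabolite) {
  edges <- character()
  for (r in network$reactions) {
    rid <- paste0("rxn:", r$id)
    for (met in names(r$reactants))
      edges <- c(edges, paste0("met:", met), rid)
    for (met in names(r$products))
      edges <- c(edges, rid, paste0("met:", met))
  }
  g <- igraph::make_graph(edges, directed = TRUE)
  target <- paste0("met:", metabolite)
  if (!target %in% igraph::V(g)$name) return(character())
  upstream <- igraph::subcomponent(g, target, mode = "in")$name
  produced <- unique(unlist(lapply(network$reactions, function(r)
    names(r$products))))
  sources <- vapply(network$reactions, function(r)
    length(r$reactants) == 0L || all(!names(r$reactants) %in% produced),
    logical(1))
  ids <- network$reaction_ids[sources]
  ids[paste0("rxn:", ids) %in% upstream]
}
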