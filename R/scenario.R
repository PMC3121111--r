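#' Scenario configuration for the pathologic LP
#'
#' Bundles the tunables of a disease scenario: the objective weights
#' \eqn{w_i} on metabolite mass flows (weight 1 on biomass metabolites is
#' the usual choice), the per-reaction flux caps \eqn{U_j}, the optional
#' per-metabolite mass-flow caps \eqn{q_i} (infinite when omitted), and any
#' enzymes inhibited in the disease state, whose reactions are removed
#' before solving.
#'
#' @param objective_weights named numeric vector, metabolite id ->
#'   nonnegative weight; at least one must be nonzero.
#' @param flux_upper named numeric vector of per-reaction caps overriding
#'   `default_flux_upper`; values must be >= 0 (`Inf` allowed).
#' @param default_flux_upper flux cap for reactions without an override.
#' @param massflow_upper named numeric vector of metabolite mass-flow caps,
#'   strictly positive or `Inf`; metabolites without an entry are uncapped.
#' @param inhibited_enzymes character vector of enzyme ids knocked out in
#'   the disease state.
#' @param tie_break how a degenerate LP optimum is resolved into one
#'   reported vertex: `"max_total_flux"` (default) re-optimizes total flux
#'   upward at the fixed optimum, `"min_total_flux"` downward, `"none"`
#'   returns the solver's vertex as-is.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(objective_weights,
                            flux_upper = numeric(),
                            default_flux_upper = Inf,
                            massflow_upper = numeric(),
                            inhibited_enzymes = character(),
                            tie_break = c("max_total_flux", "min_total_flux",
                                          "none")) {
  tie_break <- match.arg(tie_break)
  objective_weights <- unlist(objective_weights)
  if (length(objective_weights) == 0L || is.null(names(objective_weights)))
    stop("objective_weights must be a named vector", call. = FALSE)
  if (any(objective_weights < 0))
    stop("objective weights must be nonnegative", call. = FALSE)
  if (all(objective_weights == 0))
    stop("at least one objective weight must be nonzero", call. = FALSE)
  flux_upper <- unlist(flux_upper)
  if (length(flux_upper) && (is.null(names(flux_upper)) || any(flux_upper < 0)))
    stop("flux_upper must be a named vector of nonnegative caps", call. = FALSE)
  if (!is.numeric(default_flux_upper) || length(default_flux_upper) != 1L ||
      default_flux_upper < 0)
    stop("default_flux_upper must be a single nonnegative number", call. = FALSE)
  massflow_upper <- unlist(massflow_upper)
  if (length(massflow_upper) &&
      (is.null(names(massflow_upper)) || any(massflow_upper <= 0)))
    stop("massflow_upper entries must be named and strictly positive",
         call. = FALSE)
  structure(list(objective_weights = objective_weights,
                 flux_upper = flux_upper,
                 default_flux_upper = default_flux_upper,
                 massflow_upper = massflow_upper,
                 inhibited_enzymes = as.character(inhibited_enzymes),
                 tie_break = tie_break),
            class = "scenario_config")
}

# Resolve per-reaction caps against a network's reaction order.
flux_caps <- function(network, config) {
  caps <- rep(config$default_flux_upper, length(network$reaction_ids))
  names(caps) <- network$reaction_ids
  known <- intersect(names(config$flux_upper), names(caps))
  caps[known] <- config$flux_upper[known]
  caps
}

massflow_caps <- function(network, config) {
  caps <- rep(Inf, length(network$metabolite_ids))
  names(caps) <- network$metabolite_ids
  known <- intersect(names(config$massflow_upper), names(caps))
  caps[known] <- config$massflow_upper[known]
  caps
}

#' Healthy mass-flow ranges and the disease-compound set
#'
#' Declares the clinically healthy interval \eqn{[a_i, b_i]} for each ranged
#' metabolite and names the disease-causing compounds `P`. In the medication
#' LP the ranges of `P` are hard constraints; every other ranged metabolite
#' belongs to the non-disease set `N`, whose deviations from range are summed
#' into the side effect. Metabolites with no range entry behave as
#' `[0, Inf)` and contribute nothing.
#'
#' @param ranges named list, metabolite id -> numeric `c(a, b)` with
#'   `0 <= a <= b` (`b = Inf` allowed).
#' @param disease list of disease-causing metabolite ids; each must have a
#'   range entry. Must be non-empty for [solve_medication()].
#' @param weights optional named nonnegative weights on the non-disease
#'   deviations (default 1 each); the side effect is a plain unweighted sum
#'   unless these are supplied.
#' @return An object of class `healthy_ranges` with elements `ranges`,
#'   `disease`, the derived `non_disease`, and `weights`.
#' @export
healthy_ranges <- function(ranges, disease, weights = NULL) {
  if (!is.list(ranges) || is.null(names(ranges)) || any(!nzchar(names(ranges))))
    stop("ranges must be a named list of c(lower, upper) pairs", call. = FALSE)
  for (id in names(ranges)) {
    ab <- as.numeric(ranges[[id]])
    if (length(ab) != 2L || anyNA(ab) || ab[1] < 0 || ab[1] > ab[2])
      stop("invalid healthy range for '", id,
           "': need 0 <= lower <= upper", call. = FALSE)
    ranges[[id]] <- ab
  }
  disease <- as.character(disease)
  missing_rng <- setdiff(disease, names(ranges))
  if (length(missing_rng))
    stop("disease compounds without a range entry: ",
         paste(missing_rng, collapse = ", "), call. = FALSE)
  if (!is.null(weights)) {
    weights <- unlist(weights)
    if (is.null(names(weights)) || any(weights < 0))
      stop("weights must be a named vector of nonnegative values",
           call. = FALSE)
  }
  structure(list(ranges = ranges, disease = disease,
                 non_disease = setdiff(names(ranges), disease),
                 weights = weights),
            class = "healthy_ranges")
}
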