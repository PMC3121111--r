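#' Build the medication-state linear program
#'
#' The stage-2 LP shares the mass-flow skeleton of the pathologic LP (mass
#' balance for intermediates, consumption- and production-side mass-flow
#' definitions, \eqn{0 \le v_j \le U_j}) but replaces the biomass objective.
#' Disease-causing compounds \eqn{i \in P} get their healthy range as a hard
#' constraint \eqn{a_i \le x_i \le b_i}. Every other ranged metabolite
#' \eqn{i \in N} gets goal-programming deviation variables
#' \eqn{d_i^+ \ge x_i - b_i}, \eqn{d_i^- \ge a_i - x_i} (both nonnegative),
#' and the objective minimizes the total side effect
#' \eqn{\sum_{i \in N} w_i (d_i^+ + d_i^-)}. Metabolites without a range
#' entry behave as \eqn{[0, \infty)} and contribute nothing.
#'
#' Healthy bounds are treated as closed intervals: an LP cannot represent a
#' strict inequality, so a range published as \eqn{0 \le x < 1} is modelled
#' as \eqn{[0, 1]}.
#'
#' @param network a finalized `metabolic_network`.
#' @param config a [scenario_config()] (supplies the flux caps; the
#'   pathologic mass-flow caps `q_i` do not apply in this stage).
#' @param ranges a [healthy_ranges()] with a non-empty disease set.
#' @return a `linear_program` with variables `v_`, `x_`, `dplus_`, `dminus_`.
#' @export
build_medication_lp <- function(network, config, ranges) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(config, "scenario_config"),
            inherits(ranges, "healthy_ranges"))
  if (length(ranges$disease) == 0L)
    stop("no disease-causing compound specified", call. = FALSE)
  unknown <- setdiff(names(ranges$ranges), network$metabolite_ids)
  if (length(unknown))
    stop("healthy ranges name unknown metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  lp <- new_massflow_lp(network,
                        x_upper = rep(Inf, length(network$metabolite_ids)),
                        flux_upper = flux_caps(network, config))
  ndis <- intersect(network$metabolite_ids, ranges$non_disease)
  dplus <- paste0("dplus_", ndis, recycle0 = TRUE)
  dminus <- paste0("dminus_", ndis, recycle0 = TRUE)
  # extend variable space with the deviation variables
  lp$vars <- c(lp$vars, dplus, dminus)
  lp$upper <- c(lp$upper, setNames(rep(Inf, 2L * length(ndis)),
                                   c(dplus, dminus)))
  lp$A <- cbind(lp$A, matrix(0, nrow(lp$A), 2L * length(ndis),
                             dimnames = list(NULL, c(dplus, dminus))))
  w <- ranges$weights %||% setNames(rep(1, length(ndis)), ndis)
  obj <- setNames(numeric(length(lp$vars)), lp$vars)
  for (id in ndis) {
    wi <- if (id %in% names(w)) w[[id]] else 1
    obj[paste0(c("dplus_", "dminus_"), id)] <- wi
  }
  lp$objective <- obj
  lp$maximize <- FALSE
  for (id in intersect(network$metabolite_ids, ranges$disease)) {
    ab <- ranges$ranges[[id]]
    if (ab[1] > 0)
      lp <- lp_add_row(lp, setNames(1, paste0("x_", id)), ">=", ab[1],
                       paste0("disease_lower_", id))
    if (is.finite(ab[2]))
      lp <- lp_add_row(lp, setNames(1, paste0("x_", id)), "<=", ab[2],
                       paste0("disease_upper_", id))
  }
  for (id in ndis) {
    ab <- ranges$ranges[[id]]
    if (is.finite(ab[2]))                       # x - d+ <= b
      lp <- lp_add_row(lp, setNames(c(1, -1), paste0(c("x_", "dplus_"), id)),
                       "<=", ab[2], paste0("soft_upper_", id))
    if (ab[1] > 0)                              # x + d- >= a
      lp <- lp_add_row(lp, setNames(c(1, 1), paste0(c("x_", "dminus_"), id)),
                       ">=", ab[1], paste0("soft_lower_", id))
  }
  lp
}

#' Solve the medication-state LP
#'
#' Minimizes the total side effect while holding every disease-causing
#' compound inside its healthy range. At the optimum the deviations take
#' their closed forms \eqn{d_i^+ = \max(0, x_i - b_i)},
#' \eqn{d_i^- = \max(0, a_i - x_i)}, to which they are clipped post-solve;
#' a degenerate optimum is resolved by the scenario tie-break exactly as in
#' [solve_pathologic()].
#'
#' @param network a `metabolic_network`.
#' @param config a [scenario_config()].
#' @param ranges a [healthy_ranges()].
#' @param maximize_biomass logical; if `TRUE`, an extra lexicographic stage
#'   re-maximizes the pathologic biomass objective at the fixed side-effect
#'   optimum before the flux tie-break (a multi-objective extension, off by
#'   default).
#' @return A `medication_solution`: `state` (a `flux_state` with v1/x1),
#'   `dev_above`, `dev_below` (named over the non-disease ranged set), and
#'   `side_effect`.
#' @examples
#' toy <- toy_network()
#' med <- solve_medication(toy$network, toy$config, toy$scenario1)
#' med$side_effect
#' @export
solve_medication <- function(network, config, ranges,
                             maximize_biomass = FALSE) {
  net <- apply_disease_knockouts(network, config)
  lp <- build_medication_lp(net, config, ranges)
  if (isTRUE(maximize_biomass)) {
    first <- solve_lp(lp)
    if (first$status == "optimal") {
      lp <- lp_add_row(lp, lp$objective[lp$objective != 0], "==",
                       first$value, "fixed_side_effect")
      obj <- setNames(numeric(length(lp$vars)), lp$vars)
      for (id in intersect(names(config$objective_weights),
                           net$metabolite_ids))
        obj[paste0("x_", id)] <- config$objective_weights[[id]]
      lp$objective <- obj; lp$maximize <- TRUE
      res <- solve_lp_tiebreak(lp, paste0("v_", net$reaction_ids),
                               config$tie_break)
      res$value <- first$value
    } else res <- first
  } else {
    res <- solve_lp_tiebreak(lp, paste0("v_", net$reaction_ids),
                             config$tie_break)
  }
  if (res$status != "optimal") {
    binding <- diagnose_medication_infeasibility(net, config, ranges)
    state <- as_flux_state(res, net, network)
    return(structure(list(state = state, dev_above = NULL, dev_below = NULL,
                          side_effect = NA_real_, binding_ranges = binding),
                     class = "medication_solution"))
  }
  state <- as_flux_state(res, net, network)
  ndis <- intersect(network$metabolite_ids, ranges$non_disease)
  ab <- vapply(ranges$ranges[ndis], identity, numeric(2))
  dev_above <- setNames(pmax(0, state$x[ndis] - ab[2, ]), ndis)
  dev_below <- setNames(pmax(0, ab[1, ] - state$x[ndis]), ndis)
  structure(list(state = state, dev_above = dev_above,
                 dev_below = dev_below,
                 side_effect = unname(res$value)),
            class = "medication_solution")
}

# Best-effort naming of the P-ranges that make the medication LP
# infeasible: drop each disease range in turn and re-solve.
diagnose_medication_infeasibility <- function(net, config, ranges) {
  culprits <- character()
  for (id in ranges$disease) {
    relaxed <- ranges
    relaxed$ranges[[id]] <- c(0, Inf)
    ok <- tryCatch(
      solve_lp(build_medication_lp(net, config, relaxed))$status == "optimal",
      error = function(e) FALSE)
    if (ok) culprits <- c(culprits, id)
  }
  culprits
}

#' @export
print.medication_solution <- function(x, digits = 4, ...) {
  if (x$state$solver_status != "optimal") {
    cat("Medication state: ", x$state$solver_status, "\n", sep = "")
    if (length(x$binding_ranges))
      cat("  binding disease range(s): ",
          paste(x$binding_ranges, collapse = ", "), "\n", sep = "")
    return(invisible(x))
  }
  cat("Medication state: side effect = ",
      format(x$side_effect, digits = digits), "\n", sep = "")
  dev <- x$dev_above + x$dev_below
  off <- dev[dev > 1e-9]
  if (length(off))
    cat("  out-of-range metabolites: ",
        paste0(names(off), " (", signif(off, digits), ")", collapse = ", "),
        "\n", sep = "")
  else cat("  all non-disease metabolites within healthy ranges\n")
  invisible(x)
}

#' @export
summary.medication_solution <- function(object, ...) {
  print(object, ...)
  if (object$state$solver_status == "optimal") print(object$state, ...)
  invisible(object)
}
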