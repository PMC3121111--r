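#' Remove reactions disabled by inhibited enzymes
#'
#' In the disease state, reactions whose catalyzing enzyme is inhibited
#' cannot take place. This drops every reaction whose enzyme list intersects
#' `config$inhibited_enzymes` and rebuilds the stoichiometric matrices and
#' metabolite roles on the remaining reactions. Metabolites are kept even if
#' they become isolated.
#'
#' @param network a `metabolic_network`.
#' @param config a [scenario_config()].
#' @return a `metabolic_network` with the affected reactions removed.
#' @export
apply_disease_knockouts <- function(network, config) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(config, "scenario_config"))
  inhibited <- config$inhibited_enzymes
  if (length(inhibited) == 0L) return(network)
  all_enz <- unique(unlist(lapply(network$reactions, `[[`, "enzymes")))
  unmatched <- setdiff(inhibited, all_enz)
  if (length(unmatched))
    warning("inhibited enzymes matching no reaction: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  hit <- vapply(network$reactions,
                function(r) length(intersect(r$enzymes, inhibited)) > 0L,
                logical(1))
  restrict_network(network, network$reaction_ids[!hit])
}

#' Build the pathologic-state linear program
#'
#' The stage-1 LP maximizes the weighted sum of metabolite mass flows,
#' \eqn{\max \sum_i w_i x_i}, over fluxes \eqn{0 \le v_j \le U_j} and mass
#' flows \eqn{0 \le x_i \le q_i}, subject to the mass-flow definitions: for
#' every metabolite that is consumed (consumed_only or intermediate),
#' \eqn{x_i = \sum_j s_{i,j} v_j}; for every metabolite that is produced
#' (produced_only or intermediate), \eqn{x_i = \sum_j t_{j,i} v_j}. For
#' intermediates both equalities hold, which already enforces steady-state
#' mass balance; an explicit redundant balance row is emitted as well to
#' sharpen infeasibility diagnostics. Isolated metabolites are pinned to
#' \eqn{x_i = 0}.
#'
#' @param network a finalized `metabolic_network` (reversibles split).
#' @param config a [scenario_config()]. Knockouts are *not* applied here;
#'   see [apply_disease_knockouts()] / [solve_pathologic()].
#' @return a `linear_program` with variables `v_<reaction>` and
#'   `x_<metabolite>`.
#' @export
build_pathologic_lp <- function(network, config) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(config, "scenario_config"))
  w <- config$objective_weights
  lp <- new_massflow_lp(network,
                        x_upper = massflow_caps(network, config),
                        flux_upper = flux_caps(network, config))
  obj <- setNames(numeric(length(lp$vars)), lp$vars)
  for (id in intersect(names(w), network$metabolite_ids))
    obj[paste0("x_", id)] <- w[[id]]
  lp$objective <- obj
  lp$maximize <- TRUE
  lp
}

# Shared skeleton of both LPs: variables v_/x_ with bounds, the mass-flow
# definition equalities, redundant balance rows, and x = 0 for isolated
# metabolites.
new_massflow_lp <- function(network, x_upper, flux_upper) {
  v_vars <- paste0("v_", network$reaction_ids)
  x_vars <- paste0("x_", network$metabolite_ids)
  lp <- new_lp(c(v_vars, x_vars),
               objective = numeric(length(v_vars) + length(x_vars)),
               maximize = FALSE,
               upper = c(unname(flux_upper), unname(x_upper)))
  roles <- classify_metabolites(network)
  for (i in seq_along(network$metabolite_ids)) {
    id <- network$metabolite_ids[[i]]
    xv <- paste0("x_", id)
    # explicit names: single-column matrices drop dimnames on [i, ]
    srow <- setNames(as.numeric(network$S[i, ]), colnames(network$S))
    trow <- setNames(as.numeric(network$T[, i]), rownames(network$T))
    if (roles[[id]] %in% c("consumed_only", "intermediate"))
      lp <- lp_add_row(lp, c(setNames(srow[srow != 0],
                                      paste0("v_", names(srow[srow != 0]))),
                             setNames(-1, xv)),
                       "==", 0, paste0("consumption_", id))
    if (roles[[id]] %in% c("produced_only", "intermediate"))
      lp <- lp_add_row(lp, c(setNames(trow[trow != 0],
                                      paste0("v_", names(trow[trow != 0]))),
                             setNames(-1, xv)),
                       "==", 0, paste0("production_", id))
    if (roles[[id]] == "intermediate") {
      net <- setNames(as.numeric(network$Snet[i, ]),
                      colnames(network$Snet))
      lp <- lp_add_row(lp, setNames(net[net != 0],
                                    paste0("v_", names(net[net != 0]))),
                       "==", 0, paste0("balance_", id), redundant = TRUE)
    }
    if (roles[[id]] == "isolated")
      lp <- lp_add_row(lp, setNames(1, xv), "==", 0, paste0("isolated_", id))
  }
  lp
}

#' Solve the pathologic-state LP
#'
#' Applies disease knockouts, builds the stage-1 LP and solves it. When the
#' optimum is degenerate the reported vertex is fixed by the scenario's
#' tie-break (default: re-maximize total flux at the fixed optimum), so
#' results are run-to-run reproducible.
#'
#' @param network a `metabolic_network`.
#' @param config a [scenario_config()].
#' @param fixed_fluxes optional named numeric vector pinning reactions to an
#'   exact flux value (used by [verify_targets()] to emulate drug action on
#'   the target enzymes).
#' @return A `flux_state`: named flux vector `v`, named mass-flow vector
#'   `x`, `objective`, and `solver_status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`).
#' @examples
#' toy <- toy_network()
#' st <- solve_pathologic(toy$network, toy$config)
#' st$v
#' @export
solve_pathologic <- function(network, config, fixed_fluxes = NULL) {
  net <- apply_disease_knockouts(network, config)
  lp <- build_pathologic_lp(net, config)
  if (length(fixed_fluxes)) {
    unknown <- setdiff(names(fixed_fluxes), net$reaction_ids)
    if (length(unknown))
      stop("fixed_fluxes name unknown reactions: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (id in names(fixed_fluxes))
      lp <- lp_add_row(lp, setNames(1, paste0("v_", id)), "==",
                       fixed_fluxes[[id]], paste0("fixed_", id))
  }
  res <- solve_lp_tiebreak(lp, paste0("v_", net$reaction_ids),
                           config$tie_break)
  as_flux_state(res, net, network)
}

# Map an LP result onto the *original* network's ordering; knocked-out
# reactions report flux 0, metabolites of removed reactions keep their
# recomputed mass flow.
as_flux_state <- function(res, solved_network, network) {
  v <- setNames(numeric(length(network$reaction_ids)), network$reaction_ids)
  x <- setNames(numeric(length(network$metabolite_ids)),
                network$metabolite_ids)
  if (res$status == "optimal") {
    sol <- res$solution
    v[solved_network$reaction_ids] <-
      sol[paste0("v_", solved_network$reaction_ids, recycle0 = TRUE)]
    x[solved_network$metabolite_ids] <-
      sol[paste0("x_", solved_network$metabolite_ids, recycle0 = TRUE)]
  } else {
    v[] <- NA_real_; x[] <- NA_real_
  }
  structure(list(v = v, x = x, objective = res$value,
                 solver_status = res$status,
                 message = res$message %||% NULL),
            class = "flux_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.flux_state <- function(x, digits = 4, ...) {
  cat("Flux state (", x$solver_status, ")", sep = "")
  if (!is.na(x$objective)) cat(", objective = ", format(x$objective, digits = digits), sep = "")
  cat("\n")
  if (x$solver_status == "optimal") {
    cat("  v:", paste0(names(x$v), "=", signif(x$v, digits), collapse = " "), "\n")
    cat("  x:", paste0(names(x$x), "=", signif(x$x, digits), collapse = " "), "\n")
  }
  invisible(x)
}

#' Independently audit a solved flux state
#'
#' Re-evaluates, from the reaction maps rather than the LP object, the flux
#' and mass-flow bounds, steady-state balance of every intermediate, and the
#' consumption-side and production-side mass-flow identities. Used
#' throughout the test-suite as the feasibility oracle.
#'
#' @param network the network the state was solved on.
#' @param config the scenario (for bounds).
#' @param state a `flux_state`.
#' @param tol absolute tolerance.
#' @return invisibly `TRUE`; aborts with the violated condition otherwise.
#' @export
check_flux_state <- function(network, config, state, tol = 1e-6) {
  stopifnot(state$solver_status == "optimal")
  net <- apply_disease_knockouts(network, config)
  v <- state$v[net$reaction_ids]; x <- state$x[net$metabolite_ids]
  caps_v <- flux_caps(net, config); caps_x <- massflow_caps(net, config)
  if (any(v < -tol) || any(v - caps_v > tol))
    stop("flux bound violated", call. = FALSE)
  if (any(x < -tol) || any(x - caps_x > tol))
    stop("mass-flow bound violated", call. = FALSE)
  prod_minus_cons <- net_production(net, v)
  roles <- classify_metabolites(net)
  for (id in net$metabolite_ids) {
    consumption <- sum(vapply(net$reactions, function(r)
      if (id %in% names(r$reactants)) r$reactants[[id]] * v[[r$id]] else 0,
      numeric(1)))
    production <- consumption + prod_minus_cons[[id]]
    role <- roles[[id]]
    if (role == "intermediate" && abs(prod_minus_cons[[id]]) > tol)
      stop("mass balance violated at ", id, call. = FALSE)
    if (role %in% c("consumed_only", "intermediate") &&
        abs(x[[id]] - consumption) > tol)
      stop("consumption mass-flow identity violated at ", id, call. = FALSE)
    if (role %in% c("produced_only", "intermediate") &&
        abs(x[[id]] - production) > tol)
      stop("production mass-flow identity violated at ", id, call. = FALSE)
    if (role == "isolated" && abs(x[[id]]) > tol)
      stop("isolated metabolite ", id, " has nonzero mass flow", call. = FALSE)
  }
  invisible(TRUE)
}
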