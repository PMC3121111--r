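#' Reactions whose flux differs between two states
#'
#' @param v0,v1 named flux vectors over the same reactions in the same
#'   order (pathologic and medication states).
#' @param tol absolute tolerance; a reaction is "changed" iff
#'   `|v1 - v0| > tol` (strict).
#' @param relative if `TRUE`, compare `|v1 - v0| / max(1, |v0|)` instead.
#' @return character vector of changed reaction ids, input order preserved.
#' @export
changed_reactions <- function(v0, v1, tol = 1e-6, relative = FALSE) {
  if (length(v0) != length(v1))
    stop("flux vectors differ in length", call. = FALSE)
  if (!is.null(names(v0)) && !is.null(names(v1)) &&
      !identical(names(v0), names(v1)))
    stop("flux vectors are over different reaction orderings", call. = FALSE)
  stopifnot(tol > 0)
  d <- abs(v1 - v0)
  if (relative) d <- d / pmax(1, abs(v0))
  names(v0)[d > tol]
}

#' Subnetwork of changed reactions
#'
#' Restricts a network to the given reactions plus the union of their
#' reactants and products, preserving stoichiometry and input order.
#'
#' @param network a `metabolic_network`.
#' @param changed character vector of reaction ids.
#' @return a `metabolic_network`.
#' @export
build_subnetwork <- function(network, changed) {
  unknown <- setdiff(changed, network$reaction_ids)
  if (length(unknown))
    stop("unknown reaction ids: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rxns <- network$reactions[network$reaction_ids %in% changed]
  mets <- unique(unlist(lapply(rxns, function(r)
    c(names(r$reactants), names(r$products)))))
  restrict_network(network, changed,
                   metabolite_ids = intersect(network$metabolite_ids, mets))
}

#' Delete compounds that nothing in the subnetwork produces
#'
#' One pass: every metabolite that is a product of no subnetwork reaction
#' (zero in-degree in the bipartite digraph) is removed from the metabolite
#' list and from every reactant map. These compounds enter the process from
#' outside the system, so the reactions left with an empty reactant map are
#' the flux sources. Reactions are never removed. With
#' `iterative = TRUE` the deletion is repeated to a fixed point (removal of
#' a compound can never create a newly unproduced one in a single network,
#' so this matters only after external edits); the single pass is the
#' default.
#'
#' @param subnetwork a `metabolic_network`.
#' @param iterative repeat the pass to a fixed point.
#' @return a `metabolic_network` with unproduced metabolites stripped.
#' @export
prune_zero_indegree <- function(subnetwork, iterative = FALSE) {
  repeat {
    produced <- unique(unlist(lapply(subnetwork$reactions, function(r)
      names(r$products))))
    drop <- setdiff(subnetwork$metabolite_ids, produced)
    if (length(drop) == 0L) return(subnetwork)
    rxns <- lapply(subnetwork$reactions, function(r) {
      r$reactants <- r$reactants[setdiff(names(r$reactants), drop)]
      r
    })
    keep <- setdiff(subnetwork$metabolite_ids, drop)
    subnetwork <- suppress_isolated_warning(
      build_network(keep, rxns,
                    subnetwork$metabolites$name[
                      subnetwork$metabolite_ids %in% keep]))
    if (!iterative) return(subnetwork)
  }
}

suppress_isolated_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("isolated", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Identify drug targets from the two solved states
#'
#' Composes the comparison pipeline: find the reactions whose flux the
#' medication changed, build their subnetwork with all reactants and
#' products, prune compounds the subnetwork does not produce, and report as
#' targets the reactions left without reactants — the sources through which
#' the flux adjustment enters the system. Each target carries its enzymes,
#' the required medication flux \eqn{v^1_j}, and the flux change
#' \eqn{\Delta v_j = v^1_j - v^0_j} as a dose proxy, labelled `inhibition`
#' (\eqn{\Delta v < 0}) or `activation` (\eqn{\Delta v > 0}). Enzymes of a
#' target that also catalyze unchanged reactions are flagged as potential
#' off-target effects (an engineering aid beyond the core procedure).
#'
#' @param pathologic a `flux_state` from [solve_pathologic()].
#' @param medication a `medication_solution` from [solve_medication()].
#' @param network the `metabolic_network` both were solved on.
#' @param tol,relative changed-reaction tolerance, see [changed_reactions()].
#' @param iterative_prune see [prune_zero_indegree()].
#' @return A `target_report`: data.frame `changed` (reaction, v0, v1, dv),
#'   `subnetwork` (pruned), data.frame `targets` (reaction, enzymes,
#'   required_flux, dv, mode, shared_enzymes), and `side_effect`.
#' @examples
#' toy <- toy_network()
#' p <- solve_pathologic(toy$network, toy$config)
#' m <- solve_medication(toy$network, toy$config, toy$scenario1)
#' identify_targets(p, m, toy$network)$targets
#' @export
identify_targets <- function(pathologic, medication, network,
                             tol = 1e-6, relative = FALSE,
                             iterative_prune = FALSE) {
  stopifnot(inherits(pathologic, "flux_state"),
            inherits(medication, "medication_solution"),
            inherits(network, "metabolic_network"))
  v0 <- pathologic$v; v1 <- medication$state$v
  ch <- changed_reactions(v0, v1, tol = tol, relative = relative)
  changed <- data.frame(reaction = ch,
                        v0 = unname(v0[ch]), v1 = unname(v1[ch]),
                        dv = unname(v1[ch] - v0[ch]),
                        stringsAsFactors = FALSE)
  sub <- prune_zero_indegree(build_subnetwork(network, ch),
                             iterative = iterative_prune)
  src <- vapply(sub$reactions, function(r) length(r$reactants) == 0L,
                logical(1))
  tids <- sub$reaction_ids[src]
  enzymes_of <- function(id)
    network$reactions[[match(id, network$reaction_ids)]]$enzymes
  unchanged <- setdiff(network$reaction_ids, ch)
  shared <- vapply(tids, function(id) {
    enz <- enzymes_of(id)
    other <- unique(unlist(lapply(network$reactions[
      network$reaction_ids %in% unchanged], `[[`, "enzymes")))
    paste(intersect(enz, other), collapse = ",")
  }, character(1))
  targets <- data.frame(
    reaction = tids,
    enzymes = vapply(tids, function(id) paste(enzymes_of(id), collapse = ","),
                     character(1)),
    required_flux = unname(v1[tids]),
    dv = unname(v1[tids] - v0[tids]),
    mode = ifelse(v1[tids] - v0[tids] < 0, "inhibition", "activation"),
    shared_enzymes = unname(shared),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(changed = changed, subnetwork = sub, targets = targets,
                 side_effect = medication$side_effect),
            class = "target_report")
}

#' @export
print.target_report <- function(x, digits = 4, ...) {
  cat("Drug-target report\n")
  cat("  side effect: ", format(x$side_effect, digits = digits), "\n", sep = "")
  cat("  changed reactions (", nrow(x$changed), "): ",
      paste(x$changed$reaction, collapse = ", "), "\n", sep = "")
  if (nrow(x$targets) == 0L) {
    cat("  no targets (states identical)\n")
  } else {
    cat("  targets:\n")
    for (i in seq_len(nrow(x$targets)))
      cat(sprintf("    %s  required flux %.4g  (dv %+.4g, %s)%s\n",
                  x$targets$reaction[i], x$targets$required_flux[i],
                  x$targets$dv[i], x$targets$mode[i],
                  if (nzchar(x$targets$enzymes[i]))
                    paste0("  enzymes: ", x$targets$enzymes[i]) else ""))
  }
  invisible(x)
}

#' Verify a target set by re-solving with fixed fluxes
#'
#' Independent confirmation of a target report: re-solves the
#' \emph{pathologic} LP with each target reaction's flux pinned at its
#' required medication value (emulating drug action on exactly those
#' enzymes) and evaluates the resulting mass flows against the healthy
#' ranges. If the targets are sufficient, the implied side effect matches
#' [solve_medication()]'s optimum and every disease range is met.
#'
#' @param network a `metabolic_network`.
#' @param config a [scenario_config()].
#' @param ranges a [healthy_ranges()].
#' @param targets a `target_report`, or a named numeric vector of required
#'   fluxes per reaction.
#' @return list with the re-solved `state`, `side_effect`, logical
#'   `disease_in_range`, and `feasible`.
#' @export
verify_targets <- function(network, config, ranges, targets) {
  fixed <- if (inherits(targets, "target_report"))
    setNames(targets$targets$required_flux, targets$targets$reaction)
  else targets
  state <- solve_pathologic(network, config, fixed_fluxes = fixed)
  if (state$solver_status != "optimal")
    return(list(state = state, side_effect = NA_real_,
                disease_in_range = FALSE, feasible = FALSE))
  se <- 0; in_range <- TRUE
  for (id in names(ranges$ranges)) {
    if (!id %in% network$metabolite_ids) next
    ab <- ranges$ranges[[id]]
    gap <- max(0, state$x[[id]] - ab[2], ab[1] - state$x[[id]])
    if (id %in% ranges$disease) {
      if (gap > 1e-6) in_range <- FALSE
    } else {
      w <- if (!is.null(ranges$weights) && id %in% names(ranges$weights))
        ranges$weights[[id]] else 1
      se <- se + w * gap
    }
  }
  list(state = state, side_effect = se, disease_in_range = in_range,
       feasible = TRUE)
}
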