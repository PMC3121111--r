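#' Build a metabolic network from reactions
#'
#' Assembles the bipartite reaction-metabolite model: the m x n reactant
#' coefficient matrix `S`, the n x m product coefficient matrix `T`, the
#' combined stoichiometric matrix `Snet = -S + t(T)` whose null-space
#' constraint `Snet %*% v = 0` is the classic FBA steady state, and a role
#' for every metabolite (see [classify_metabolites()]). Metabolite and
#' reaction order follow the input, so matrix columns and report rows are
#' reproducible.
#'
#' @param metabolite_ids character vector of metabolite ids, in display
#'   order. Must cover every id referenced by `reactions`; may include extra
#'   (isolated) metabolites, which are kept with a warning.
#' @param reactions list of irreversible `fba_reaction` objects (apply
#'   [split_reversible()] first; a reversible reaction here is an error).
#' @param metabolite_names optional character vector of free-text names,
#'   parallel to `metabolite_ids`.
#' @return An object of class `metabolic_network`: list with `metabolites`
#'   (data.frame `id`, `name`, `role`), `reactions`, matrices `S`, `T`,
#'   `Snet`, and convenience vectors `metabolite_ids`, `reaction_ids`.
#' @examples
#' rxns <- list(parse_reaction_equation("A -> B", "R1"),
#'              parse_reaction_equation("B -> C", "R2"))
#' net <- build_network(c("A", "B", "C"), rxns)
#' net$Snet
#' @export
build_network <- function(metabolite_ids, reactions,
                          metabolite_names = metabolite_ids) {
  metabolite_ids <- as.character(metabolite_ids)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]),
               collapse = ", "), call. = FALSE)
  if (any(!nzchar(metabolite_ids))) stop("empty metabolite id", call. = FALSE)
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  if (any(vapply(reactions, function(r) isTRUE(r$reversible), logical(1))))
    stop("network contains reversible reactions; apply split_reversible() first",
         call. = FALSE)
  referenced <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  unknown <- setdiff(referenced, metabolite_ids)
  if (length(unknown))
    stop("reactions reference unknown metabolite ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  m <- length(metabolite_ids); n <- length(reactions)
  S <- matrix(0, m, n, dimnames = list(metabolite_ids, rids))
  Tm <- matrix(0, n, m, dimnames = list(rids, metabolite_ids))
  for (j in seq_len(n)) {
    r <- reactions[[j]]
    S[names(r$reactants), j] <- r$reactants
    Tm[j, names(r$products)] <- r$products
  }
  role <- classify_roles(S, Tm)
  if (any(role == "isolated"))
    warning("isolated metabolites (in no reaction): ",
            paste(metabolite_ids[role == "isolated"], collapse = ", "),
            call. = FALSE)
  structure(list(
    metabolites = data.frame(id = metabolite_ids,
                             name = as.character(metabolite_names),
                             role = role, stringsAsFactors = FALSE),
    reactions = reactions,
    S = S, T = Tm, Snet = -S + t(Tm),
    metabolite_ids = metabolite_ids, reaction_ids = rids),
    class = "metabolic_network")
}

classify_roles <- function(S, Tm) {
  consumed <- rowSums(S) > 0
  produced <- colSums(Tm) > 0
  ifelse(consumed & produced, "intermediate",
         ifelse(consumed, "consumed_only",
                ifelse(produced, "produced_only", "isolated")))
}

#' Classify metabolites by topological role
#'
#' A metabolite is `consumed_only` if it is a reactant of at least one
#' reaction and a product of none (it enters the system from outside),
#' `produced_only` in the mirror case (it leaves the system),
#' `intermediate` if both — these are exactly the metabolites subject to the
#' strict mass-balance constraint in the two LPs — and `isolated` if neither.
#'
#' @param network a `metabolic_network`.
#' @return named character vector, metabolite id -> role.
#' @export
classify_metabolites <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  setNames(network$metabolites$role, network$metabolites$id)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network: ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions\n", sep = "")
  tab <- table(factor(x$metabolites$role,
                      c("consumed_only", "intermediate", "produced_only",
                        "isolated")))
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  for (r in head(x$reactions, 10L)) cat("  ", r$id, ": ",
                                        format_reaction(r), "\n", sep = "")
  if (length(x$reactions) > 10L)
    cat("  ... and", length(x$reactions) - 10L, "more\n")
  invisible(x)
}

# Rebuild a network from a subset of its reactions (and optionally a subset
# of metabolites); used by knockouts and target identification.
restrict_network <- function(network, reaction_ids,
                             metabolite_ids = NULL, warn_isolated = FALSE) {
  keep <- network$reaction_ids %in% reaction_ids
  rxns <- network$reactions[keep]
  if (is.null(metabolite_ids)) metabolite_ids <- network$metabolite_ids
  met_keep <- network$metabolite_ids %in% metabolite_ids
  withCallingHandlers(
    build_network(network$metabolite_ids[met_keep], rxns,
                  network$metabolites$name[met_keep]),
    warning = function(w) {
      if (!warn_isolated && grepl("isolated", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Production minus consumption per metabolite for a flux vector, computed
# from the reaction maps (not the matrices) - independent checker route.
net_production <- function(network, v) {
  out <- setNames(numeric(nrow(network$metabolites)), network$metabolite_ids)
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    if (length(r$products))
      out[names(r$products)] <- out[names(r$products)] + r$products * v[[j]]
    if (length(r$reactants))
      out[names(r$reactants)] <- out[names(r$reactants)] - r$reactants * v[[j]]
  }
  out
}
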