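#' Run the whole two-stage pipeline
#'
#' Solves the pathologic LP, the medication LP, identifies targets, and
#' (optionally) verifies them by re-solving with the target fluxes fixed.
#'
#' @param network a `metabolic_network`.
#' @param config a [scenario_config()].
#' @param ranges a [healthy_ranges()].
#' @param tol changed-reaction tolerance.
#' @param verify also run [verify_targets()].
#' @param iterative_prune see [prune_zero_indegree()].
#' @return An `fba_pipeline` list: `pathologic`, `medication`, `report`,
#'   and (if requested) `verification`.
#' @examples
#' toy <- toy_network()
#' res <- fba_drug_targets(toy$network, toy$config, toy$scenario1)
#' res$report
#' @export
fba_drug_targets <- function(network, config, ranges, tol = 1e-6,
                             verify = TRUE, iterative_prune = FALSE) {
  pathologic <- solve_pathologic(network, config)
  if (pathologic$solver_status != "optimal")
    stop("pathologic LP not optimal: ", pathologic$solver_status,
         call. = FALSE)
  medication <- solve_medication(network, config, ranges)
  if (medication$state$solver_status != "optimal")
    stop("medication LP not optimal: ", medication$state$solver_status,
         if (length(medication$binding_ranges))
           paste0(" (binding disease range: ",
                  paste(medication$binding_ranges, collapse = ", "), ")")
         else "", call. = FALSE)
  report <- identify_targets(pathologic, medication, network, tol = tol,
                             iterative_prune = iterative_prune)
  out <- list(pathologic = pathologic, medication = medication,
              report = report)
  if (isTRUE(verify))
    out$verification <- verify_targets(network, config, ranges, report)
  structure(out, class = "fba_pipeline")
}

#' @export
print.fba_pipeline <- function(x, ...) {
  cat("Two-stage FBA drug-target analysis\n")
  cat("pathologic objective: ", format(x$pathologic$objective), "\n",
      sep = "")
  print(x$report, ...)
  if (!is.null(x$verification))
    cat("  verification: side effect ",
        format(x$verification$side_effect),
        if (x$verification$disease_in_range)
          ", disease ranges met\n" else ", DISEASE RANGE VIOLATED\n",
        sep = "")
  invisible(x)
}
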