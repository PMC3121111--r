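# TSV network files and YAML/JSON scenario files.
#
# Network TSV columns: reaction_id, equation, enzymes (comma-separated, may
# be empty), flux_upper (number or "inf"). Lines starting with '#' are
# comments. An optional metabolites sidecar TSV (metabolite_id, name) fixes
# metabolite order and display names; otherwise metabolites are inferred
# from the equations in order of first appearance.

#' Read a metabolic network from a TSV file
#'
#' @param path network TSV (see Details in [write_network()]).
#' @param metabolites_path optional sidecar TSV `metabolite_id<TAB>name`.
#' @return a finalized `metabolic_network` (reversible reactions split); the
#'   per-reaction flux caps from the `flux_upper` column are attached as
#'   attribute `"flux_upper"` (named vector) for [read_scenario()] to pick
#'   up.
#' @export
read_network <- function(path, metabolites_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("reaction_id", "equation", "enzymes", "flux_upper")
  if (!all(required %in% names(tab)))
    stop("network file must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$reaction_id)) {
    dup <- which(duplicated(tab$reaction_id))[1L]
    stop("duplicate reaction_id '", tab$reaction_id[dup], "' at data row ",
         dup, call. = FALSE)
  }
  rxns <- vector("list", nrow(tab))
  caps <- numeric(0)
  for (i in seq_len(nrow(tab))) {
    enz <- trimws(strsplit(tab$enzymes[i], ",", fixed = TRUE)[[1L]])
    enz <- enz[nzchar(enz)]
    r <- tryCatch(
      parse_reaction_equation(tab$equation[i], tab$reaction_id[i], enz),
      error = function(e) stop("row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    rxns[[i]] <- r
    u <- tolower(trimws(tab$flux_upper[i]))
    uval <- if (u %in% c("inf", "+inf", "infinity", "")) Inf
            else suppressWarnings(as.numeric(u))
    if (is.na(uval) || uval < 0)
      stop("row ", i, ": invalid flux_upper ", sQuote(tab$flux_upper[i]),
           call. = FALSE)
    if (isTRUE(r$reversible))
      caps[paste0(r$id, c("_fwd", "_bwd"))] <- uval
    else caps[r$id] <- uval
  }
  rxns <- split_reversible(rxns)
  if (!is.null(metabolites_path)) {
    side <- read.delim(metabolites_path, comment.char = "#",
                       stringsAsFactors = FALSE, colClasses = "character")
    met_ids <- side$metabolite_id; met_names <- side$name
  } else {
    met_ids <- unique(unlist(lapply(rxns, function(r)
      c(names(r$reactants), names(r$products)))))
    met_names <- met_ids
  }
  net <- build_network(met_ids, rxns, met_names)
  attr(net, "flux_upper") <- caps
  net
}

#' Write a metabolic network to TSV
#'
#' Inverse of [read_network()] (modulo comments); fluxes print with 6
#' significant digits and `inf` for infinity.
#'
#' @param network a `metabolic_network`.
#' @param path output file.
#' @param flux_upper named per-reaction caps (default: the attribute left
#'   by [read_network()], else `inf`).
#' @return invisibly `path`.
#' @export
write_network <- function(network, path,
                          flux_upper = attr(network, "flux_upper")) {
  rows <- vapply(network$reactions, function(r) {
    u <- if (!is.null(flux_upper) && r$id %in% names(flux_upper))
      flux_upper[[r$id]] else Inf
    paste(r$id, format_reaction(r), paste(r$enzymes, collapse = ","),
          fmt_num(u), sep = "\t")
  }, character(1))
  writeLines(c("reaction_id\tequation\tenzymes\tflux_upper", rows), path)
  invisible(path)
}

fmt_num <- function(x) ifelse(is.finite(x), signif(x, 6), "inf")

#' Merge a network file's per-reaction flux caps into a scenario
#'
#' [read_network()] attaches the `flux_upper` column as an attribute; this
#' copies those caps into the scenario config for reactions the scenario
#' does not itself override.
#'
#' @param config a [scenario_config()].
#' @param network a network read with [read_network()].
#' @return the updated `scenario_config`.
#' @export
merge_network_caps <- function(config, network) {
  caps <- attr(network, "flux_upper")
  if (is.null(caps)) return(config)
  add <- setdiff(names(caps), names(config$flux_upper))
  config$flux_upper <- c(config$flux_upper, caps[add])
  config
}

#' Read a scenario (config + healthy ranges) from YAML or JSON
#'
#' Recognized keys: `objective_weights` (map), `default_flux_upper`,
#' `flux_upper` (map of overrides), `massflow_upper` (map),
#' `inhibited_enzymes` (list), `healthy_ranges` (map id -> `[a, b]`, `inf`
#' allowed), `disease_compounds` (list), `side_effect_weights` (map),
#' `tie_break`, `tol`. Unknown keys are rejected.
#'
#' @param path YAML (or JSON) scenario file.
#' @return list with `config` ([scenario_config()]), `ranges`
#'   ([healthy_ranges()] or `NULL` if no ranges given), and `tol`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  known <- c("objective_weights", "default_flux_upper", "flux_upper",
             "massflow_upper", "inhibited_enzymes", "healthy_ranges",
             "disease_compounds", "side_effect_weights", "tie_break", "tol")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         "; known keys are: ", paste(known, collapse = ", "), call. = FALSE)
  as_inf <- function(x) {
    x <- unlist(x)
    num <- suppressWarnings(as.numeric(ifelse(
      tolower(as.character(x)) %in% c("inf", "+inf", ".inf", "infinity"),
      "Inf", as.character(x))))
    setNames(num, names(x))
  }
  config <- scenario_config(
    objective_weights = as_inf(raw$objective_weights),
    flux_upper = if (!is.null(raw$flux_upper)) as_inf(raw$flux_upper)
                 else numeric(),
    default_flux_upper = if (!is.null(raw$default_flux_upper))
      as_inf(list(u = raw$default_flux_upper))[["u"]] else Inf,
    massflow_upper = if (!is.null(raw$massflow_upper))
      as_inf(raw$massflow_upper) else numeric(),
    inhibited_enzymes = unlist(raw$inhibited_enzymes) %||% character(),
    tie_break = raw$tie_break %||% "max_total_flux")
  ranges <- NULL
  if (!is.null(raw$healthy_ranges)) {
    rng <- lapply(raw$healthy_ranges, function(ab) unname(as_inf(ab)))
    ranges <- healthy_ranges(
      rng, unlist(raw$disease_compounds) %||% character(),
      weights = if (!is.null(raw$side_effect_weights))
        as_inf(raw$side_effect_weights))
  }
  list(config = config, ranges = ranges, tol = raw$tol %||% 1e-6)
}

#' Write a pipeline report to TSV or JSON
#'
#' Deterministic, column-ordered dump of a solved pipeline: one block per
#' reaction (v0, v1, dv, changed/target flags), one per metabolite (x0, x1,
#' healthy range, deviation), and a summary with the side effect. The JSON
#' and TSV forms carry the same content; numbers print with 6 significant
#' digits and `inf` for infinity.
#'
#' @param result an `fba_pipeline` from [fba_drug_targets()].
#' @param network the network it was run on.
#' @param ranges the [healthy_ranges()] used.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly `path`.
#' @export
write_report <- function(result, network, ranges, path,
                         format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "fba_pipeline"))
  v0 <- result$pathologic$v; v1 <- result$medication$state$v
  x0 <- result$pathologic$x; x1 <- result$medication$state$x
  rx <- data.frame(reaction = network$reaction_ids,
                   v0 = unname(v0), v1 = unname(v1),
                   dv = unname(v1 - v0),
                   changed = network$reaction_ids %in%
                     result$report$changed$reaction,
                   target = network$reaction_ids %in%
                     result$report$targets$reaction,
                   stringsAsFactors = FALSE)
  rng_of <- function(id) if (id %in% names(ranges$ranges))
    ranges$ranges[[id]] else c(0, Inf)
  dev_of <- function(id) {
    ab <- rng_of(id); max(0, x1[[id]] - ab[2], ab[1] - x1[[id]])
  }
  mt <- data.frame(metabolite = network$metabolite_ids,
                   x0 = unname(x0), x1 = unname(x1),
                   healthy_lower = vapply(network$metabolite_ids,
                                          function(i) rng_of(i)[1], 0),
                   healthy_upper = vapply(network$metabolite_ids,
                                          function(i) rng_of(i)[2], 0),
                   deviation = vapply(network$metabolite_ids, dev_of, 0),
                   disease = network$metabolite_ids %in% ranges$disease,
                   stringsAsFactors = FALSE)
  if (format == "json") {
    jsonlite::write_json(
      list(side_effect = result$medication$side_effect,
           reactions = rx, metabolites = mt,
           targets = result$report$targets),
      path, digits = 6, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# side_effect\t%s",
                     fmt_num(result$medication$side_effect)), con)
  num_cols <- function(df) {
    for (cl in names(df))
      if (is.numeric(df[[cl]])) df[[cl]] <- fmt_num(df[[cl]])
    df
  }
  writeLines("# reactions", con)
  suppressWarnings(write.table(num_cols(rx), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  writeLines("# metabolites", con)
  suppressWarnings(write.table(num_cols(mt), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  writeLines("# targets", con)
  suppressWarnings(write.table(num_cols(result$report$targets), con,
                               sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}
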