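#' Parse a reaction-equation string
#'
#' Parses text of the form `"2 C1 + 3 C2 -> C5 + 2 C6"` into a reaction
#' object. Each side is a `+`-separated list of terms, a term being an
#' optional positive coefficient (default 1) followed by a metabolite id.
#' `->` (or the arrow glyph) separates reactants from products; `<->` (or the
#' double-headed glyph) marks the reaction reversible. Either side may be
#' empty, denoting an exchange/boundary reaction. Duplicate metabolites on
#' one side have their coefficients summed.
#'
#' @param equation character scalar, the reaction equation.
#' @param id character scalar, reaction identifier.
#' @param enzymes character vector of catalyzing-enzyme ids (may be empty).
#' @return An object of class `fba_reaction`: a list with elements `id`,
#'   `reactants` and `products` (named numeric vectors of strictly positive
#'   stoichiometric coefficients), `enzymes`, and logical `reversible`.
#' @examples
#' parse_reaction_equation("2 C1 + 3 C2 -> C5 + 2 C6", "Rk")
#' parse_reaction_equation("A <-> B", "R1")
#' @export
parse_reaction_equation <- function(equation, id, enzymes = character()) {
  stopifnot(is.character(equation), length(equation) == 1L,
            is.character(id), length(id) == 1L, nzchar(id))
  eq <- gsub("↔", "<->", equation, fixed = TRUE)
  eq <- gsub("→", "->", eq, fixed = TRUE)
  reversible <- grepl("<->", eq, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1L]]
  n_arrows <- lengths(regmatches(eq, gregexpr(arrow, eq, fixed = TRUE)))
  if (n_arrows != 1L)
    stop("reaction '", id, "': equation must contain exactly one '", arrow,
         "' arrow: ", sQuote(equation), call. = FALSE)
  if (length(sides) == 1L) sides <- c(sides, "")
  reaction(id,
           reactants = parse_side(sides[[1L]], id),
           products  = parse_side(sides[[2L]], id),
           enzymes   = enzymes,
           reversible = reversible)
}

# One side of an equation -> named coefficient vector (duplicates summed).
parse_side <- function(text, id) {
  text <- trimws(text)
  if (!nzchar(text)) return(setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1L]])
  coefs <- numeric(0)
  for (term in terms) {
    if (!nzchar(term))
      stop("reaction '", id, "': empty term (stray '+') in ",
           sQuote(text), call. = FALSE)
    m <- regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", term)
    parts <- regmatches(term, m)[[1L]]
    if (length(parts) == 0L)
      stop("reaction '", id, "': malformed term ", sQuote(term), call. = FALSE)
    coef <- if (nzchar(parts[[2L]])) as.numeric(parts[[2L]]) else 1
    met <- parts[[3L]]
    if (grepl("^[0-9.]+$", met))
      stop("reaction '", id, "': term ", sQuote(term),
           " has a coefficient but no metabolite id", call. = FALSE)
    if (!is.finite(coef) || coef <= 0)
      stop("reaction '", id, "': metabolite '", met,
           "' has non-positive coefficient ", coef, call. = FALSE)
    coefs[met] <- if (met %in% names(coefs)) coefs[[met]] + coef else coef
  }
  coefs
}

#' Construct a reaction object directly
#'
#' @param id reaction identifier.
#' @param reactants,products named numeric vectors mapping metabolite ids to
#'   strictly positive stoichiometric coefficients; either may be empty
#'   (exchange reactions), not both.
#' @param enzymes character vector of enzyme ids.
#' @param reversible logical; reversible reactions are split by
#'   [split_reversible()] before a network is built.
#' @return An `fba_reaction` object.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     enzymes = character(), reversible = FALSE) {
  reactants <- validate_coefs(reactants, id, "reactant")
  products <- validate_coefs(products, id, "product")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", id, "': both sides empty", call. = FALSE)
  structure(list(id = as.character(id),
                 reactants = reactants, products = products,
                 enzymes = as.character(enzymes),
                 reversible = isTRUE(reversible)),
            class = "fba_reaction")
}

validate_coefs <- function(x, id, side) {
  x <- unlist(x)
  if (length(x) == 0L) return(setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("reaction '", id, "': unnamed ", side, " coefficient", call. = FALSE)
  if (any(!is.finite(x) | x <= 0))
    stop("reaction '", id, "': ", side, " coefficients must be positive and ",
         "finite", call. = FALSE)
  x
}

#' Format a reaction back to equation text
#'
#' Inverse of [parse_reaction_equation()]: unit coefficients are omitted,
#' reversible reactions print `<->`.
#'
#' @param reaction an `fba_reaction` object.
#' @return character scalar equation.
#' @export
format_reaction <- function(reaction) {
  side <- function(coefs) {
    if (length(coefs) == 0L) return("")
    paste(ifelse(coefs == 1, names(coefs),
                 paste(format(coefs, trim = TRUE), names(coefs))),
          collapse = " + ")
  }
  arrow <- if (isTRUE(reaction$reversible)) "<->" else "->"
  trimws(paste(side(reaction$reactants), arrow, side(reaction$products)))
}

#' @export
print.fba_reaction <- function(x, ...) {
  cat(x$id, ": ", format_reaction(x), sep = "")
  if (length(x$enzymes)) cat("  [", paste(x$enzymes, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Split reversible reactions into forward/backward pairs
#'
#' Every reversible reaction `X` is replaced by two irreversible reactions
#' `X_fwd` (same orientation) and `X_bwd` (sides swapped), both inheriting
#' `X`'s enzymes, with `X_bwd` immediately following `X_fwd`. Irreversible
#' reactions pass through unchanged, so the operation is idempotent.
#'
#' @param reactions list of `fba_reaction` objects.
#' @return list of irreversible `fba_reaction` objects, input order preserved.
#' @export
split_reversible <- function(reactions) {
  out <- list()
  for (r in reactions) {
    if (isTRUE(r$reversible)) {
      fwd <- r; fwd$id <- paste0(r$id, "_fwd"); fwd$reversible <- FALSE
      bwd <- r; bwd$id <- paste0(r$id, "_bwd"); bwd$reversible <- FALSE
      bwd$reactants <- r$products; bwd$products <- r$reactants
      out <- c(out, list(fwd, bwd))
    } else {
      out <- c(out, list(r))
    }
  }
  out
}
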