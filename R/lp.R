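# Solver-agnostic LP description and the simplex driver.
#
# All decision variables are nonnegative; finite upper bounds are carried
# per-variable and lowered to inequality rows at solve time. Constraint
# directions are "<=", ">=", "==". The engine is the deterministic
# two-phase simplex in simplex.R.

new_lp <- function(vars, objective, maximize, upper = rep(Inf, length(vars))) {
  structure(list(vars = vars,
                 objective = setNames(objective, vars),
                 maximize = isTRUE(maximize),
                 upper = setNames(upper, vars),
                 A = matrix(0, 0, length(vars), dimnames = list(NULL, vars)),
                 dir = character(), rhs = numeric(),
                 row_labels = character(), redundant = logical()),
            class = "linear_program")
}

# coefs: named numeric over (a subset of) lp$vars
# redundant rows document implied constraints (clearer infeasibility
# diagnostics); they are implied by the others and are dropped before the
# simplex engine, which does not pivot on linearly dependent equality rows.
lp_add_row <- function(lp, coefs, dir, rhs, label = "", redundant = FALSE) {
  row <- setNames(numeric(length(lp$vars)), lp$vars)
  row[names(coefs)] <- coefs
  lp$A <- rbind(lp$A, row, deparse.level = 0)
  lp$dir <- c(lp$dir, dir)
  lp$rhs <- c(lp$rhs, rhs)
  lp$row_labels <- c(lp$row_labels, label)
  lp$redundant <- c(lp$redundant, isTRUE(redundant))
  lp
}

#' @export
print.linear_program <- function(x, ...) {
  cat("Linear program: ", length(x$vars), " variables, ", nrow(x$A),
      " constraints, ", if (x$maximize) "maximize" else "minimize", "\n",
      sep = "")
  invisible(x)
}

# Returns list(status, solution (named), value). status in
# {"optimal", "infeasible", "unbounded"}.
solve_lp <- function(lp, eps = 1e-9) {
  nv <- length(lp$vars)
  keep <- !lp$redundant
  A <- lp$A[keep, , drop = FALSE]
  dir <- lp$dir[keep]; rhs <- lp$rhs[keep]
  finite_ub <- which(is.finite(lp$upper))
  if (length(finite_ub)) {
    Ub <- matrix(0, length(finite_ub), nv)
    Ub[cbind(seq_along(finite_ub), finite_ub)] <- 1
    A <- rbind(A, Ub)
    dir <- c(dir, rep("<=", length(finite_ub)))
    rhs <- c(rhs, lp$upper[finite_ub])
  }
  res <- simplex_solve(unname(lp$objective), A, dir, rhs,
                       maximize = lp$maximize, tol = eps)
  if (res$status != "optimal")
    return(list(status = res$status, solution = NULL, value = NA_real_,
                message = res$message %||% NULL))
  list(status = "optimal",
       solution = setNames(res$x, lp$vars),
       value = res$value)
}

# Solve, then (for a degenerate optimum) re-optimize total flux over the
# optimal face so the reported vertex is reproducible. flux_vars names the
# subset of variables whose sum is the secondary objective.
solve_lp_tiebreak <- function(lp, flux_vars,
                              tie_break = "max_total_flux", eps = 1e-9) {
  first <- solve_lp(lp, eps)
  if (first$status != "optimal" || identical(tie_break, "none") ||
      length(flux_vars) == 0L)
    return(first)
  lp2 <- lp_add_row(lp, lp$objective[lp$objective != 0], "==", first$value,
                    "fixed_primary_objective")
  lp2$objective <- setNames(as.numeric(lp$vars %in% flux_vars), lp$vars)
  lp2$maximize <- identical(tie_break, "max_total_flux")
  second <- solve_lp(lp2, eps)
  if (second$status != "optimal") return(first)  # keep any vertex we have
  list(status = "optimal", solution = second$solution, value = first$value)
}
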