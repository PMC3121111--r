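# Dense two-phase simplex with Bland's rule.
#
# The LPs solved here are small (tens of variables), so a dense tableau is
# adequate, and Bland's smallest-index pivoting makes the method both
# cycle-free and fully deterministic: re-running a degenerate problem
# always returns the same vertex, which the lexicographic tie-break in
# solve_lp_tiebreak() relies on.
#
# Standard form solved: min c'x  s.t.  A x (<=,>=,==) b, x >= 0.
# Rows are sign-normalized to b >= 0; <= rows get a slack, >= rows a
# surplus plus an artificial, == rows an artificial. Phase 1 minimizes the
# artificial sum (> tol at optimum means infeasible); phase 2 minimizes c
# with artificial columns barred from entering.

simplex_solve <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9,
                          max_iter = 100000L) {
  n <- length(obj)
  m <- length(rhs)
  c0 <- if (maximize) -as.numeric(obj) else as.numeric(obj)
  if (m == 0L) {                       # box-free: optimum at x = 0 or unbounded
    if (any(c0 < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(n), value = 0))
  }
  A <- unname(as.matrix(A)); b <- as.numeric(rhs); dir <- as.character(dir)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- chartr("<>", "><", dir[neg])
  }
  n_slack <- sum(dir == "<=") + sum(dir == ">=")
  n_art <- sum(dir == ">=") + sum(dir == "==")
  Tb <- cbind(A, matrix(0, m, n_slack + n_art), b)
  basis <- integer(m)
  s_col <- n; a_col <- n + n_slack
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      s_col <- s_col + 1L; Tb[i, s_col] <- 1; basis[i] <- s_col
    } else if (dir[i] == ">=") {
      s_col <- s_col + 1L; Tb[i, s_col] <- -1
      a_col <- a_col + 1L; Tb[i, a_col] <- 1; basis[i] <- a_col
      art_cols <- c(art_cols, a_col)
    } else {
      a_col <- a_col + 1L; Tb[i, a_col] <- 1; basis[i] <- a_col
      art_cols <- c(art_cols, a_col)
    }
  }
  ncols <- n + n_slack + n_art
  rhs_col <- ncols + 1L

  pivot <- function(Tb, r, c) {
    Tb[r, ] <- Tb[r, ] / Tb[r, c]
    for (i in seq_len(nrow(Tb)))
      if (i != r && abs(Tb[i, c]) > 0)
        Tb[i, ] <- Tb[i, ] - Tb[i, c] * Tb[r, ]
    Tb
  }
  # Bland: entering = lowest-index column with reduced cost < -tol;
  # leaving = min ratio, ties broken by lowest basis index.
  run_phase <- function(Tb, basis, cost, allowed) {
    for (it in seq_len(max_iter)) {
      cb <- cost[basis]
      red <- cost - as.numeric(crossprod(cb, Tb[, seq_len(ncols),
                                               drop = FALSE]))
      enter <- 0L
      for (j in which(allowed)) {
        if (red[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L)
        return(list(Tb = Tb, basis = basis, status = "optimal"))
      col <- Tb[, enter]
      ratios <- ifelse(col > tol, Tb[, rhs_col] / col, Inf)
      if (all(is.infinite(ratios)))
        return(list(Tb = Tb, basis = basis, status = "unbounded"))
      rmin <- min(ratios)
      cand <- which(ratios <= rmin + tol & is.finite(ratios))
      leave <- cand[which.min(basis[cand])]
      basis[leave] <- enter
      Tb <- pivot(Tb, leave, enter)
    }
    list(Tb = Tb, basis = basis, status = "maxiter")
  }

  allowed <- rep(TRUE, ncols)
  if (n_art > 0L) {
    cost1 <- numeric(ncols); cost1[art_cols] <- 1
    ph1 <- run_phase(Tb, basis, cost1, allowed)
    if (ph1$status != "optimal") return(list(status = "infeasible"))
    Tb <- ph1$Tb; basis <- ph1$basis
    if (sum(Tb[, rhs_col][basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible"))
    # drive leftover (degenerate) artificials out of the basis if possible
    for (i in which(basis %in% art_cols)) {
      cand <- which(abs(Tb[i, seq_len(n + n_slack)]) > tol)
      if (length(cand)) {
        Tb <- pivot(Tb, i, cand[1L]); basis[i] <- cand[1L]
      }
    }
    allowed[art_cols] <- FALSE
  }
  cost2 <- numeric(ncols); cost2[seq_len(n)] <- c0
  ph2 <- run_phase(Tb, basis, cost2, allowed)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status == "maxiter")
    return(list(status = "infeasible",
                message = "iteration limit reached"))
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(ncols)
  x[basis] <- Tb[, rhs_col]
  value <- sum(c0 * x[seq_len(n)])
  list(status = "optimal", x = x[seq_len(n)],
       value = if (maximize) -value else value)
}
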