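#' Solve a box- and equality-constrained convex quadratic program
#'
#' Minimizes `0.5 * v' diag(qdiag) v - lin' v` subject to `Eq v = rhs` and
#' `lb <= v <= ub`, via the dual active-set method of Goldfarb and Idnani
#' (through \pkg{quadprog}). Because that method requires a positive-definite
#' Hessian, zero diagonal entries are lifted to a small ridge; callers should
#' recompute reported objective values from the returned point with the exact
#' (unridged) objective.
#'
#' Variables whose bounds pin them to a single value are eliminated before the
#' solve, and linearly dependent equality rows are dropped by a pivoted QR of
#' the constraint matrix; the full residual is checked afterwards so that an
#' inconsistent system is still reported as infeasible.
#'
#' @param qdiag Non-negative diagonal of the quadratic term.
#' @param lin Linear term (note the minus sign in the objective above).
#' @param Eq Equality-constraint matrix (may be `NULL` for none).
#' @param rhs Equality right-hand side (defaults to zeros).
#' @param lb,ub Elementwise variable bounds.
#' @param ridge Ridge added to zero Hessian entries.
#' @param feas_tol Feasibility tolerance used for the post-hoc residual check.
#' @return A list with elements `v` (the solution, `NULL` when infeasible) and
#'   `status` (`"optimal"` or `"infeasible"`).
#' @keywords internal
qp_box_solve <- function(qdiag, lin, Eq = NULL, rhs = NULL, lb, ub,
                         ridge = 1e-8, feas_tol = 1e-7) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(qdiag) == n, length(lin) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(v = NULL, status = "infeasible"))
  }
  if (!is.null(Eq)) {
    Eq <- as.matrix(Eq)
    if (is.null(rhs)) rhs <- numeric(nrow(Eq))
  }

  ## eliminate variables fixed by their bounds
  fixed <- (ub - lb) < 1e-12
  v_full <- numeric(n)
  v_full[fixed] <- (lb[fixed] + ub[fixed]) / 2
  free <- which(!fixed)

  if (length(free) == 0L) {
    if (!is.null(Eq) && max(abs(Eq %*% v_full - rhs)) > feas_tol) {
      return(list(v = NULL, status = "infeasible"))
    }
    return(list(v = v_full, status = "optimal"))
  }

  Eq_f <- NULL
  rhs_f <- NULL
  if (!is.null(Eq) && nrow(Eq) > 0L) {
    rhs_adj <- rhs - as.numeric(Eq %*% v_full)
    Eq_f <- Eq[, free, drop = FALSE]
    ## drop linearly dependent rows (pivoted QR on the transpose)
    qrt <- qr(t(Eq_f))
    r <- qrt$rank
    keep <- if (r > 0L) sort(qrt$pivot[seq_len(r)]) else integer(0)
    Eq_f <- Eq_f[keep, , drop = FALSE]
    rhs_f <- rhs_adj[keep]
  }

  q_f <- pmax(qdiag[free], ridge)
  d_f <- lin[free] + 0  # dvec of solve.QP is the negated linear term already
  n_f <- length(free)
  Amat <- cbind(
    if (!is.null(Eq_f) && nrow(Eq_f) > 0L) t(Eq_f) else NULL,
    diag(n_f),
    -diag(n_f)
  )
  bvec <- c(rhs_f, lb[free], -ub[free])
  meq <- if (is.null(Eq_f)) 0L else nrow(Eq_f)

  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(q_f, n_f), dvec = d_f,
                       Amat = Amat, bvec = bvec, meq = meq),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    return(list(v = NULL, status = "infeasible"))
  }
  v_full[free] <- sol$solution
  ## clip round-off excursions outside the box
  v_full <- pmin(pmax(v_full, lb), ub)
  if (!is.null(Eq) && nrow(Eq) > 0L &&
      max(abs(Eq %*% v_full - rhs)) > feas_tol * max(1, max(abs(rhs)))) {
    return(list(v = NULL, status = "infeasible"))
  }
  list(v = v_full, status = "optimal")
}

#' Minimize a linear function over the steady-state flux polytope
#'
#' Solves `min c' v` subject to `S v = 0` and `lb <= v <= ub` as a ridge-
#' regularized QP. For a linear program a sufficiently small ridge yields an
#' exact optimum (the least-norm one), so the optimal value is recovered to
#' solver precision; the problems arising here (flux variability on small to
#' mid-size networks) are well inside that regime.
#'
#' @param S Stoichiometric matrix (metabolites x reactions).
#' @param c_vec Objective coefficients.
#' @param lb,ub Flux bounds.
#' @return List with `value`, `v`, `status`.
#' @keywords internal
lp_flux_solve <- function(S, c_vec, lb, ub) {
  res <- qp_box_solve(
    qdiag = numeric(length(lb)),
    lin = -c_vec,
    Eq = as.matrix(S),
    lb = lb, ub = ub,
    ridge = 1e-10
  )
  if (res$status != "optimal") {
    return(list(value = NA_real_, v = NULL, status = res$status))
  }
  list(value = sum(c_vec * res$v), v = res$v, status = "optimal")
}
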