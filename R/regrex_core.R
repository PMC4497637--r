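## The regularized flux-fitting problem:
##
##   min over v, eps, x   0.5 * ||eps||^2 + lambda * ||v||_1
##   s.t.  S_split v = 0,  0 <= v <= vmax,  -eps_max <= eps <= eps_max,
##         v_i + eps_i = d_i for data-covered irreversible reactions,
##         and for each reversible reaction a binary x_i selecting the
##         direction tied to the data (the other direction forced to zero).
##
## Split fluxes are non-negative, so the l1 norm is the plain sum. For a
## fixed binary assignment the problem is a convex QP: the error of the
## selected direction is substituted out (eps = d - v), turning the data
## constraint into a quadratic data term plus bound intersections, and the
## deselected direction's upper bound becomes 0. Only the selected
## direction's error enters the objective.

#' Build the mixed-integer quadratic flux-fitting problem
#'
#' Assembles the problem description for a split model, a per-reaction data
#' vector and a fixed regularization weight. With `x` supplied (one binary
#' per reversible reaction; 0 = forward, 1 = reverse; `NA` = undecided) the
#' direction variables are partially fixed; a fully fixed problem is a
#' convex QP.
#'
#' @param split A `split_model`.
#' @param data A `reaction_data`.
#' @param lambda Regularization weight, `>= 0`.
#' @param epsilon_max Error bound; defaults to the maximum data value, the
#'   smallest bound that keeps the all-zero flux vector feasible.
#' @param x Optional binary direction vector over the reversible reactions
#'   (in `split$rev_set` order).
#' @return An object of class `regrex_miqp` with counting fields
#'   (`n_split`, `n_binaries`, `n_error_vars`), `is_qp`, and the aligned
#'   data vector.
#' @export
build_miqp <- function(split, data, lambda, epsilon_max = NULL, x = NULL) {
  stopifnot(inherits(split, "split_model"), inherits(data, "reaction_data"))
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  model <- split$base
  unknown <- setdiff(names(data$d), model$rxn_ids)
  if (length(unknown) > 0) {
    stop("data refers to unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- stats::setNames(rep(NA_real_, n_reactions(model)), model$rxn_ids)
  d[names(data$d)] <- data$d
  if (is.null(epsilon_max)) {
    epsilon_max <- if (any(!is.na(d))) max(d, na.rm = TRUE) else 1
  }
  if (epsilon_max < 0) stop("epsilon_max must be non-negative", call. = FALSE)
  n_rev <- length(split$rev_set)
  if (is.null(x)) {
    x <- rep(NA_real_, n_rev)
  } else {
    stopifnot(length(x) == n_rev, all(x %in% c(0, 1) | is.na(x)))
  }
  has_data <- !is.na(d)
  n_err <- sum(has_data[split$irrev_set]) + 2L * sum(has_data[split$rev_set])
  structure(
    list(
      split = split,
      d = d,
      lambda = lambda,
      epsilon_max = epsilon_max,
      x = x,
      n_split = ncol(split$S_split),
      n_binaries = n_rev,
      n_free_binaries = sum(is.na(x)),
      n_error_vars = n_err,
      is_qp = !anyNA(x) || n_rev == 0L
    ),
    class = "regrex_miqp"
  )
}

#' @export
print.regrex_miqp <- function(x, ...) {
  cat("Flux-fitting MIQP: ", x$n_split, " split fluxes, ",
      x$n_binaries, " direction binaries (", x$n_free_binaries, " free), ",
      x$n_error_vars, " error variables, lambda = ", x$lambda, "\n", sep = "")
  invisible(x)
}

## Solve the convex relaxation/subproblem for a (possibly partial) binary
## assignment x (values 0/1/NA over split$rev_set). Data terms of undecided
## reversible reactions are dropped (each contributes >= 0 to the true
## objective, so the relaxed optimum is a valid lower bound) and their
## direction-exclusivity constraints are relaxed.
regrex_qp_node <- function(problem, x) {
  split <- problem$split
  d <- problem$d
  lam <- problem$lambda
  emax <- problem$epsilon_max
  n_split <- problem$n_split
  vmax <- split$vmax_split

  qdiag <- numeric(n_split)
  target <- numeric(n_split)
  lb <- numeric(n_split)
  ub <- vmax

  tie_data <- function(col, di) {
    qdiag[col] <<- 1
    target[col] <<- di
    lb[col] <<- max(0, di - emax)
    ub[col] <<- min(ub[col], di + emax)
  }

  for (k in seq_along(split$rev_set)) {
    i <- split$rev_set[k]
    fc <- split$fwd_index[i]
    rc <- split$rev_index[i]
    if (is.na(x[k])) {
      if (!is.na(d[i])) {
        # relaxed: bounds must contain both fixings' feasible sets
        ub[fc] <- min(ub[fc], d[i] + emax)
        ub[rc] <- min(ub[rc], d[i] + emax)
      }
    } else if (x[k] == 0) {
      ub[rc] <- 0
      if (!is.na(d[i])) tie_data(fc, d[i])
    } else {
      ub[fc] <- 0
      if (!is.na(d[i])) tie_data(rc, d[i])
    }
  }
  for (i in split$irrev_set) {
    if (!is.na(d[i])) tie_data(split$fwd_index[i], d[i])
  }

  lin <- qdiag * target - lam
  res <- qp_box_solve(qdiag = qdiag, lin = lin, Eq = split$S_split,
                      lb = lb, ub = ub)
  if (res$status != "optimal") return(list(status = "infeasible"))
  v <- res$v
  inc <- qdiag > 0
  bound <- 0.5 * sum((target[inc] - v[inc])^2) + lam * sum(v)
  list(status = "optimal", v = v, bound = bound)
}

## Exact objective of a fully assigned solution.
regrex_objective <- function(problem, v, x) {
  split <- problem$split
  d <- problem$d
  err2 <- 0
  for (i in which(!is.na(d))) {
    k <- match(i, split$rev_set)
    col <- if (is.na(k)) {
      split$fwd_index[i]
    } else if (x[k] == 1) {
      split$rev_index[i]
    } else {
      split$fwd_index[i]
    }
    err2 <- err2 + (d[i] - v[col])^2
  }
  unname(0.5 * err2 + problem$lambda * sum(v))
}

## Matched flux over the data set: the flux of the direction selected by x
## for reversible reactions, the (forward) flux otherwise.
matched_fluxes <- function(problem, v, x) {
  split <- problem$split
  idx <- which(!is.na(problem$d))
  out <- numeric(length(idx))
  for (t in seq_along(idx)) {
    i <- idx[t]
    k <- match(i, split$rev_set)
    col <- if (is.na(k) || is.na(x[k]) || x[k] == 0) {
      split$fwd_index[i]
    } else {
      split$rev_index[i]
    }
    out[t] <- v[col]
  }
  stats::setNames(out, split$base$rxn_ids[idx])
}

regrex_solution_from <- function(problem, v, x, objective, status) {
  split <- problem$split
  v_net <- net_flux(split, v)
  mf <- matched_fluxes(problem, v, x)
  eps <- problem$d[!is.na(problem$d)] - mf
  sol <- structure(
    list(
      lambda = problem$lambda,
      epsilon_max = problem$epsilon_max,
      v_split = v,
      v_net = v_net,
      x = stats::setNames(x, split$base$rxn_ids[split$rev_set]),
      epsilon = eps,
      matched_flux = mf,
      objective = objective,
      status = status,
      data_set = names(mf),
      correlation = NA_real_
    ),
    class = "regrex_solution"
  )
  sol$correlation <- pearson_flux_data(sol)
  sol
}

#' @export
print.regrex_solution <- function(x, ...) {
  cat("Flux fit at lambda = ", x$lambda, " [", x$status, "]\n", sep = "")
  cat("  objective: ", format(x$objective, digits = 6),
      " | active reactions (>1e-6): ", sum(abs(x$v_net) > 1e-6),
      " / ", length(x$v_net), "\n", sep = "")
  cat("  flux-data correlation: ",
      ifelse(is.na(x$correlation), "undefined", format(x$correlation, digits = 4)),
      "\n", sep = "")
  invisible(x)
}

#' Solve the flux-fitting MIQP by branch and bound
#'
#' Fits fluxes to data at a fixed regularization weight. Direction binaries
#' of reversible reactions are resolved by depth-first branch and bound: at
#' each node a convex QP relaxation is solved in which undecided reactions
#' have their data term dropped and their direction constraint relaxed (a
#' valid lower bound); nodes are pruned against the incumbent. The search is
#' deterministic (model reaction order; the child matching the relaxed
#' fluxes is explored first).
#'
#' @param split A `split_model`.
#' @param data A `reaction_data`.
#' @param lambda Regularization weight, `>= 0`.
#' @param time_limit Wall-clock budget in seconds (default 60); on expiry the
#'   best incumbent is returned with status `"time_limit_incumbent"`.
#' @param epsilon_max Error bound; default `max(d)` guarantees feasibility of
#'   the all-zero flux vector.
#' @param seed Stored for reproducibility bookkeeping; the search itself is
#'   deterministic.
#' @return A `regrex_solution`: split and net fluxes, direction binaries,
#'   per-data-reaction errors, objective, status, and the Pearson
#'   correlation between matched fluxes and data.
#' @export
solve_regrex <- function(split, data, lambda, time_limit = 60,
                         epsilon_max = NULL, seed = NULL) {
  problem <- build_miqp(split, data, lambda, epsilon_max)
  n_rev <- length(split$rev_set)
  t0 <- proc.time()[["elapsed"]]
  timed_out <- function() (proc.time()[["elapsed"]] - t0) > time_limit

  if (n_rev == 0L) {
    node <- regrex_qp_node(problem, numeric(0))
    if (node$status != "optimal") {
      stop("flux-fitting problem infeasible; epsilon_max (",
           problem$epsilon_max, ") is below the largest data value",
           call. = FALSE)
    }
    return(regrex_solution_from(problem, node$v, numeric(0),
                                regrex_objective(problem, node$v, numeric(0)),
                                "optimal"))
  }

  ## branch order: data-covered reversible reactions first (largest d first),
  ## then the rest in model order
  d_rev <- problem$d[split$rev_set]
  ord <- order(is.na(d_rev), -ifelse(is.na(d_rev), 0, d_rev),
               seq_len(n_rev))

  env <- new.env(parent = emptyenv())
  env$best_obj <- Inf
  env$best <- NULL
  env$stopped <- FALSE

  visit <- function(x) {
    if (env$stopped) return(invisible())
    if (timed_out()) {
      env$stopped <- TRUE
      return(invisible())
    }
    node <- regrex_qp_node(problem, x)
    if (node$status != "optimal") return(invisible())
    if (node$bound >= env$best_obj - 1e-9) return(invisible())
    free <- ord[is.na(x[ord])]
    if (length(free) == 0L) {
      env$best_obj <- node$bound
      env$best <- list(v = node$v, x = x)
      return(invisible())
    }
    k <- free[1]
    i <- split$rev_set[k]
    first <- if (node$v[split$rev_index[i]] > node$v[split$fwd_index[i]]) 1 else 0
    for (val in c(first, 1 - first)) {
      child <- x
      child[k] <- val
      visit(child)
    }
    invisible()
  }

  ## rounding heuristic for an initial incumbent
  root <- regrex_qp_node(problem, rep(NA_real_, n_rev))
  if (root$status == "optimal") {
    x0 <- as.numeric(root$v[split$rev_index[split$rev_set]] >
                     root$v[split$fwd_index[split$rev_set]])
    leaf <- regrex_qp_node(problem, x0)
    if (leaf$status == "optimal") {
      env$best_obj <- leaf$bound
      env$best <- list(v = leaf$v, x = x0)
    }
  }

  visit(rep(NA_real_, n_rev))

  if (is.null(env$best)) {
    if (env$stopped) {
      stop("time limit reached before any incumbent was found; ",
           "increase time_limit", call. = FALSE)
    }
    stop("flux-fitting problem infeasible; epsilon_max (",
         problem$epsilon_max, ") is below the largest data value",
         call. = FALSE)
  }
  status <- if (env$stopped) "time_limit_incumbent" else "optimal"
  regrex_solution_from(problem, env$best$v, env$best$x,
                       regrex_objective(problem, env$best$v, env$best$x),
                       status)
}

#' Exhaustive enumeration oracle for the flux-fitting MIQP
#'
#' Fixes every possible assignment of the direction binaries, solves the
#' resulting convex QP for each, and returns the global best. Intended as an
#' independent ground truth for testing [solve_regrex()] on small instances.
#'
#' @inheritParams solve_regrex
#' @param cap Refuse instances with more reversible reactions than this
#'   (default 12, i.e. at most 4096 QPs).
#' @return A `regrex_solution` with status `"optimal"`; the attribute
#'   `n_qps` records how many QPs were solved.
#' @export
enumerate_oracle <- function(split, data, lambda, epsilon_max = NULL,
                             cap = 12) {
  problem <- build_miqp(split, data, lambda, epsilon_max)
  n_rev <- length(split$rev_set)
  if (n_rev > cap) {
    stop("enumeration oracle refuses ", n_rev,
         " reversible reactions (cap ", cap, ")", call. = FALSE)
  }
  best <- NULL
  best_obj <- Inf
  n_qps <- 0L
  for (code in 0:(2^n_rev - 1)) {
    x <- as.numeric(bitwAnd(bitwShiftR(code, seq_len(n_rev) - 1L), 1L))
    node <- regrex_qp_node(problem, x)
    n_qps <- n_qps + 1L
    if (node$status != "optimal") next
    if (node$bound < best_obj) {
      best_obj <- node$bound
      best <- list(v = node$v, x = x)
    }
  }
  if (is.null(best)) {
    stop("flux-fitting problem infeasible; epsilon_max (",
         problem$epsilon_max, ") is below the largest data value",
         call. = FALSE)
  }
  sol <- regrex_solution_from(problem, best$v, best$x,
                              regrex_objective(problem, best$v, best$x),
                              "optimal")
  attr(sol, "n_qps") <- n_qps
  sol
}

#' Pearson correlation between matched fluxes and data
#'
#' Correlates the data values with the matched fluxes (the flux of the
#' direction selected by the binary for reversible data reactions, the flux
#' itself otherwise) over the data-covered set.
#'
#' @param solution A `regrex_solution`.
#' @param data Optional `reaction_data`; defaults to the data the solution
#'   was fitted to (its matched fluxes and errors are stored).
#' @return The correlation, or `NA` when either vector has zero variance
#'   (undefined).
#' @export
pearson_flux_data <- function(solution, data = NULL) {
  mf <- solution$matched_flux
  dv <- if (is.null(data)) {
    mf + solution$epsilon
  } else {
    data$d[names(mf)]
  }
  if (length(mf) < 2L) return(NA_real_)
  ## flux spread at or below the activity-threshold scale counts as zero
  ## variance: such a vector is the all-zero model up to sub-threshold noise,
  ## and correlating that noise with the data would be meaningless. Since
  ## sd > 1e-6 forces some non-negative flux above 2e-6, any lambda selected
  ## on a defined correlation yields a non-empty active set at the default
  ## activity threshold.
  if (stats::sd(mf) <= 1e-6 || stats::sd(dv) <= 1e-12) return(NA_real_)
  unname(stats::cor(mf, dv))
}
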