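## Automated selection of the regularization weight: a coarse grid (step
## 0.1, from 0 until every flux has shrunk to zero) followed by a fine grid
## (step 0.01, one coarse step either side of the best coarse lambda),
## keeping the lambda with the highest Pearson correlation between matched
## fluxes and data. Grids are generated on integer indices (tenths and
## hundredths) to avoid floating-point drift.

regrex_config <- function(config = list()) {
  defaults <- list(
    flux_cap = 1,
    time_limit = 60,
    epsilon_max = NULL,
    activity_tol = 1e-6,
    consistency_tol = 1e-6,
    lambda_max = 10,
    lambda = NULL,
    seed = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, config)
}

eval_lambda <- function(split, data, lambda, config) {
  sol <- solve_regrex(split, data, lambda,
                      time_limit = config[["time_limit"]],
                      epsilon_max = config[["epsilon_max"]],
                      seed = config[["seed"]])
  list(
    row = data.frame(
      lambda = lambda,
      correlation = sol$correlation,
      cardinality = sum(abs(sol$v_net) > config[["activity_tol"]]),
      l1_norm = sum(sol$v_split),
      objective = sol$objective,
      status = sol$status,
      stringsAsFactors = FALSE
    ),
    solution = sol
  )
}

#' Coarse lambda grid search
#'
#' Evaluates lambda = 0, 0.1, 0.2, ... and stops at the first lambda whose
#' solution is entirely shrunk to zero (every `|v_net| <=` activity
#' tolerance); that terminal lambda is included in the trace. A guard stops
#' with a warning if no all-zero solution appears by `lambda_max`
#' (default 10) — with data and fluxes bounded by 1, shrinkage must occur far
#' earlier in any non-pathological configuration.
#'
#' @param split A `split_model`.
#' @param data A `reaction_data`.
#' @param config Named list of options (`time_limit`, `epsilon_max`,
#'   `activity_tol`, `lambda_max`, `seed`); see [run_regrex()].
#' @return A list with `trace` (data frame: lambda, correlation,
#'   cardinality, l1_norm, objective, status) and `solutions` (one
#'   `regrex_solution` per evaluated lambda).
#' @export
coarse_search <- function(split, data, config = list()) {
  config <- regrex_config(config)
  rows <- list()
  sols <- list()
  k <- 0L
  repeat {
    lambda <- k / 10
    if (lambda > config[["lambda_max"]]) {
      warning("no all-zero solution up to lambda_max = ", config[["lambda_max"]],
              "; stopping the coarse search", call. = FALSE)
      break
    }
    ev <- eval_lambda(split, data, lambda, config)
    rows[[length(rows) + 1L]] <- ev$row
    sols[[length(sols) + 1L]] <- ev$solution
    if (all(abs(ev$solution$v_net) <= config[["activity_tol"]])) break
    k <- k + 1L
  }
  trace <- do.call(rbind, rows)
  names(sols) <- format_lambda(trace$lambda)
  list(trace = trace, solutions = sols)
}

format_lambda <- function(lambda) sprintf("%.2f", lambda)

#' Fine lambda grid search around a coarse center
#'
#' Evaluates lambda over `[max(0, center - 0.1), center + 0.1]` in steps of
#' 0.01, skipping values already covered by the coarse trace.
#'
#' @inheritParams coarse_search
#' @param center A lambda from the coarse trace (the correlation maximizer).
#' @param skip Lambda values already evaluated (typically the coarse grid).
#' @return Same shape as [coarse_search()].
#' @export
fine_search <- function(split, data, center, config = list(),
                        skip = numeric(0)) {
  config <- regrex_config(config)
  lo <- max(0L, as.integer(round(100 * center)) - 10L)
  hi <- as.integer(round(100 * center)) + 10L
  grid <- (lo:hi) / 100
  grid <- grid[!format_lambda(grid) %in% format_lambda(skip)]
  rows <- list()
  sols <- list()
  for (lambda in grid) {
    ev <- eval_lambda(split, data, lambda, config)
    rows[[length(rows) + 1L]] <- ev$row
    sols[[length(sols) + 1L]] <- ev$solution
  }
  trace <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(lambda = numeric(0), correlation = numeric(0),
               cardinality = integer(0), l1_norm = numeric(0),
               objective = numeric(0), status = character(0))
  names(sols) <- format_lambda(trace$lambda)
  list(trace = trace, solutions = sols)
}

#' Select the regularization weight from search traces
#'
#' Returns the lambda with the highest defined correlation; exact and
#' near-exact ties (within `1e-9`) are broken toward the larger lambda, i.e.
#' the sparser model. Undefined correlations (zero-variance fluxes, e.g. the
#' all-zero solution) never win.
#'
#' @param ... One or more results of [coarse_search()] / [fine_search()].
#' @return A list with `lambda_star`, `best_solution`, and the combined
#'   `trace`.
#' @export
select_lambda <- function(...) {
  parts <- list(...)
  trace <- do.call(rbind, lapply(parts, `[[`, "trace"))
  sols <- do.call(c, lapply(parts, `[[`, "solutions"))
  defined <- which(!is.na(trace$correlation))
  if (length(defined) == 0L) {
    stop("every evaluated lambda yielded an undefined flux-data correlation ",
         "(zero-variance fluxes); the data may be constant or all zero",
         call. = FALSE)
  }
  best_corr <- max(trace$correlation[defined])
  cand <- defined[trace$correlation[defined] >= best_corr - 1e-9]
  lambda_star <- max(trace$lambda[cand])
  list(
    lambda_star = lambda_star,
    best_solution = sols[[format_lambda(lambda_star)]],
    trace = trace[order(trace$lambda), , drop = FALSE]
  )
}

#' End-to-end context-specific model extraction
#'
#' Orchestrates the full pipeline for one context: consistency reduction of
#' the input model, cross-context max-normalization of the expression data,
#' GPR mapping to per-reaction data, reversible splitting, coarse and fine
#' lambda search (or a single fit when `lambda` is fixed in the config),
#' selection of the correlation-maximizing lambda, and extraction of the
#' active submodel with its metrics.
#'
#' @param model A `metabolic_model`.
#' @param expr An `expression_matrix` (raw values; normalization is applied
#'   internally).
#' @param context Context id to extract.
#' @param config Named list of options: `flux_cap` (split-flux upper bound,
#'   default 1), `time_limit` (seconds per MIQP, default 60), `epsilon_max`
#'   (default: largest data value), `activity_tol` (default `1e-6`),
#'   `consistency_tol` (default `1e-6`), `lambda` (fix the weight instead of
#'   searching), `lambda_max` (coarse-search guard, default 10), `seed`.
#' @return A list of class `regrex_result` with `search` (lambda_star,
#'   traces, best solution), `context_model` (a `context_model` with
#'   metrics), `data` (the `reaction_data` used), and `consistent_model`.
#' @export
run_regrex <- function(model, expr, context, config = list()) {
  config <- regrex_config(config)
  cons <- extract_consistent_model(model, config[["consistency_tol"]])
  normed <- normalize_expression(expr)
  data <- map_expression_to_reactions(cons, normed, context)
  split <- split_reversible(cons, config[["flux_cap"]])

  if (!is.null(config[["lambda"]])) {
    ev <- eval_lambda(split, data, config[["lambda"]], config)
    search <- list(lambda_star = config[["lambda"]], best_solution = ev$solution,
                   trace = ev$row)
  } else {
    coarse <- coarse_search(split, data, config)
    defined <- which(!is.na(coarse$trace$correlation))
    if (length(defined) > 0L) {
      best_corr <- max(coarse$trace$correlation[defined])
      cand <- defined[coarse$trace$correlation[defined] >= best_corr - 1e-9]
      center <- max(coarse$trace$lambda[cand])
      fine <- fine_search(split, data, center, config,
                          skip = coarse$trace$lambda)
      search <- select_lambda(coarse, fine)
    } else {
      search <- select_lambda(coarse)  # errors with a diagnostic
    }
  }

  active <- active_reactions(search$best_solution, config[["activity_tol"]])
  cm <- build_context_model(cons, active, search$best_solution$v_net,
                            context_id = context)
  cm$metrics <- model_metrics(cm, data,
                              solution = search$best_solution)
  structure(
    list(search = search, context_model = cm, data = data,
         consistent_model = cons, config = config),
    class = "regrex_result"
  )
}

#' @export
print.regrex_result <- function(x, ...) {
  cat("Context-specific extraction for '", x$context_model$context_id,
      "'\n", sep = "")
  cat("  lambda* = ", x$search$lambda_star, " (",
      nrow(x$search$trace), " lambdas evaluated)\n", sep = "")
  m <- x$context_model$metrics
  cat("  cardinality ", m$cardinality,
      " | data-orphan ratio ", format(m$data_orphan_ratio, digits = 3),
      " | correlation ", format(m$correlation, digits = 3),
      " | mean residual ", format(m$mean_residual, digits = 3), "\n", sep = "")
  invisible(x)
}
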