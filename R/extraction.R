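#' Active reactions of a solution
#'
#' Reactions whose absolute net flux exceeds the activity threshold
#' (strictly, so exact zeros are never active even at threshold 0).
#'
#' @param solution A `regrex_solution`.
#' @param threshold Activity threshold (default `1e-6`).
#' @return Character vector of active reaction ids.
#' @export
active_reactions <- function(solution, threshold = 1e-6) {
  names(solution$v_net)[abs(solution$v_net) > threshold]
}

#' Build a context-specific model from an active set
#'
#' Restricts the parent model to the active reactions, pruning metabolites
#' that no active reaction uses; bounds, GPR rules and subsystem labels are
#' inherited, and the solved net flux is attached.
#'
#' @param model The (consistent) parent `metabolic_model`.
#' @param active Character vector of active reaction ids.
#' @param flux Net flux named by reaction id (at least the active ones).
#' @param context_id Context identifier.
#' @return An object of class `context_model` with fields `context_id`,
#'   `submodel`, `active_set`, `flux` (over the active set) and `metrics`
#'   (filled by [model_metrics()]).
#' @export
build_context_model <- function(model, active, flux, context_id = "context") {
  if (length(active) == 0L) {
    stop("empty active set; no context model can be built", call. = FALSE)
  }
  sub <- subset_model(model, active)
  structure(
    list(
      context_id = context_id,
      submodel = sub,
      active_set = sub$rxn_ids,
      flux = flux[sub$rxn_ids],
      metrics = NULL
    ),
    class = "context_model"
  )
}

#' @export
print.context_model <- function(x, ...) {
  cat("Context model '", x$context_id, "': ", length(x$active_set),
      " active reactions, ", n_metabolites(x$submodel), " metabolites\n",
      sep = "")
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat("  orphan ratio ", format(m$data_orphan_ratio, digits = 3),
        " | correlation ", format(m$correlation, digits = 3),
        " | mean residual ", format(m$mean_residual, digits = 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Per-model extraction metrics
#'
#' Computes the summary metrics of an extracted model against the data it
#' was fitted to: cardinality (number of active reactions), the data-orphan
#' ratio (active reactions without associated data divided by active
#' reactions with data — `NA` when no active reaction has data), the Pearson
#' correlation between matched fluxes and data over the active data-covered
#' reactions, and the mean absolute residual between matched fluxes and data
#' over the whole data set (inactive data reactions carry their solved,
#' sub-threshold flux).
#'
#' @param cm A `context_model`.
#' @param data The `reaction_data` the model was extracted from.
#' @param solution Optional `regrex_solution` providing matched (direction-
#'   resolved) fluxes; when omitted, `|net flux|` is used, which coincides
#'   with the matched flux under direction exclusivity.
#' @return A list with `cardinality`, `data_orphan_ratio`, `correlation`,
#'   `mean_residual`.
#' @export
model_metrics <- function(cm, data, solution = NULL) {
  active <- cm$active_set
  with_data <- intersect(active, data$data_set)
  orphans <- setdiff(active, data$data_set)
  orphan_ratio <- if (length(with_data) == 0L) NA_real_ else
    length(orphans) / length(with_data)

  matched <- if (!is.null(solution)) {
    solution$matched_flux
  } else {
    full <- stats::setNames(rep(0, length(data$data_set)), data$data_set)
    shared <- intersect(data$data_set, names(cm$flux))
    full[shared] <- abs(cm$flux[shared])
    full
  }
  dvals <- data$d[data$data_set]

  corr <- NA_real_
  if (length(with_data) >= 2L) {
    mf <- matched[with_data]
    dd <- dvals[with_data]
    if (stats::sd(mf) > 1e-12 && stats::sd(dd) > 1e-12) {
      corr <- unname(stats::cor(mf, dd))
    }
  }
  mean_residual <- if (length(dvals) > 0L) {
    mean(abs(dvals - matched[data$data_set]))
  } else {
    NA_real_
  }
  list(
    cardinality = length(active),
    data_orphan_ratio = orphan_ratio,
    correlation = corr,
    mean_residual = mean_residual
  )
}

#' Write extraction metrics as a one-row TSV
#' @param metrics Result of [model_metrics()].
#' @param path Output path.
#' @param context_id Optional context label column.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, context_id = NULL) {
  df <- data.frame(
    cardinality = metrics$cardinality,
    data_orphan_ratio = metrics$data_orphan_ratio,
    correlation = metrics$correlation,
    mean_residual = metrics$mean_residual
  )
  if (!is.null(context_id)) df <- cbind(context = context_id, df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
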