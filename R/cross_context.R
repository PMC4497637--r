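## Multi-context comparisons of extracted models: structural similarity
## (Jaccard matrices, z-scores, core/exclusive sets), agreement with the
## expression data (context correlation matrix, RV coefficient), and
## functional comparison by flux capacity (FVA range), mean flux capacity
## per subsystem or category, and CV ranking across contexts.

#' Jaccard similarity matrix of active-reaction sets
#'
#' Entry (a, b) is `|A n B| / |A u B|`. Two empty sets get similarity 1 by
#' convention (flagged via the `"empty_pairs"` attribute).
#'
#' @param active_sets Named list (>= 2) of character vectors.
#' @return Symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
jaccard_matrix <- function(active_sets) {
  stopifnot(length(active_sets) >= 2)
  k <- length(active_sets)
  nm <- names(active_sets)
  if (is.null(nm)) nm <- paste0("context", seq_len(k))
  J <- matrix(1, k, k, dimnames = list(nm, nm))
  empty_pairs <- FALSE
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      A <- unique(active_sets[[a]])
      B <- unique(active_sets[[b]])
      u <- length(union(A, B))
      if (u == 0) {
        J[a, b] <- J[b, a] <- 1
        empty_pairs <- TRUE
      } else {
        J[a, b] <- J[b, a] <- length(intersect(A, B)) / u
      }
    }
  }
  attr(J, "empty_pairs") <- empty_pairs
  J
}

#' Context z-scores from a similarity matrix
#'
#' Sums each context's similarity to the remaining contexts and z-normalizes
#' the sums (sample standard deviation). The z-score quantifies how much a
#' context differs from the rest: large negative values mark outlying
#' contexts.
#'
#' @param similarity Square symmetric similarity matrix.
#' @return Named numeric z-scores; all zero (with attribute
#'   `"degenerate" = TRUE`) when the sums have zero spread.
#' @export
context_zscores <- function(similarity) {
  stopifnot(nrow(similarity) == ncol(similarity))
  s <- rowSums(similarity) - diag(similarity)
  sdev <- stats::sd(s)
  if (is.na(sdev) || sdev == 0) {
    z <- stats::setNames(rep(0, length(s)), rownames(similarity))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  stats::setNames((s - mean(s)) / sdev, rownames(similarity))
}

#' RV coefficient between two square symmetric matrices
#'
#' Escoufier's matrix correlation: both matrices are double-centered (row
#' and column means removed) and
#' `RV = trace(AB) / sqrt(trace(AA) * trace(BB))`. It is invariant to
#' simultaneous relabeling of the contexts and to positive rescaling of
#' either matrix; for positive semidefinite inputs it lies in \[0, 1\].
#'
#' @param A,B Same-shaped square symmetric numeric matrices.
#' @return The coefficient, or `NA` when a denominator term vanishes.
#' @export
rv_coefficient <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)), nrow(A) == ncol(A))
  dc <- function(M) {
    M <- as.matrix(M)
    sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
  }
  Ac <- dc(A)
  Bc <- dc(B)
  num <- sum(Ac * Bc)           # trace(Ac %*% Bc) for symmetric matrices
  den <- sqrt(sum(Ac * Ac) * sum(Bc * Bc))
  if (den == 0) return(NA_real_)
  num / den
}

#' Core, exclusive and union reaction sets across contexts
#'
#' @param active_sets Named list (>= 2) of character vectors.
#' @return List with `core` (reactions in every context), `exclusive`
#'   (per context, reactions present in exactly that context) and
#'   `total_cardinality` (size of the union).
#' @export
core_and_exclusive <- function(active_sets) {
  stopifnot(length(active_sets) >= 2)
  sets <- lapply(active_sets, unique)
  all_rxns <- unlist(sets, use.names = FALSE)
  counts <- table(all_rxns)
  core <- Reduce(intersect, sets)
  once <- names(counts)[counts == 1]
  exclusive <- lapply(sets, function(s) intersect(s, once))
  list(core = core, exclusive = exclusive,
       total_cardinality = length(counts))
}

#' Flux capacity of a context model
#'
#' Runs FVA on the extracted submodel with bounds reset to
#' `[0, bound_magnitude]` for irreversible and
#' `[-bound_magnitude, bound_magnitude]` for reversible reactions (arbitrary
#' symmetric bounds that keep the flux cone bounded while respecting
#' directionality); the capacity of a reaction is `max - min >= 0`. Capacity
#' depends only on the topology of the extracted network, so it is a proxy
#' for which functions a context favors, independent of any single flux
#' state.
#'
#' @param cm A `context_model` (or a `metabolic_model`).
#' @param bound_magnitude Bound magnitude (default 1); capacities are
#'   homogeneous of degree 1 in it.
#' @return Named numeric vector of capacities.
#' @export
flux_capacity <- function(cm, bound_magnitude = 1) {
  model <- if (inherits(cm, "context_model")) cm$submodel else cm
  rev <- is_reversible(model)
  capped <- model
  capped$lb <- ifelse(rev, -bound_magnitude, 0)
  capped$ub <- rep(bound_magnitude, n_reactions(model))
  fva <- flux_variability(capped)
  stats::setNames(pmax(fva$max - fva$min, 0), fva$rxn_id)
}

#' Mean flux capacity per group and context
#'
#' Averages per-reaction flux capacities within each group (subsystem or
#' broader category) for every context. Reactions without a group label fall
#' into `"ungrouped"`. A group absent from a context's model contributes 0,
#' flagged in the `"absent"` attribute.
#'
#' @param capacities Named list: context id -> named capacity vector from
#'   [flux_capacity()].
#' @param grouping Named character vector: reaction id -> group label.
#' @return Matrix of mean capacities (groups x contexts) with an `"absent"`
#'   logical attribute matrix of the same shape.
#' @export
mfc_by_group <- function(capacities, grouping) {
  contexts <- names(capacities)
  stopifnot(!is.null(contexts))
  lab <- function(rxns) {
    g <- grouping[rxns]
    g[is.na(g) | !nzchar(g)] <- "ungrouped"
    g
  }
  groups <- sort(unique(unlist(lapply(capacities, function(cp) lab(names(cp))))))
  mfc <- matrix(0, length(groups), length(contexts),
                dimnames = list(groups, contexts))
  absent <- matrix(TRUE, length(groups), length(contexts),
                   dimnames = list(groups, contexts))
  for (cx in contexts) {
    cp <- capacities[[cx]]
    g <- lab(names(cp))
    means <- tapply(cp, g, mean)
    mfc[names(means), cx] <- means
    absent[names(means), cx] <- FALSE
  }
  attr(mfc, "absent") <- absent
  mfc
}

coef_variation <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Rank groups by the CV of their mean flux capacity across contexts
#'
#' The coefficient of variation (sample sd / mean) of each group's MFC row
#' across contexts measures context specificity: low-CV groups are evenly
#' represented everywhere (housekeeping metabolism), high-CV groups are
#' specific to few contexts. Groups with zero mean have undefined CV and are
#' ranked last.
#'
#' @param mfc Matrix from [mfc_by_group()] (groups x contexts, >= 2
#'   contexts).
#' @return Data frame (`group`, `mean_mfc`, `cv`) sorted by ascending CV.
#' @export
cv_ranking <- function(mfc) {
  stopifnot(ncol(mfc) >= 2)
  cv <- apply(mfc, 1, coef_variation)
  df <- data.frame(group = rownames(mfc), mean_mfc = rowMeans(mfc), cv = cv,
                   row.names = NULL, stringsAsFactors = FALSE)
  df[order(is.na(df$cv), df$cv), , drop = FALSE]
}

#' Robust core reactions (context-invariant flux capacity)
#'
#' Among the core reactions (present in every context), those whose flux
#' capacity has CV = 0 across contexts — i.e. the capacity is identical
#' everywhere — are robust to the context-specific network modifications.
#'
#' @param capacities Named list: context id -> named capacity vector.
#' @param core Character vector of core reaction ids.
#' @param tol CVs not exceeding this count as zero (absorbs LP round-off).
#' @return List with `robust` (ids), and `cv` (named CV per core reaction).
#' @export
robust_reactions <- function(capacities, core, tol = 1e-6) {
  if (length(core) == 0L) return(list(robust = character(0), cv = numeric(0)))
  cv <- vapply(core, function(r) {
    vals <- vapply(capacities, function(cp) cp[[r]], numeric(1))
    v <- coef_variation(vals)
    if (is.na(v) && all(vals == 0)) 0 else v
  }, numeric(1))
  list(robust = core[!is.na(cv) & cv <= tol], cv = cv)
}

#' Pearson correlation matrix of expression between contexts
#'
#' @param expr An `expression_matrix` (typically max-normalized).
#' @param genes Optional gene subset (e.g. the genes mapped to model
#'   reactions, the default comparison basis when a model is given).
#' @return Symmetric context-by-context correlation matrix.
#' @export
expression_correlation_matrix <- function(expr, genes = NULL) {
  v <- expr$values
  if (!is.null(genes)) {
    v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  }
  stats::cor(v, use = "pairwise.complete.obs")
}

#' Mann-Whitney enrichment of model genes in categorical protein levels
#'
#' For every context model, counts how many of its genes fall into each
#' protein-level category (`high`, `medium`, `low`) in that context; the
#' three one-sided Mann-Whitney tests then compare the per-context count
#' distributions (high > medium, medium > low, high > low). Exact p-values
#' are used for small untied samples, the normal approximation with tie
#' correction otherwise. Genes absent from the protein table are excluded.
#'
#' @param models Named list of `context_model` objects (names = context ids
#'   present in the protein table).
#' @param protein A `protein_level_table`.
#' @return List with `counts` (levels x contexts matrix) and `p_values`
#'   (named vector: `high_gt_medium`, `medium_gt_low`, `high_gt_low`).
#' @export
categorical_enrichment <- function(models, protein) {
  stopifnot(inherits(protein, "protein_level_table"))
  contexts <- names(models)
  missing_ctx <- setdiff(contexts, protein$context_ids)
  if (length(missing_ctx) > 0) {
    stop("context(s) absent from the protein table: ",
         paste(missing_ctx, collapse = ", "), call. = FALSE)
  }
  counts <- sapply(contexts, function(cx) {
    genes <- intersect(models[[cx]]$submodel$genes, protein$gene_ids)
    lv <- protein$level[genes, cx]
    c(high = sum(lv == "high"), medium = sum(lv == "medium"),
      low = sum(lv == "low"))
  })
  p <- c(
    high_gt_medium = mann_whitney_greater(counts["high", ], counts["medium", ]),
    medium_gt_low = mann_whitney_greater(counts["medium", ], counts["low", ]),
    high_gt_low = mann_whitney_greater(counts["high", ], counts["low", ])
  )
  list(counts = counts, p_values = p)
}

#' One-sided Mann-Whitney p-value (x stochastically greater than y)
#'
#' Thin wrapper over [stats::wilcox.test()]: exact for small samples without
#' ties, normal approximation with tie correction otherwise. Returns `NA`
#' for empty groups.
#'
#' @param x,y Numeric samples.
#' @return The one-sided p-value.
#' @export
mann_whitney_greater <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater")$p.value
  )
}

#' Assemble the full cross-context comparison report
#'
#' Given the per-context extraction results, computes the Jaccard similarity
#' matrix of active sets, the expression correlation matrix (over the genes
#' mapped to model reactions), the RV coefficient between the two, model-
#' and data-derived context z-scores, core/exclusive/union sets, per-context
#' flux capacities, MFC per group with its CV ranking, the robust core
#' subset, and (optionally) the categorical protein-level enrichment.
#'
#' @param models Named list of `context_model` objects (one per context).
#' @param expr The `expression_matrix` used for extraction (raw; normalized
#'   internally).
#' @param grouping Optional named character vector reaction -> group label;
#'   defaults to the subsystem labels of the models.
#' @param protein Optional `protein_level_table` for enrichment.
#' @param bound_magnitude Bound magnitude for flux capacity (default 1).
#' @return A list of class `cross_context_report`.
#' @export
cross_context_report <- function(models, expr, grouping = NULL,
                                 protein = NULL, bound_magnitude = 1) {
  stopifnot(length(models) >= 2)
  contexts <- names(models)
  active_sets <- lapply(models, function(m) m$active_set)
  jac <- jaccard_matrix(active_sets)
  sets <- core_and_exclusive(active_sets)

  model_genes <- sort(unique(unlist(lapply(models,
                                           function(m) m$submodel$genes))))
  normed <- normalize_expression(expr)
  expr_corr <- expression_correlation_matrix(normed, genes = model_genes)
  expr_corr <- expr_corr[contexts, contexts, drop = FALSE]
  rv <- rv_coefficient(jac, expr_corr)

  capacities <- lapply(models, flux_capacity,
                       bound_magnitude = bound_magnitude)
  if (is.null(grouping)) {
    grouping <- unlist(unname(lapply(models, function(m) {
      stats::setNames(m$submodel$subsystem, m$submodel$rxn_ids)
    })))
    grouping <- grouping[!duplicated(names(grouping))]
  }
  mfc <- mfc_by_group(capacities, grouping)
  ranking <- cv_ranking(mfc)
  robust <- robust_reactions(capacities, sets$core)

  enrichment <- if (!is.null(protein)) {
    categorical_enrichment(models, protein)
  }

  structure(
    list(
      contexts = contexts,
      jaccard = jac,
      expr_corr = expr_corr,
      rv = rv,
      zscores_model = context_zscores(jac),
      zscores_data = context_zscores(expr_corr),
      core_set = sets$core,
      exclusive_sets = sets$exclusive,
      total_cardinality = sets$total_cardinality,
      capacities = capacities,
      mfc = mfc,
      cv_ranking = ranking,
      robust_set = robust$robust,
      core_capacity_cv = robust$cv,
      enrichment = enrichment
    ),
    class = "cross_context_report"
  )
}

#' @export
print.cross_context_report <- function(x, ...) {
  cat("Cross-context report over", length(x$contexts), "contexts\n")
  cat("  mean off-diagonal Jaccard:",
      format(mean(x$jaccard[lower.tri(x$jaccard)]), digits = 3), "\n")
  cat("  RV(model structure, expression):", format(x$rv, digits = 3), "\n")
  cat("  core:", length(x$core_set),
      "| total exclusive:", sum(lengths(x$exclusive_sets)),
      "| union:", x$total_cardinality, "\n")
  cat("  robust core reactions:", length(x$robust_set), "\n")
  invisible(x)
}
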