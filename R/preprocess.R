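#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its flux subject to the
#' steady-state condition `S v = 0` and the model's bounds (two linear
#' programs per reaction).
#'
#' @param model A `metabolic_model` with finite bounds.
#' @param tolerance Kept for interface symmetry with
#'   [find_blocked_reactions()]; the LPs themselves are solved to backend
#'   precision.
#' @return A data frame with columns `rxn_id`, `min`, `max`.
#' @export
flux_variability <- function(model, tolerance = 1e-6) {
  if (any(!is.finite(model$lb)) || any(!is.finite(model$ub))) {
    stop("flux variability requires finite bounds on all reactions",
         call. = FALSE)
  }
  S <- as.matrix(model$S)
  n <- n_reactions(model)
  vmin <- vmax <- numeric(n)
  for (j in seq_len(n)) {
    ej <- numeric(n)
    ej[j] <- 1
    lo <- lp_flux_solve(S, ej, model$lb, model$ub)
    hi <- lp_flux_solve(S, -ej, model$lb, model$ub)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("steady-state system infeasible during FVA (reaction ",
           model$rxn_ids[j], ")", call. = FALSE)
    }
    vmin[j] <- lo$value
    vmax[j] <- -hi$value
  }
  data.frame(rxn_id = model$rxn_ids, min = vmin, max = vmax,
             stringsAsFactors = FALSE)
}

#' Identify blocked reactions
#'
#' A reaction is blocked when it cannot carry flux in any feasible
#' steady-state distribution, i.e. its FVA minimum and maximum are both
#' within `tolerance` of zero.
#'
#' @param model A `metabolic_model`.
#' @param tolerance Activity tolerance (default `1e-6`).
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, tolerance = 1e-6) {
  fva <- flux_variability(model, tolerance)
  fva$rxn_id[abs(fva$min) <= tolerance & abs(fva$max) <= tolerance]
}

#' Extract the consistent part of a model
#'
#' Removes blocked reactions (iterating to a fixpoint) and prunes metabolites
#' left without reactions. The result has an empty blocked set at the same
#' tolerance, and applying the function again returns it unchanged.
#'
#' @param model A `metabolic_model`.
#' @param tolerance Activity tolerance for blocked-reaction detection.
#' @return A consistent `metabolic_model`.
#' @export
extract_consistent_model <- function(model, tolerance = 1e-6) {
  repeat {
    blocked <- find_blocked_reactions(model, tolerance)
    if (length(blocked) == 0L) return(model)
    keep <- setdiff(model$rxn_ids, blocked)
    if (length(keep) == 0L) {
      stop("all reactions are blocked; no consistent submodel exists",
           call. = FALSE)
    }
    model <- subset_model(model, keep)
  }
}

#' Max-normalize expression across contexts
#'
#' Each gene's values are divided by the gene's maximum across all contexts:
#' `d[i, j] = t[i, j] / max_j t[i, j]`. This removes the between-gene scale
#' differences (orders of magnitude in RNAseq data) that would otherwise bias
#' the flux fit toward highly expressed genes. All-zero rows map to all-zero
#' (0/0 := 0); absent (`NA`) cells stay absent and are ignored when taking
#' the maximum.
#'
#' @param expr An `expression_matrix`.
#' @return An `expression_matrix` with values in \[0, 1\].
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  mx <- apply(v, 1, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  scale <- ifelse(is.na(mx) | mx == 0, 1, mx)
  expression_matrix(v / scale)
}

#' Map expression data onto reactions for one context
#'
#' Evaluates each reaction's GPR rule on the normalized gene values of the
#' chosen context (AND = min, OR = max over defined genes, see
#' [evaluate_gpr()]). Reactions with no GPR, or whose genes are all absent,
#' receive no data and become data-orphan candidates. Genes present in the
#' model but missing from the expression matrix are treated as absent.
#'
#' @param model A `metabolic_model`.
#' @param normalized A max-normalized `expression_matrix`.
#' @param context A context id present in the matrix.
#' @return An object of class `reaction_data` with fields `context_id`,
#'   `d` (numeric named by reaction id, `NA` outside the data set) and
#'   `data_set` (character vector of data-covered reaction ids).
#' @export
map_expression_to_reactions <- function(model, normalized, context) {
  stopifnot(inherits(normalized, "expression_matrix"))
  if (!context %in% normalized$context_ids) {
    stop("context '", context, "' not present in the expression matrix",
         call. = FALSE)
  }
  gv <- stats::setNames(rep(NA_real_, length(model$genes)), model$genes)
  shared <- intersect(model$genes, normalized$gene_ids)
  gv[shared] <- normalized$values[shared, context]
  d <- vapply(model$gpr_ast, function(ast) {
    if (is.null(ast)) NA_real_ else evaluate_gpr(ast, gv)
  }, numeric(1))
  names(d) <- model$rxn_ids
  reaction_data(context_id = context, d = d)
}

#' Construct a per-reaction data vector
#'
#' @param context_id Context identifier.
#' @param d Numeric vector named by reaction id; values in \[0, 1\], `NA`
#'   marking reactions without data.
#' @return A `reaction_data` object.
#' @export
reaction_data <- function(context_id, d) {
  if (is.null(names(d))) stop("d must be named by reaction id", call. = FALSE)
  if (any(d < -1e-12 | d > 1 + 1e-12, na.rm = TRUE)) {
    stop("reaction data values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(context_id = context_id, d = d, data_set = names(d)[!is.na(d)]),
    class = "reaction_data"
  )
}

#' @export
print.reaction_data <- function(x, ...) {
  cat("Reaction data for context '", x$context_id, "': ",
      length(x$data_set), " of ", length(x$d),
      " reactions data-covered\n", sep = "")
  invisible(x)
}

#' Split reversible reactions into forward and reverse components
#'
#' Produces the irreversible-only augmentation consumed by the optimizer:
#' every reaction contributes a forward column, and each reversible reaction
#' (lower bound < 0) additionally a negated reverse column. All split fluxes
#' are bounded by \[0, `flux_cap`\]; the cap replaces the model's own bound
#' magnitudes so that fluxes live on the same \[0, 1\] scale as the
#' max-normalized data (the default cap of 1). The net flux of a reversible
#' reaction is `v_fwd - v_rev`.
#'
#' @param model A consistent `metabolic_model`.
#' @param flux_cap Upper bound applied to every split flux (default 1).
#' @return An object of class `split_model` with fields `base`, `S_split`,
#'   `fwd_index`, `rev_index` (NA for irreversible reactions), `irrev_set`,
#'   `rev_set` (reaction indices), `vmax_split`, and `col_rxn` (original
#'   reaction index per split column).
#' @export
split_reversible <- function(model, flux_cap = 1) {
  stopifnot(flux_cap > 0)
  n <- n_reactions(model)
  rev <- which(is_reversible(model))
  irrev <- setdiff(seq_len(n), rev)
  S <- as.matrix(model$S)
  S_split <- cbind(S, -S[, rev, drop = FALSE])
  fwd_index <- seq_len(n)
  rev_index <- rep(NA_integer_, n)
  rev_index[rev] <- n + seq_along(rev)
  n_split <- n + length(rev)
  rev_names <- if (length(rev) > 0) paste0(model$rxn_ids[rev], "__rev") else character(0)
  colnames(S_split) <- c(model$rxn_ids, rev_names)
  structure(
    list(
      base = model,
      S_split = S_split,
      fwd_index = fwd_index,
      rev_index = rev_index,
      irrev_set = irrev,
      rev_set = rev,
      vmax_split = rep(flux_cap, n_split),
      col_rxn = c(seq_len(n), rev)
    ),
    class = "split_model"
  )
}

#' Reconstruct net fluxes from a split flux vector
#' @param split A `split_model`.
#' @param v_split Non-negative split flux vector.
#' @return Numeric net flux named by reaction id.
#' @export
net_flux <- function(split, v_split) {
  n <- n_reactions(split$base)
  v <- v_split[split$fwd_index]
  has_rev <- !is.na(split$rev_index)
  v[has_rev] <- v[has_rev] - v_split[split$rev_index[has_rev]]
  stats::setNames(v, split$base$rxn_ids)
}
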