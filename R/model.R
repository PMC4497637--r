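#' Construct a metabolic model
#'
#' The internal representation of a (genome-scale) metabolic network: a sparse
#' stoichiometric matrix `S` (metabolites x reactions), per-reaction flux
#' bounds, GPR rules, and optional subsystem labels. A reaction is reversible
#' iff its lower bound is negative. GPR strings are parsed once at
#' construction and stored both as canonical text and as expression trees.
#'
#' @param S Stoichiometric matrix (dense or sparse), metabolites in rows.
#' @param lb,ub Numeric flux bounds, one per reaction; `lb <= ub` required.
#' @param rxn_ids,met_ids Unique identifier vectors matching the columns and
#'   rows of `S`.
#' @param gpr Character vector of GPR rules (empty string = no association).
#' @param subsystem Character vector of subsystem labels (may be empty
#'   strings).
#' @param category_map Optional named character vector mapping subsystem
#'   labels to broader categories.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lb, ub, rxn_ids, met_ids,
                            gpr = NULL, subsystem = NULL,
                            category_map = NULL) {
  S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  n <- ncol(S)
  m <- nrow(S)
  if (is.null(gpr)) gpr <- rep("", n)
  if (is.null(subsystem)) subsystem <- rep("", n)
  gpr[is.na(gpr)] <- ""
  subsystem[is.na(subsystem)] <- ""
  if (nrow(S) != length(met_ids) || ncol(S) != length(rxn_ids)) {
    stop("stoichiometric matrix dimensions (", nrow(S), " x ", ncol(S),
         ") do not match identifier lists (", length(met_ids), " x ",
         length(rxn_ids), ")", call. = FALSE)
  }
  gpr_ast <- lapply(gpr, parse_gpr)
  gpr <- vapply(gpr_ast, deparse_gpr, "")  # canonical text form
  genes <- sort(unique(unlist(lapply(gpr_ast, gpr_genes))))
  rownames(S) <- met_ids
  colnames(S) <- rxn_ids
  model <- structure(
    list(
      met_ids = as.character(met_ids),
      rxn_ids = as.character(rxn_ids),
      S = S,
      lb = as.numeric(lb),
      ub = as.numeric(ub),
      gpr = gpr,
      gpr_ast = gpr_ast,
      genes = genes,
      subsystem = as.character(subsystem),
      category_map = category_map
    ),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks matrix dimensions against the identifier lists, identifier
#' uniqueness, bound ordering (`lb <= ub`), and that every gene referenced by
#' a GPR appears in the model's gene set.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- length(model$rxn_ids)
  m <- length(model$met_ids)
  if (nrow(model$S) != m || ncol(model$S) != n) {
    stop("stoichiometric matrix dimensions (", nrow(model$S), " x ",
         ncol(model$S), ") do not match identifier lists (", m, " x ", n, ")",
         call. = FALSE)
  }
  if (anyDuplicated(model$rxn_ids)) stop("duplicate reaction ids", call. = FALSE)
  if (anyDuplicated(model$met_ids)) stop("duplicate metabolite ids", call. = FALSE)
  if (length(model$lb) != n || length(model$ub) != n) {
    stop("bound vectors must have one entry per reaction", call. = FALSE)
  }
  bad <- which(model$lb > model$ub)
  if (length(bad) > 0L) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(model$rxn_ids[bad], collapse = ", "), call. = FALSE)
  }
  if (length(model$gpr) != n || length(model$subsystem) != n) {
    stop("gpr/subsystem vectors must have one entry per reaction", call. = FALSE)
  }
  rule_genes <- unique(unlist(lapply(model$gpr_ast, gpr_genes)))
  if (!all(rule_genes %in% model$genes)) {
    stop("GPR references genes outside the model gene set", call. = FALSE)
  }
  invisible(model)
}

#' Reversibility indicator per reaction (lower bound < 0)
#' @param model A `metabolic_model`.
#' @return Logical vector over reactions.
#' @export
is_reversible <- function(model) model$lb < 0

#' Number of reactions / metabolites
#' @param model A `metabolic_model`.
#' @export
n_reactions <- function(model) length(model$rxn_ids)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) length(model$met_ids)

#' Restrict a model to a subset of reactions
#'
#' Keeps the given reactions and prunes metabolites that no longer take part
#' in any remaining reaction (all-zero stoichiometry rows).
#'
#' @param model A `metabolic_model`.
#' @param keep Reaction ids (character) or indices to keep.
#' @return A `metabolic_model`.
#' @export
subset_model <- function(model, keep) {
  if (is.character(keep)) {
    idx <- match(keep, model$rxn_ids)
    if (anyNA(idx)) {
      stop("unknown reaction id(s): ",
           paste(keep[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(keep)
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L) stop("cannot build an empty model", call. = FALSE)
  S_sub <- model$S[, idx, drop = FALSE]
  used_mets <- which(Matrix::rowSums(abs(S_sub)) > 0)
  if (length(used_mets) == 0L) {
    stop("subset leaves no connected metabolites", call. = FALSE)
  }
  metabolic_model(
    S = S_sub[used_mets, , drop = FALSE],
    lb = model$lb[idx], ub = model$ub[idx],
    rxn_ids = model$rxn_ids[idx],
    met_ids = model$met_ids[used_mets],
    gpr = model$gpr[idx],
    subsystem = model$subsystem[idx],
    category_map = model$category_map
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", n_metabolites(x), "metabolites x",
      n_reactions(x), "reactions\n")
  cat("  reversible:", sum(is_reversible(x)),
      "| with GPR:", sum(nzchar(x$gpr)),
      "| genes:", length(x$genes), "\n")
  subs <- unique(x$subsystem[nzchar(x$subsystem)])
  if (length(subs) > 0) cat("  subsystems:", length(subs), "\n")
  invisible(x)
}
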