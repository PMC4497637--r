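## Synthetic ground-truth fixtures: small stoichiometrically consistent
## networks (uptake -> parallel pathways -> secretion) with one gene per
## internal reaction, and expression matrices in which each context favors
## one pathway. The generator emulates only what the method consumes —
## non-negative per-context profiles whose cross-context maxima make the
## normalization non-trivial — not realistic transcriptome distributions.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy metabolic network with known pathway structure
#'
#' Builds an uptake -> {parallel pathways} -> secretion topology: a single
#' uptake reaction produces the root metabolite, each of `n_parallel_pathways`
#' linear pathways of `pathway_length` reactions converts it to the sink
#' metabolite, and a secretion reaction drains the sink. Every internal
#' (pathway) reaction carries a unique gene as its GPR and the subsystem
#' label `pathway_<p>`; a requested number of internal reactions are made
#' reversible (bounds \[-1, 1\]) or stripped of their GPR (data orphans),
#' chosen deterministically under `seed`. The network is consistent by
#' construction: every reaction can carry flux along its pathway.
#'
#' @param n_parallel_pathways Number of parallel pathways (>= 1).
#' @param pathway_length Reactions per pathway (>= 1).
#' @param n_reversible Number of reversible internal reactions.
#' @param n_orphan Number of internal reactions without a GPR.
#' @param seed Integer seed controlling the reversible/orphan choices.
#' @return A `metabolic_model` with
#'   `n_parallel_pathways * pathway_length + 2` reactions.
#' @export
make_toy_network <- function(n_parallel_pathways = 2, pathway_length = 3,
                             n_reversible = 1, n_orphan = 0, seed = 1) {
  stopifnot(n_parallel_pathways >= 1, pathway_length >= 1,
            n_reversible >= 0, n_orphan >= 0)
  n_internal <- n_parallel_pathways * pathway_length
  if (n_reversible > n_internal) {
    stop("more reversible reactions requested (", n_reversible,
         ") than internal reactions (", n_internal, ")", call. = FALSE)
  }
  if (n_orphan > n_internal) {
    stop("more orphan reactions requested (", n_orphan,
         ") than internal reactions (", n_internal, ")", call. = FALSE)
  }

  mets <- c("M_root",
            unlist(lapply(seq_len(n_parallel_pathways), function(p) {
              if (pathway_length > 1)
                sprintf("M_p%d_%d", p, seq_len(pathway_length - 1))
            })),
            "M_sink")
  rxn_ids <- c("R_uptake",
               unlist(lapply(seq_len(n_parallel_pathways), function(p) {
                 sprintf("P%d_R%d", p, seq_len(pathway_length))
               })),
               "R_secrete")
  n <- length(rxn_ids)
  S <- matrix(0, length(mets), n, dimnames = list(mets, rxn_ids))
  S["M_root", "R_uptake"] <- 1
  S["M_sink", "R_secrete"] <- -1
  for (p in seq_len(n_parallel_pathways)) {
    chain <- c("M_root",
               if (pathway_length > 1)
                 sprintf("M_p%d_%d", p, seq_len(pathway_length - 1)),
               "M_sink")
    for (r in seq_len(pathway_length)) {
      rid <- sprintf("P%d_R%d", p, r)
      S[chain[r], rid] <- -1
      S[chain[r + 1], rid] <- 1
    }
  }

  internal <- setdiff(rxn_ids, c("R_uptake", "R_secrete"))
  picks <- with_seed(seed, list(
    reversible = sample(internal, n_reversible),
    orphan = sample(internal, n_orphan)
  ))
  lb <- stats::setNames(rep(0, n), rxn_ids)
  lb[picks$reversible] <- -1
  gpr <- stats::setNames(rep("", n), rxn_ids)
  gpr[internal] <- paste0("g_", internal)
  gpr[picks$orphan] <- ""
  subsystem <- stats::setNames(rep("exchange", n), rxn_ids)
  for (p in seq_len(n_parallel_pathways)) {
    subsystem[sprintf("P%d_R%d", p, seq_len(pathway_length))] <-
      paste0("pathway_", p)
  }

  metabolic_model(S = S, lb = unname(lb), ub = rep(1, n),
                  rxn_ids = rxn_ids, met_ids = mets,
                  gpr = unname(gpr), subsystem = unname(subsystem))
}

toy_pathways <- function(model) {
  subs <- unique(model$subsystem)
  sort(subs[grepl("^pathway_", subs)])
}

#' Generate a synthetic expression matrix with pathway-specific signal
#'
#' Each context favors one pathway: genes of the favored pathway draw from
#' `N(signal, noise_sd)` and all other pathway genes from
#' `N(0.1 * signal, noise_sd)`, clipped at zero (expression is
#' non-negative). By default context 1 favors `favored_pathway` and the
#' remaining contexts favor the other pathways cyclically, so that each
#' gene's cross-context maximum sits in its pathway's favored context and
#' max-normalization is non-trivial. An `NA` entry in a `favored_pathway`
#' vector makes that context unstructured (uniform draws on
#' \[0, `signal`\]).
#'
#' @param model A toy network from [make_toy_network()].
#' @param favored_pathway Pathway index favored by context 1, or a vector of
#'   length `n_contexts` giving each context's favored pathway.
#' @param signal Expression level of favored-pathway genes, in (0, 1\].
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_contexts Number of contexts (>= 1).
#' @param seed Integer seed; draws are deterministic under it.
#' @return An `expression_matrix` (genes x contexts).
#' @export
make_synthetic_expression <- function(model, favored_pathway = 1,
                                      signal = 1, noise_sd = 0.05,
                                      n_contexts = 2, seed = 1) {
  stopifnot(signal > 0, signal <= 1, noise_sd >= 0, n_contexts >= 1)
  pathways <- toy_pathways(model)
  np <- length(pathways)
  if (np == 0) stop("model carries no pathway_<p> subsystems", call. = FALSE)
  if (length(favored_pathway) == 1L) {
    favored <- ((favored_pathway - 1 + seq_len(n_contexts) - 1) %% np) + 1
  } else {
    stopifnot(length(favored_pathway) == n_contexts)
    favored <- favored_pathway
  }
  if (any(!is.na(favored) & (favored < 1 | favored > np))) {
    stop("favored pathway index out of range (1..", np, ")", call. = FALSE)
  }

  gene_rxn <- stats::setNames(model$rxn_ids, paste0("g_", model$rxn_ids))
  genes <- intersect(names(gene_rxn), model$genes)
  gene_pathway <- model$subsystem[match(gene_rxn[genes], model$rxn_ids)]

  values <- with_seed(seed, {
    v <- matrix(0, length(genes), n_contexts,
                dimnames = list(genes, sprintf("context_%d", seq_len(n_contexts))))
    for (j in seq_len(n_contexts)) {
      if (is.na(favored[j])) {
        v[, j] <- stats::runif(length(genes), 0, signal)
      } else {
        mu <- ifelse(gene_pathway == paste0("pathway_", favored[j]),
                     signal, 0.1 * signal)
        v[, j] <- pmax(stats::rnorm(length(genes), mu, noise_sd), 0)
      }
    }
    v
  })
  expression_matrix(values)
}

#' Ground-truth recovery score of an extracted toy model
#'
#' Sensitivity is the fraction of the favored pathway's reactions included
#' in the active set; specificity the fraction of the *other* pathways'
#' reactions correctly excluded.
#'
#' @param cm A `context_model`, or a character vector of active reaction
#'   ids (so the empty active set can be scored).
#' @param model The toy `metabolic_model` the extraction started from.
#' @param favored_pathway Index of the ground-truth favored pathway.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
ground_truth_score <- function(cm, model, favored_pathway) {
  active <- if (inherits(cm, "context_model")) cm$active_set else as.character(cm)
  fav_lab <- paste0("pathway_", favored_pathway)
  pathway_rxns <- model$rxn_ids[grepl("^pathway_", model$subsystem)]
  favored_rxns <- model$rxn_ids[model$subsystem == fav_lab]
  if (length(favored_rxns) == 0) {
    stop("no reactions labelled ", fav_lab, call. = FALSE)
  }
  other_rxns <- setdiff(pathway_rxns, favored_rxns)
  c(
    sensitivity = mean(favored_rxns %in% active),
    specificity = if (length(other_rxns) == 0) 1 else
      mean(!(other_rxns %in% active))
  )
}
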