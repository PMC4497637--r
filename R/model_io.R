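## Model serialization: COBRA-style JSON and SBML Level 3 with the fbc
## (flux-bound / gene-association) extension. Both dialects round-trip the
## fields this package uses: stoichiometry, bounds, GPR text, subsystems.

#' Read a metabolic model from SBML or COBRA JSON
#'
#' @param path Path to the model file.
#' @param format `"auto"` (by extension), `"sbml"`, or `"json"`.
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path)
  )
}

#' Write a metabolic model to SBML or COBRA JSON
#'
#' @param model A `metabolic_model` or `context_model` (the submodel is
#'   written, with orphan metabolites already pruned).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"sbml"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (inherits(model, "context_model")) model <- model$submodel
  stopifnot(inherits(model, "metabolic_model"))
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
    json = write_model_json(model, path),
    sbml = write_model_sbml(model, path)
  )
  invisible(path)
}

#' @rdname write_model
#' @export
write_context_model <- write_model

## ---- COBRA JSON dialect ----------------------------------------------------

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    stop("not a COBRA-style JSON model (missing reactions/metabolites): ",
         path, call. = FALSE)
  }
  met_ids <- vapply(doc$metabolites, function(m) m$id, "")
  rxns <- doc$reactions
  rxn_ids <- vapply(rxns, function(r) r$id, "")
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxns))
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$metabolites
    if (length(st) > 0) {
      i <- match(names(st), met_ids)
      if (anyNA(i)) {
        stop("reaction ", rxn_ids[j], " references unknown metabolite(s)",
             call. = FALSE)
      }
      S[i, j] <- unlist(st)
    }
  }
  getf <- function(field, default) {
    vapply(rxns, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else v
    }, default)
  }
  model <- metabolic_model(
    S = S,
    lb = getf("lower_bound", NA_real_),
    ub = getf("upper_bound", NA_real_),
    rxn_ids = rxn_ids, met_ids = met_ids,
    gpr = getf("gene_reaction_rule", ""),
    subsystem = getf("subsystem", "")
  )
  model
}

write_model_json <- function(model, path) {
  rxns <- lapply(seq_along(model$rxn_ids), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    list(
      id = model$rxn_ids[j],
      metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                            model$met_ids[nz])),
      lower_bound = model$lb[j],
      upper_bound = model$ub[j],
      gene_reaction_rule = model$gpr[j],
      subsystem = model$subsystem[j]
    )
  })
  doc <- list(
    metabolites = lapply(model$met_ids, function(id) list(id = id)),
    reactions = rxns,
    genes = lapply(model$genes, function(id) list(id = id))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- SBML Level 3 + fbc v2 -------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_safe_id <- function(x, prefix) {
  paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))
}

num17 <- function(x) sprintf("%.17g", x)

write_model_sbml <- function(model, path) {
  n <- n_reactions(model)
  bounds <- sort(unique(c(model$lb, model$ub)))
  bid <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)), num17(bounds))
  gene_sid <- stats::setNames(sbml_safe_id(model$genes, "G_"), model$genes)

  doc <- xml2::xml_new_root(
    "sbml",
    "xmlns" = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(bounds)) {
    xml2::xml_add_child(lop, "parameter", id = bid[[k]],
                        value = num17(bounds[k]), constant = "true")
  }
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(loc, "compartment", id = "c", constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$met_ids) {
    xml2::xml_add_child(los, "species", id = sbml_safe_id(m, "M_"),
                        name = m, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  if (length(model$genes) > 0) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = gene_sid[[g]], "fbc:label" = g)
    }
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(n)) {
    rx <- xml2::xml_add_child(
      lor, "reaction",
      id = sbml_safe_id(model$rxn_ids[j], "R_"),
      name = model$rxn_ids[j],
      reversible = tolower(as.character(model$lb[j] < 0)),
      fast = "false",
      "fbc:lowerFluxBound" = bid[[num17(model$lb[j])]],
      "fbc:upperFluxBound" = bid[[num17(model$ub[j])]]
    )
    if (nzchar(model$subsystem[j])) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p",
                          paste0("SUBSYSTEM: ", model$subsystem[j]))
    }
    col <- model$S[, j]
    reac <- which(col < 0)
    prod <- which(col > 0)
    if (length(reac) > 0) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in reac) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sbml_safe_id(model$met_ids[i], "M_"),
                            stoichiometry = num17(-col[i]), constant = "true")
      }
    }
    if (length(prod) > 0) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in prod) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sbml_safe_id(model$met_ids[i], "M_"),
                            stoichiometry = num17(col[i]), constant = "true")
      }
    }
    if (!is.null(model$gpr_ast[[j]])) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      sbml_write_gpa(gpa, model$gpr_ast[[j]], gene_sid)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpa <- function(parent, node, gene_sid) {
  if (node$type == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = gene_sid[[node$id]])
  } else {
    grp <- xml2::xml_add_child(parent, paste0("fbc:", node$type))
    for (a in node$args) sbml_write_gpa(grp, a, gene_sid)
  }
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met_sid <- xml2::xml_attr(species, "id")
  met_ids <- xml2::xml_attr(species, "name")
  met_ids[is.na(met_ids)] <- met_sid[is.na(met_ids)]
  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_label <- stats::setNames(
    xml2::xml_attr(gps, "label"),
    xml2::xml_attr(gps, "id")
  )
  gene_label[is.na(gene_label)] <- names(gene_label)[is.na(gene_label)]

  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rxns)
  m <- length(met_ids)
  if (n == 0L || m == 0L) stop("SBML model has no reactions or species",
                               call. = FALSE)
  S <- matrix(0, nrow = m, ncol = n)
  lb <- ub <- numeric(n)
  gpr <- subsystem <- character(n)
  rxn_ids <- character(n)
  for (j in seq_len(n)) {
    rx <- rxns[[j]]
    nm <- xml2::xml_attr(rx, "name")
    rxn_ids[j] <- if (is.na(nm)) xml2::xml_attr(rx, "id") else nm
    lb[j] <- pval[[xml2::xml_attr(rx, "lowerFluxBound")]]
    ub[j] <- pval[[xml2::xml_attr(rx, "upperFluxBound")]]
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)) {
      i <- match(xml2::xml_attr(sr, "species"), met_sid)
      S[i, j] <- S[i, j] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)) {
      i <- match(xml2::xml_attr(sr, "species"), met_sid)
      S[i, j] <- S[i, j] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    note <- xml2::xml_find_first(rx, ".//s:notes//*[starts-with(text(),'SUBSYSTEM:')]", ns)
    if (!inherits(note, "xml_missing")) {
      subsystem[j] <- trimws(sub("^SUBSYSTEM:", "", xml2::xml_text(note)))
    }
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation/*", ns)
    if (!inherits(gpa, "xml_missing")) {
      gpr[j] <- deparse_gpr(sbml_read_gpa(gpa, gene_label))
    }
  }
  metabolic_model(S = S, lb = lb, ub = ub, rxn_ids = rxn_ids,
                  met_ids = met_ids, gpr = gpr, subsystem = subsystem)
}

sbml_read_gpa <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    sid <- xml2::xml_attr(node, "geneProduct")
    lbl <- gene_label[[sid]]
    return(list(type = "gene", id = if (is.null(lbl) || is.na(lbl)) sid else lbl))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(type = nm, args = lapply(kids, sbml_read_gpa, gene_label)))
  }
  stop("unsupported geneProductAssociation node: ", nm, call. = FALSE)
}
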