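## Gene-protein-reaction (GPR) rules: boolean expressions over gene
## identifiers with the COBRA grammar — "and"/"or" (case-insensitive) and
## parentheses, nothing else.

#' Parse a GPR rule into a boolean expression tree
#'
#' @param rule A GPR string such as `"(g1 and g2) or g3"`. Empty strings and
#'   `NA` parse to `NULL` (no association).
#' @return A nested list: leaves are `list(type = "gene", id = <chr>)`,
#'   internal nodes `list(type = "and"|"or", args = <list>)`, or `NULL`.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  ast <- gpr_parse_or(st)
  if (st$pos <= length(st$tokens)) {
    stop("GPR parse error: unexpected token '", st$tokens[st$pos],
         "' in rule: ", rule, call. = FALSE)
  }
  ast
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  tokens[nzchar(tokens)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$tokens)) NA_character_ else st$tokens[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(type = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(type = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: unexpected end of rule", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop("GPR parse error: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tk, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  list(type = "gene", id = tk)
}

#' Deparse a GPR tree back to its canonical string form
#'
#' Compound subexpressions are always parenthesized, so the output is a
#' stable canonical form: `parse_gpr(deparse_gpr(x))` reproduces `x` and
#' serialization round-trips are textually exact.
#'
#' @param ast A tree from [parse_gpr()].
#' @return A character string (empty for `NULL`).
#' @export
deparse_gpr <- function(ast) {
  if (is.null(ast)) return("")
  rec <- function(node, top) {
    if (node$type == "gene") return(node$id)
    inner <- paste(vapply(node$args, rec, "", top = FALSE),
                   collapse = paste0(" ", node$type, " "))
    if (top) inner else paste0("(", inner, ")")
  }
  rec(ast, top = TRUE)
}

#' List the gene identifiers occurring in a GPR tree
#' @param ast A tree from [parse_gpr()].
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  out <- character(0)
  rec <- function(node) {
    if (node$type == "gene") {
      out[[length(out) + 1L]] <<- node$id
    } else {
      for (a in node$args) rec(a)
    }
  }
  rec(ast)
  unique(out)
}

#' Evaluate a GPR rule on gene-level values
#'
#' AND nodes take the minimum and OR nodes the maximum of their *defined*
#' children; a node all of whose children are absent (`NA`) is itself absent,
#' and an empty rule evaluates to absent. This min/max aggregation preserves
#' the \[0, 1\] range of max-normalized expression.
#'
#' @param ast A tree from [parse_gpr()] (or a rule string).
#' @param gene_values Named numeric vector of non-negative values; `NA` marks
#'   an absent (unmeasured) gene. Every gene referenced by the rule must be
#'   named here.
#' @return A single value, or `NA` when the rule is absent/undefined.
#' @examples
#' evaluate_gpr("g1 and g2", c(g1 = 0.2, g2 = 0.8))  # 0.2
#' evaluate_gpr("g1 or g2", c(g1 = 0.2, g2 = 0.8))   # 0.8
#' @export
evaluate_gpr <- function(ast, gene_values) {
  if (is.character(ast)) ast <- parse_gpr(ast)
  if (is.null(ast)) return(NA_real_)
  missing_genes <- setdiff(gpr_genes(ast), names(gene_values))
  if (length(missing_genes) > 0L) {
    stop("unknown gene id(s) in GPR rule: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  rec <- function(node) {
    if (node$type == "gene") return(unname(gene_values[[node$id]]))
    vals <- vapply(node$args, rec, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (node$type == "and") min(vals) else max(vals)
  }
  rec(ast)
}
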