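#' Construct an expression matrix
#'
#' A gene-by-context table of non-negative expression values (e.g. RPKM).
#' Missing cells are `NA` and mean "absent" (unmeasured), never zero: a zero
#' would wrongly pull the associated reaction's flux toward zero through the
#' data constraint, whereas an absent gene simply contributes no data.
#'
#' @param values Numeric matrix with genes in rows and contexts in columns;
#'   must carry row and column names.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need gene row names and context column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  structure(
    list(gene_ids = rownames(values), context_ids = colnames(values),
         values = values),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", length(x$gene_ids), "genes x",
      length(x$context_ids), "contexts\n")
  cat("  contexts:", paste(x$context_ids, collapse = ", "), "\n")
  na <- sum(is.na(x$values))
  if (na > 0) cat("  absent cells:", na, "\n")
  invisible(x)
}

#' Read a gene-by-context expression table
#'
#' Delimited text (TSV, or CSV for `.csv` paths) with a header row: the first
#' column holds gene identifiers, the remaining columns one context each.
#' Empty cells become `NA` (absent). Negative values and duplicated gene ids
#' are validation errors.
#'
#' @param path Path to the table.
#' @param sep Field separator; default inferred from the file extension.
#' @return An `expression_matrix`.
#' @export
read_expression_table <- function(path, sep = NULL) {
  df <- read_id_table(path, sep)
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) storage.mode(values) <- "double"
  rownames(values) <- as.character(df[[1]])
  expression_matrix(values)
}

#' Read a gene-by-context categorical protein-level table
#'
#' Same layout as [read_expression_table()], but cells hold the categorical
#' levels `high`, `medium`, `low` or `absent` (case-insensitive; empty cells
#' and `NA` map to `absent`).
#'
#' @param path Path to the table.
#' @param sep Field separator; default inferred from the file extension.
#' @return An object of class `protein_level_table` with fields `gene_ids`,
#'   `context_ids` and a character matrix `level`.
#' @export
read_protein_table <- function(path, sep = NULL) {
  df <- read_id_table(path, sep)
  lv <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(lv) <- "character"
  lv <- tolower(trimws(lv))
  lv[is.na(lv) | lv == ""] <- "absent"
  bad <- setdiff(unique(as.vector(lv)), c("high", "medium", "low", "absent"))
  if (length(bad) > 0) {
    stop("invalid protein level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(lv) <- as.character(df[[1]])
  if (anyDuplicated(rownames(lv))) {
    stop("duplicate gene ids in protein-level table", call. = FALSE)
  }
  structure(
    list(gene_ids = rownames(lv), context_ids = colnames(lv), level = lv),
    class = "protein_level_table"
  )
}

read_id_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) {
    stop("table needs a gene-id column plus at least one context column",
         call. = FALSE)
  }
  df
}

#' Write an expression matrix to a delimited file
#' @param expr An `expression_matrix`.
#' @param path Output path (`.csv` writes comma-separated, otherwise TSV).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = expr$gene_ids, expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
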