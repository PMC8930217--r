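#' Gene-expression matrix with sample labels
#'
#' The central data container: a numeric genes x samples matrix plus ordered
#' gene identifiers (duplicates allowed before replicate collapsing), unique
#' sample identifiers, and a binary class label per sample. Missing cells are
#' stored as `NA`; [missing_mask()] exposes them as a logical matrix.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. `NA`
#'   marks missing cells.
#' @param gene_ids Character vector, one id per row. Duplicates allowed.
#' @param sample_ids Character vector, one unique id per column.
#' @param labels Vector of per-sample class labels with exactly two distinct
#'   values; coerced to factor. The first factor level is taken as the
#'   reference (negative) class unless a caller states otherwise.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `sample_ids`, `labels`.
#' @examples
#' m <- expr_matrix(matrix(rnorm(12), 3, 4),
#'                  gene_ids = c("g1", "g2", "g3"),
#'                  sample_ids = paste0("s", 1:4),
#'                  labels = c("normal", "normal", "tumor", "tumor"))
#' dim(m$values)
#' @export
expr_matrix <- function(values, gene_ids, sample_ids, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids)) {
    stop("values has ", nrow(values), " rows but ", length(gene_ids),
         " gene_ids were given")
  }
  if (ncol(values) != length(sample_ids)) {
    stop("values has ", ncol(values), " columns but ", length(sample_ids),
         " sample_ids were given")
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique")
  }
  if (length(labels) != length(sample_ids)) {
    stop("labels length (", length(labels), ") != number of samples (",
         length(sample_ids), ")")
  }
  labels <- as.factor(as.character(labels))
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) {
    stop("labels must contain exactly two distinct values, got ",
         nlevels(labels))
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, gene_ids = gene_ids,
         sample_ids = sample_ids, labels = labels),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  %d missing cells\n", n_na))
  if (anyDuplicated(x$gene_ids)) {
    cat(sprintf("  %d duplicated gene ids\n",
                sum(duplicated(x$gene_ids))))
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Logical mask of missing cells
#'
#' @param m An [expr_matrix()].
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  is.na(m$values)
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param m An [expr_matrix()].
#' @param genes Row index vector (integer, logical, or gene ids).
#' @param samples Column index vector (integer, logical, or sample ids).
#' @return The subset as an `expr_matrix`. Subsetting samples may not drop a
#'   class entirely.
#' @export
subset_expr <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  gi <- seq_along(m$gene_ids)
  si <- seq_along(m$sample_ids)
  if (!is.null(genes)) {
    gi <- if (is.character(genes)) which(m$gene_ids %in% genes) else gi[genes]
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, m$sample_ids) else si[samples]
  }
  expr_matrix(m$values[gi, si, drop = FALSE], m$gene_ids[gi],
              m$sample_ids[si], m$labels[si])
}
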