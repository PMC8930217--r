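# Reading and writing expression matrices as TSV, CSV, or GCT 1.2.

MISSING_TOKENS <- c("", "NA", "NaN", "null")

# Split delimited lines, enforcing rectangular shape. Returns a character
# matrix including the header line as row 1.
parse_delim_lines <- function(lines, sep, path) {
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row in ", path, " at line ", bad, ": expected ",
         widths[1], " fields, found ", widths[bad])
  }
  matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
}

# Convert a character block to numeric, treating the missing tokens as NA
# and reporting the first genuinely non-numeric cell with its line number.
numeric_block <- function(chr, path, line_offset) {
  is_missing <- matrix(chr %in% MISSING_TOKENS, nrow(chr), ncol(chr))
  vals <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(vals) & !is_missing)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(chr))
    stop("non-numeric cell '", chr[bad[1]], "' in ", path, " at line ",
         rc[1] + line_offset, ", field ", rc[2])
  }
  vals[is_missing] <- NA_real_
  matrix(vals, nrow(chr), ncol(chr))
}

resolve_labels <- function(labels, sample_ids, path) {
  if (is.null(labels)) {
    stop("no label source given for ", path,
         "; supply a vector or a two-column sample/label file")
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    tab <- utils::read.table(labels, header = FALSE, sep = "",
                             col.names = c("sample", "label"),
                             colClasses = "character")
    labels <- stats::setNames(tab$label, tab$sample)
  }
  if (!is.null(names(labels))) {
    miss <- setdiff(sample_ids, names(labels))
    if (length(miss)) {
      stop("missing label for sample(s): ", paste(miss, collapse = ", "))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("got ", length(labels), " labels for ", length(sample_ids),
         " samples")
  }
  labels
}

#' Read an expression matrix from TSV, CSV, or GCT
#'
#' TSV/CSV files carry a header line (first field an id column name, the
#' rest sample ids) and one gene per row; GCT 1.2 files carry the
#' `#1.2` magic line, a `n_genes n_samples` count line, and
#' `Name`/`Description` columns. Empty strings, `NA`, `NaN` and `null`
#' are read as missing cells; duplicate gene ids are preserved.
#'
#' @param path Input file.
#' @param format `"tsv"`, `"csv"`, or `"gct"`; default guessed from the
#'   file extension.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`
#'   (TSV/CSV only; the matrix is transposed after parsing).
#' @param labels Label source: a (optionally named) vector, or the path
#'   to a two-column whitespace-separated sample/label file.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path,
                            format = c("auto", "tsv", "csv", "gct"),
                            orientation = c("genes_in_rows",
                                            "samples_in_rows"),
                            labels = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", gct = "gct", "tsv")
  }
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3L || !startsWith(lines[1], "#1.2")) {
      stop(path, " is not a GCT 1.2 file (missing '#1.2' header)")
    }
    counts <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]])
    body <- parse_delim_lines(lines[-(1:2)], "\t", path)
    header <- body[1, ]
    if (!identical(toupper(header[1:2]), c("NAME", "DESCRIPTION"))) {
      stop(path, ": GCT header must start with Name and Description columns")
    }
    sample_ids <- header[-(1:2)]
    gene_ids <- body[-1, 1]
    vals <- numeric_block(body[-1, -(1:2), drop = FALSE], path,
                          line_offset = 3L)
    if (nrow(vals) != counts[1] || ncol(vals) != counts[2]) {
      stop(path, ": declared ", counts[1], "x", counts[2],
           " but parsed ", nrow(vals), "x", ncol(vals))
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    body <- parse_delim_lines(lines, sep, path)
    sample_ids <- body[1, -1]
    gene_ids <- body[-1, 1]
    vals <- numeric_block(body[-1, -1, drop = FALSE], path, line_offset = 1L)
    if (orientation == "samples_in_rows") {
      vals <- t(vals)
      tmp <- gene_ids
      gene_ids <- sample_ids
      sample_ids <- tmp
    }
  }
  labels <- resolve_labels(labels, sample_ids, path)
  expr_matrix(vals, gene_ids, sample_ids, labels)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
  out
}

#' Write an expression matrix as TSV, CSV, or GCT
#'
#' Values are written at full double precision so a
#' [read_expression()] round trip is value-identical; missing cells are
#' emitted as `NA`. Labels are not part of these matrix formats — use
#' [write_labels()].
#'
#' @param m An [expr_matrix()] with at least one gene and one sample.
#' @param path Output file.
#' @param format `"tsv"`, `"csv"`, or `"gct"`; default guessed from the
#'   extension.
#' @export
write_expression <- function(m, path,
                             format = c("auto", "tsv", "csv", "gct")) {
  stopifnot(inherits(m, "expr_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", gct = "gct", "tsv")
  }
  if (nrow(m$values) == 0L || ncol(m$values) == 0L) {
    stop("refusing to write an empty matrix")
  }
  chr <- matrix(fmt_num(m$values), nrow(m$values), ncol(m$values))
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (format == "gct") {
      writeLines("#1.2", con)
      writeLines(paste(nrow(chr), ncol(chr), sep = "\t"), con)
      writeLines(paste(c("Name", "Description", m$sample_ids),
                       collapse = "\t"), con)
      writeLines(paste(m$gene_ids, m$gene_ids,
                       apply(chr, 1, paste, collapse = "\t"),
                       sep = "\t"), con)
    } else {
      sep <- if (format == "csv") "," else "\t"
      writeLines(paste(c("gene_id", m$sample_ids), collapse = sep), con)
      writeLines(paste(m$gene_ids, apply(chr, 1, paste, collapse = sep),
                       sep = sep), con)
    }
  })
  invisible(path)
}

#' Write sample labels as a two-column file
#'
#' @param m An [expr_matrix()].
#' @param path Output file (tab-separated `sample label` lines).
#' @export
write_labels <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  atomic_write(path, function(tmp) {
    writeLines(paste(m$sample_ids, as.character(m$labels), sep = "\t"), tmp)
  })
}
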